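Package: fluctmap
Title: Temporal Speckle Fluctuation Mapping for Grayscale Ultrasound Cine Loops
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and depicts the "fluttering sign" of hepatic hemangiomas in
    grayscale B-mode ultrasound cine loops. Computes a per-pixel cross-correlation
    coefficient between consecutive frames over a local (~2 mm) window, aggregates
    it into a degree-of-coincidence / degree-of-fluctuation map quantized to 255
    gradation levels, and renders a parametric color overlay (blue = stable,
    yellow to red = fluctuating). Includes block-matching motion compensation to
    cancel bulk breathing and pulsation motion before analysis, a rule-based
    positive/negative lesion call, Cohen's kappa agreement statistics, and a
    seeded synthetic speckle cine simulator with known fluttering regions for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
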