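---
title: "Fluctuation mapping: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluctuation mapping: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctmap)
```

## The problem

Hepatic hemangiomas — the most common benign solid liver lesion — sometimes
show a *fluttering sign* on grayscale B-mode ultrasound: over a few seconds
the lesion's internal echogenicity changes continuously, as if the speckle
were shimmering, while surrounding liver speckle stays put. Plausible drivers
are slow internal blood flow, arterial pulsation deforming the lesion's
vascular spaces, and acoustic streaming. The sign is specific enough to be
diagnostically useful, but reading it from a live or replayed video is
subjective and weak cases are easy to miss. This package turns the finding
into an objective, per-pixel parametric map computed from a short cine loop.

## The statistic

Fix a pixel $p$ and two consecutive frames $n-1, n$. Let $W(p)$ be the square
window of physical width about 2 mm centred on $p$. The cross-correlation
coefficient is the Pearson correlation of the two frames over that window,

$$R_n(p) \;=\; \frac{\sum_{(i,j)\in W(p)} (I_n(i,j)-\bar I_n)\,(I_{n-1}(i,j)-\bar I_{n-1})}
{\sqrt{\sum_{(i,j)\in W(p)} (I_n(i,j)-\bar I_n)^2}\;
 \sqrt{\sum_{(i,j)\in W(p)} (I_{n-1}(i,j)-\bar I_{n-1})^2}},$$

with $\bar I_n$ the window mean of frame $n$. Stable speckle reproduces
itself from frame to frame and gives $R \approx 1$; speckle that decorrelates
(because the scatterers rearrange) drives $R$ toward 0. $R$ is invariant
under positive linear intensity maps of either frame, so gain, per-clip
normalization and (approximately) log compression do not change it.

The per-pixel values are aggregated into a **degree of coincidence**

$$C(p) \;=\; \operatorname{mean}\Big\{\, \max(0, \min(1, R_t(q))) \;:\;
t = 1,\dots,T-1,\;\; q \in N(p),\; (t,q)\ \text{valid} \,\Big\},$$

the spatio-temporal mean of $R$ clamped to $[0,1]$ over a spatial
neighbourhood $N(p)$ (also about 2 mm) and all consecutive frame pairs. The
**degree of fluctuation** is $F = 1 - C$, quantized to
$\mathrm{level} = \mathrm{round}(255\,F)$ gradation levels, and rendered
blue (stable) through green and yellow to red (strongly fluctuating).

The aggregation rule deserves a note: what exactly "coincidence around the
analysis point" should average is an open design question for this kind of
method. We chose the clamped spatio-temporal mean because it is linear,
bounded, oracle-checkable by brute force, and reproduces the qualitative
behaviours the method needs — stable tissue maps to blue ($C \to 1$), strong
fluctuation maps to warm colors ($C \to 0$), and negative correlations (which
only arise from noise or motion, never from stationary speckle) count as zero
coincidence. A single forward pass (motion → $R$ → $C$ → $F$) is used; no
temporal smoothing of $R$ is applied.

## Motion compensation

Breathing and cardiac pulsation translate the whole ROI. Uncompensated, a
1-pixel bulk shift between frames decorrelates the speckle pattern inside
every window and masquerades as fluctuation — this is the method's classic
false-positive mechanism near the diaphragm and heart. We model bulk motion
as one global 2D translation per frame, estimated by exhaustive
block-matching: the ROI patch of frame 0 is compared against every integer
shift of frame $t$ within a search radius (default 8 px) and the shift with
the highest normalized cross-correlation wins. Ties break deterministically
(smallest magnitude, then row, then column). Frames are then resampled by the
negative displacement — exactly for integer shifts, bilinearly for
fractional ones — and pixels sampled from outside the frame are flagged
invalid and excluded downstream.

Design choices here, made once: the reference is frame 0, not the previous
frame, because 3.5-s clips are short enough that a fixed reference avoids
drift accumulation; rotation and deformation are not modelled (the target is
*overall* movement of the ROI); subpixel refinement (1D parabolic fit around
the peak) exists but is off by default, keeping the estimator exact on
integer motion and bit-reproducible.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `window_mm` | 2.0 | mm | width of the Pearson window; converted per axis as `radius = round(mm / (2 * spacing))`, min 1 px |
| `neighborhood_mm` | 2.0 | mm | width of the coincidence neighbourhood |
| `n_frames` | 70 | frames | analysis span; 3.5 s at the default 20 fps |
| `frame_rate_hz` | 20 | Hz | cine frame rate (from the container or an override) |
| `motion` | on | — | bulk-motion cancellation before correlation |
| `search_radius_px` | 8 | px | block-matching search radius |
| `display_min_level` | 64 | level | overlay shows color only at or above this level (display only) |
| `level_threshold` | 170 | level | a lesion pixel counts as "colored" for detection at or above this (the yellow anchor) |
| `min_fraction` | 0.05 | — | minimum colored fraction of valid lesion pixels for a positive call |
| `min_component_px` | 25 | px | minimum largest 8-connected colored component |

Pixel spacing matters because the window is physical: at 0.2 mm/pixel the
2 mm window is an 11×11 px box. Missing calibration is an error, never a
silent default. Edge handling fabricates nothing: windows must be fully
supported inside the frame (and inside motion-valid data), so a 1-window
border of the ROI is invalid rather than padded.

## The synthetic generator

No clinical clips ship with the package, so every stage is validated against
a seeded first-order speckle simulator (`simulate_cine()`):

* **Speckle.** A complex circular-Gaussian scatterer field convolved with a
  separable Gaussian PSF (defaults $\sigma$ = 1.5 px axial, 2.0 px lateral);
  the envelope magnitude is the image. Per pixel the envelope is Rayleigh,
  so the point SNR (mean/sd) must be $\sqrt{\pi/(4-\pi)} \approx 1.91$ — a
  distributional check the tests perform on $>10^5$ samples.
* **Flutter.** Inside a lesion mask the field evolves as an AR(1) process,
  $z_t = \rho z_{t-1} + \sqrt{1-\rho^2}\,w_t$; outside it is static. The
  single knob $\rho$ is exactly the quantity the method measures (the
  inter-frame field correlation), enabling parameter-recovery tests: the
  envelope correlation is $\approx \rho^2$, so the expected fluctuation
  inside the lesion is $F \approx 1-\rho^2$.
* **Pulsation.** An optional global sinusoidal translation (default 2 px at
  1 Hz) emulates transmitted heartbeat. Displacements are rounded to whole
  pixels and applied circularly, keeping the artifact a pure bulk
  translation with unchanged speckle statistics — so motion compensation
  can in principle cancel it exactly, and any residual fluctuation is
  attributable to the method, not to interpolation smoothing.
* **Noise.** Additive Gaussian intensity noise (default sd 0.01 on the
  [0,1] scale), a realistic electronic-noise floor.

The canonical presets (`synthetic_preset()`) are 70-frame, 20 fps, 64×64 px
clips at 0.2 mm/pixel — the method's standard analysis budget at a typical
linear-probe resolution — with a 12 px radius flutter disc ($\rho = 0.9$)
and a 30×30 ROI, about twice the disc area, following the guidance that the
analysis needs comparison tissue of roughly the lesion's own size.

What the generator does **not** emulate: depth-dependent PSF and gain,
scan-conversion geometry, reverberation and shadowing, tissue deformation
(only rigid translation), and any physiological model of *why* hemangioma
speckle decorrelates. Passing tests therefore show the pipeline measures
speckle decorrelation correctly and rejects bulk-motion artifacts; they do
not show clinical sensitivity or specificity, and the $\rho$ presets are
engineering choices, not physiological claims.

## Numerical choices

* Box sums use integral images; on the 32×32 oracle fixtures the vectorized
  $R$ agrees with the naive double sum to better than $10^{-10}$.
* Windows with sum-of-squares variance below $10^{-12}$ are invalid
  (correlation undefined), as are unsupported windows.
* All quantization rounds half away from zero (`floor(x + 0.5)`), so levels
  and overlays are bit-identical across platforms; `round()`'s half-to-even
  rule would make single levels platform- and parity-dependent.
* Coincidence is clipped back to $[0,1]$ after averaging to absorb
  last-bit roundoff.
* Simulation uses a private RNG stream (seed in the spec) and restores the
  caller's `.Random.seed`; identical seeds give bit-identical clips, maps
  and files.
* The kappa CI is the Wald interval $\kappa \pm 1.96\,\mathrm{se}$ with the
  Fleiss–Cohen–Everitt large-sample standard error, truncated to $[-1,1]$;
  degenerate marginals ($p_e = 1$) raise a typed error instead of returning
  NaN.

## Validation summary

The test suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch) checks, among others: exact recovery of injected
integer motion up to 5 px; zero fluctuation (level 0 everywhere valid) on a
noise-free static clip; an inside/outside mean-F ratio above 3 (measured
about 10–12) for the $\rho=0.9$ flutter disc against far-field static
speckle over a full-frame analysis region; monotone decrease of inside-F in
$\rho$ over $\{0.5, 0.7, 0.9, 1.0\}$ across 5 replicates; a pulsation-only
clip inflating mean F more than tenfold over the static floor, with motion
compensation removing over 99% of the excess; Rayleigh envelope SNR within
5%; and bit-exact determinism of all written artifacts.

## Known limitations

* **The default detection threshold is conservative by construction.** With
  the clamped-mean coincidence statistic, a region whose field correlation
  is $\rho$ sits at $F \approx 1-\rho^2$: a moderately fluttering lesion
  ($\rho = 0.9$, $F \approx 0.2$, level ≈ 50) colors blue-green and does
  **not** reach the yellow anchor (level 170) that the default
  `level_threshold` uses, so under defaults it is called negative even
  though its map contrast against background is large (the
  $\rho=0.9$-positive expectation in the acceptance suite documents exactly
  this and is expected to fail under defaults). Only near-total inter-frame
  decorrelation ($\rho \lesssim 0.58$) turns yellow. The thresholds are
  explicit parameters precisely so users can calibrate them to their data;
  we deliberately do not lower the default, because any smaller value would
  be an arbitrary point between the noise floor (level ≈ 2–10) and the
  display threshold with no principled anchor.
* One global translation per frame cannot cancel differential motion inside
  the ROI (e.g. the diaphragm moving against the liver); residual local
  motion still registers as fluctuation.
* Real-time operation is out of scope; the pipeline analyses saved clips.
* Supported containers are multi-page TIFF, PNG/TIFF frame directories and
  RDS stacks; DICOM and compressed video must be exported first.
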