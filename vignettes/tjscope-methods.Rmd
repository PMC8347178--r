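---
title: "tjscope: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tjscope: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tjscope analyses tight-junction experiments in which barrier function,
widefield immunofluorescence and single-molecule localization microscopy
(SMLM) are measured on the same endothelial monolayer. This vignette
documents the statistical models, the tunable parameters, the synthetic-data
generator used for validation, and the design decisions taken where the
methodology was genuinely open.

## Barrier function

**TER.** A raw Transwell resistance reading contains the filter and
electrode contribution, so the blank-filter resistance is subtracted before
multiplying by the effective membrane area:

    TER [ohm cm^2] = (R_raw − R_blank) [ohm] × A [cm^2],  A = 0.33 cm^2.

Readings below the blank produce negative TER values; these are returned
with a warning rather than silently clipped, because they indicate a
measurement problem the analyst must see. Treatment effects are expressed
as the fold change `(TER_t / TER_initial)` of each treated replicate,
divided by the *mean* control ratio of the same experiment. Division (not
subtraction) is used so that "a factor of 1.30" is literally the reported
statistic. This ratio-of-means estimator carries a small finite-sample
bias of order `fold × cv² / n` from the nonlinearity of `1/mean(control)`;
at the default noise level (cv = 0.1, n = 6) this is ≈ 0.4% and is left in
place because it is a property of the estimator itself, not of the
implementation.

**Dextran flux.** Fluorescence readings are converted to tracer
concentrations through an unweighted ordinary-least-squares calibration
line `AU = slope × conc + intercept` (no weighting scheme is standard for
a 6-point fluorimeter series). Negative inferred concentrations are
clipped to zero with a warning. The assay readout is
`100 × mean(treated conc) / mean(control conc)`, which is invariant to any
common rescaling of all fluorescence values.

**Group comparison.** `compare_conditions()` is the classical
equal-variance two-sample Student's t-test (two-sided), via `t.test(...,
var.equal = TRUE)` — the unqualified "Student's t-test" convention.
Zero-variance degeneracies are handled explicitly (identical means:
p = 1; distinct means: p = 0, flagged). No multiple-testing correction is
applied; the workflow reports a handful of pre-planned comparisons.

## Widefield quantification

Z-stacks are reduced by maximum-intensity projection (the projection is
idempotent and commutes with monotone transforms, both tested). Intensity
is reported as summed grey value divided by the analyzed pixel count
(A.U. per pixel), so junction-ROI and whole-image values are each
normalized by their own area. Junction "annotation" enters as a binary
mask; the interactive drawing step of a real analysis is out of scope, and
in tests the mask comes from the known synthetic geometry.

Whole-filter surveys are assembled by `stitch_tiles()`: tiles on a nominal
grid (10% overlap by default) are registered by integer-pixel normalized
cross-correlation within a ±5 px search window and blended with linear
feathering. Correlation needs texture; featureless overlaps fall back to
the nominal grid with a warning. Sub-pixel registration is deliberately
omitted — stage jitter in these surveys is integer-pixel scale, and the
cut-and-reassemble test recovers ±3 px jitter exactly.

## SMLM localization

Per frame, background is the median and noise the scaled median absolute
deviation (1.4826 × MAD), both robust to the sparse bright emitters. The
classical "threshold of 3" is implemented as: a candidate must be a strict
8-neighbourhood local maximum of the matched-filtered frame (Gaussian
pre-filter, σ = 1 px) and exceed `bg + 3 × noise_sd`. The matched filter
is what makes a bare 3-SD rule usable: without it, single-pixel noise
excursions above 3 SD are expected by the thousands per movie; with it,
PSF-sized spots survive while uncorrelated noise is suppressed by the
filter's noise gain. The first 30 frames of each stack are discarded
(bleach-down transient).

Each candidate is fit by Levenberg–Marquardt least squares with the
symmetric single-σ model

    I(x, y) = offset + A · exp(−((x − x₀)² + (y − y₀)²) / 2σ²)

in pixel-centre coordinates; pixel `(i, j)` spans
`[(j−1)p, jp) × [(i−1)p, ip)` nm (half-open, origin at the image top-left),
a convention the sub-pixel accuracy tests depend on. Position
uncertainties come from the parameter covariance
`s² (JᵀJ)⁻¹`. Fits are rejected — with machine-readable reason codes —
for non-convergence, widths outside `[0.5, 3] ×` the nominal PSF σ,
centres escaping the window, singular covariance, or amplitudes at the
noise floor (the detection threshold re-applied to the fitted peak
height). The Thompson–Larson–Webb precision formula is used only as an
independent oracle in tests, never inside the pipeline; the measured RMS
error at 1000 photons sits ≈ 1.2 × that bound, as expected for
least-squares fitting of Poisson data.

Counts are event-level: repeated blinks of one fluorophore are not merged,
so densities (`localizations / ROI area` in molecules/nm²) are event
densities, comparable across conditions at matched acquisition settings
but not interpretable as absolute molecule numbers. Overlapping emitters
are not multi-fit; simulations therefore use sparse activation
(on-probability ≈ 0.005/frame) to stay in the valid regime. No drift
correction is applied (the intended instrument class is
thermomechanically stabilized).

## Spatial statistics

The clustering readout is the relative pairwise-distance histogram: all
point pairs closer than `r_max` (200 nm same-channel, 400 nm
cross-channel) on half-open 10 nm bins, normalized by the number of pairs
counted. The bin width is a package choice, exposed in the configuration.
Neighbour search uses a cell-list grid (Rcpp) whose output is verified
identical to O(n²) enumeration on random instances up to n = 2000.

No analytic edge correction is applied. Instead the null model is
simulated: `csr_reference()` places the same number of points uniformly
inside the same ROI mask, so edge, shape and intensity effects are
absorbed by construction. The envelope is the standard rank-based Monte
Carlo envelope (order statistics nearest the 2.5%/97.5% tails of
`n_sim = 99` simulations, giving ≈ 96% pointwise coverage). A channel is
called *clustered* when its observed 40 nm bin exceeds the upper envelope
— a bin-specific call matching the biological claim (claudin-5 cluster
spacing), not a global goodness-of-fit test.

The choice of ROI mask defines the null. For belt-bound molecules the
reference mask is the junction skeleton rasterized one pixel wide at
10 nm/px: the null is "uniformly positioned along the belt". This matters
— against a 2D areal null, any belt-bound point set would show short-range
"clustering" purely because it is concentrated on a 1D structure. With
the skeleton null, dispersed placements sit inside the envelope (negative
control) while Thomas-clustered placements (σ = 20 nm) exceed it
essentially always.

Colocalization is coordinate-based: a molecule is colocalized if at least
one molecule of the other channel lies within 90 nm (the span of two
antibody–fluorophore complexes at minimal distance), counted once
regardless of partner multiplicity. The operation is symmetric under
channel swap and monotone in the radius, both enforced by tests. Note
that chance colocalization grows with density; at junction-belt densities
of tens of molecules per µm the percentage saturates, which is why the
recovery validation runs at sparse densities where the generated fraction
dominates.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults are the
reference experiment:

* **Geometry** — bounded Voronoi tessellation of uniform seeds (computed
  by half-plane clipping; cell shapes are otherwise unparameterized in
  this field). Shared edges form the junction belts; the mean total edge
  length tracks the `2√λ` Poisson–Voronoi law to within the boundary
  clipping effect (≈ 17% at 25 cells in a 40 µm field).
* **Placement** — expected count = belt length × linear density in both
  modes. Dispersed: uniform along arc length. Clustered: Thomas process
  (parents on the belt, Poisson offspring, isotropic Gaussian σ, default
  20 nm). An `off_belt_fraction` adds uniform background labelling.
  Two-channel ground truth offsets true partners by an isotropic Gaussian
  (σ = 20 nm), so true partners fall within 90 nm with probability
  > 0.999.
* **Camera** — per-frame independent Bernoulli blinking (no dark-state
  memory; sufficient for count/cluster recovery), integrated Gaussian PSF
  (σ default 130 nm, typical for a 1.46 NA objective at 561–642 nm),
  Poisson shot noise × EM gain (default 100), Gaussian read noise,
  constant baseline, clipped to 16 bits with a saturation warning.
  Defaults: 2000 frames at 80 nm/px. The EMCCD excess-noise factor is
  omitted — a known limitation that makes simulated images slightly less
  noisy than a real EMCCD at the same gain.
* **Widefield** — one sharp in-focus slice plus defocus-blurred
  neighbours (σ growing 1.5 px per slice of distance), additive
  background ordered glass < polycarbonate < polyester, Poisson noise.
* **Functional records** — mean-preserving lognormal noise of coefficient
  of variation `replicate_cv` on every measurement; raw resistances
  include the substrate blank (PE 121 Ω, PC 88 Ω) so blank subtraction is
  exercised; fluorescence is synthesized through a known calibration line
  so curve fitting is exercised. Defaults encode a tightening treatment:
  TER fold 1.30 (1 h) and 1.41 (5 h), flux 31.7% of control, baseline
  12.9 Ω cm².

What the generator does **not** emulate: optical aberrations, stage
drift, 3D PSF structure, photobleaching decay across the stack, spectral
crosstalk, fluorophore re-blinking statistics (so absolute molecule-count
calibration is out of scope), and the EMCCD excess noise above. Passing
recovery tests therefore demonstrates correctness of the analysis
arithmetic and robustness in the intended operating regime — not
performance on aberrated or drifting real-world data.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and is bit-reproducible;
the workflow (`run_workflow()` / `run_demo()`) derives all stage seeds
from one master seed and re-runs byte-identically. Stages communicate
only through files (TIFF/CSV/JSON), so later stages can be re-run in
isolation.

Validation sizes were chosen to give comfortable Monte-Carlo margins:
500 simulated experiments for functional recovery, 500 spots for
localization accuracy, 100 random instances for brute-force equivalence,
50 placement seeds for the clustering contrast, 20 for colocalization
recovery. The demo images a 6 × 6 µm field (2000 frames per channel),
large enough for ≈ 700 molecules per channel while keeping a full run in
the minutes range on one CPU.

## Known limitations

* Single-emitter fitting only; dense activation biases positions.
* Event-level counting; blink multiplicity inflates densities and the
  zero-distance histogram bin (the 40 nm call is robust to this because
  the multiplicity clump is far narrower than 40 nm, but the bin
  normalization is diluted).
* Integer-pixel stitching; no illumination flat-fielding.
* The interactive steps of a real workflow (junction annotation, SMLM
  ROI drawing) enter as mask inputs, not as automated segmentation.
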