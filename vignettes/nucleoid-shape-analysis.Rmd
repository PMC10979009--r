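---
title: "Methods: quantifying unconfined chromosome shape from single-cell images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying unconfined chromosome shape from single-cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleoidshape)
```

## The measurement problem

In rod-shaped *B. subtilis* the chromosome is squeezed by the cell wall
into a confined object below the optical resolution of its inner
structure. Converting cells to wall-less spheroids in mildly hypoosmotic
medium lets them swell (to roughly 2.3 µm across), giving the chromosome
room to relax toward its intrinsic shape. Imaged with a DNA label
(HbsU fusion or intercalator dye), a ParB fusion marking the replication
origin, and optionally an SMC-condensin fusion and a ter-region marker,
the relaxed chromosome most often appears as a **crescent** arc hugging
the inside of the cell, ori at one tip and ter at the other; cutting the
SMC ring that zips the two chromosome arms opens the crescent into a
**torus**. This package turns such multichannel images into per-cell and
population-level measurements: ori-anchored intensity profiles,
demographs, PSF-limited cluster decompositions, focus counts and
distances, shape calls, and bootstrap shape-ratio estimates.

Because raw image data for this experimental system is not generally
available, the package ships a ground-truthed synthetic generator that
emulates the imaging conditions; all quantitative guarantees quoted here
are demonstrated by the test suite and `scripts/acceptance.R` on that
generator, at the problem sizes given below.

## The synthetic image model

`simulate_cell()` renders one cell on a 64×64 px frame at
65.35 nm/px (the study's calibrated pixel size). The geometry is a
circular-arc backbone of radius 0.75 µm centered in a 2.3 µm cell disc:

* **crescent** — arc span drawn from 90–180° (the range the patterns
  subtend in-plane), ori at one endpoint, ter at the other; the arc's
  angular phase and handedness are randomized so profiles must be
  flipped, exactly as in real fields of view;
* **toroid** — the same annulus closed to 360°;
* **compact** — a single Gaussian blob (σ = 250 nm);
* **other** — a straight bar (1.9 µm) through the cell center, a
  non-annular pattern that exercises the classifier's fallback.

DNA mass is distributed along the backbone by a linear density model
(uniform, exponential with decay length λ, or piecewise-constant) and
smeared transversely with a Gaussian ribbon (σ = 150 nm). Condensed
regions are added as Gaussian blobs carrying a stated fraction of the
photon budget: a primary blob at the ori and any number of secondaries
at chosen arc positions. The ParB channel holds one PSF-limited focus at
the ori (extras can be placed for multi-origin scenarios); the SMC
channel tracks the DNA density multiplied by a Gaussian enrichment bump
at the ori, calibrated so its profile fold-increase at the origin hits
the requested value (default 1.6); the `cell` channel is a uniform disc
standing in for the phase/membrane image the cell mask is drawn from;
an optional ter channel places foci at the ter tip with a diffuse
intracellular fraction emulating the low SNR of sparse ter labels.

Optics and camera follow the standard model: pixel-integrated Gaussian
PSF of σ = 120 nm (the order of the quoted optical resolution), a
constant camera background (5 counts), Poisson shot noise, Gaussian read
noise (σ = 2 counts), and rounding to integer ADU clipped to 16 bits.
The default photon budgets (2×10⁵ DNA photons, 2×10⁴ per ParB focus)
put the on-arc signal-to-noise well above 10. Z-stacks are rendered as
the in-focus plane plus defocus-widened planes
(σ(dz) = √(σ² + (dz/2)²)); analysis uses the maximum projection, so full
3-D optics are not modeled. Absolute brightness and gain are not known
quantities of the study; the defaults are documented choices giving
mid-range SNR, not values inferred from data.

`SimTruth` records everything needed to score recovery exactly: the arc
geometry, the normalized linear density sampled at quarter-pixel steps
(cluster mass included as point mass at its grid position), the cluster
table, and noiseless per-channel photon totals. In the noiseless limit
the rendered channels conserve photons exactly, rendering is
mirror-symmetric to floating-point precision, and identical seeds give
bit-identical stacks — all asserted by tests.

**What the generator does not emulate:** polymer fluctuations and
fine-scale density texture, cell-to-cell brightness variability,
aberrated or measured PSFs, uneven illumination, and segmentation-
confusing debris. Passing tests therefore demonstrate correctness of the
measurement chain under a faithful optical model, not robustness to
every artifact of real microscopy.

## Segmentation and screening

Cells are detected on a Gaussian-smoothed (σ = 1 px) max projection of
the `cell` channel with Otsu's threshold computed on the image rescaled
to [0, 1] — making masks invariant to intensity rescaling — followed by
hole filling, connected-component labeling and a 1 µm² minimum area.
Roundness is the isoperimetric ratio `4πA/P²`; the default cutoff 0.85
retains discs (ratio → 1) and rejects elongated or ragged thresholding
artifacts (a 4:1 rectangle scores ≈ 0.5). Screening criteria of this
kind are usually stated qualitatively, so the cutoff is a documented
package default. Cells are accepted only when exactly
one ParB focus appears in the ParB maximum projection within the mask,
which restricts analysis to single-chromosome (replication-halted)
cells.

## Backbone fitting and profiles

The annular coordinate system is anchored by a circle fit to the
above-Otsu DNA pixels (intensity-weighted algebraic fit refined by eight
Gauss–Newton steps on the geometric residual; the algebraic fit alone
underestimates the radius of short wide arcs). Two degeneracy guards
reject cells the arc model cannot describe, with a typed
`shape_not_arclike` error that the pipeline logs as an exclusion: a
relative radial spread above 0.35 (compact blobs fit a small circle
through their interior), and signal confined to fewer than 3 angular
bins. Angular support is computed from chromosome-classified (Otsu)
pixels per 5° bin; an intensity-versus-median rule was rejected because
the all-bin median is a noise floor for sparse arcs but the full signal
level for tori, breaking both cases.

Arc length is measured from the ParB angle, `s = r̄·(θ − θ_ori)`, with
r̄ the intensity-weighted mean radius. Each channel's
background-subtracted intensity is integrated per arc-length bin
(default 0.13 µm ≈ 2 px) in both angular directions and divided by the
bin length ("per unit annular section"). Whole pixels are deposited into
bins with a tent kernel over the two nearest bin centers; hard wedge
assignment leaves ~3 % quantization ripple on a flat profile, the tent
kernel brings the noiseless flat-profile coefficient of variation under
2 %. `align_and_flip()` chooses the orientation with the larger total
DNA signal on the positive side, keeps the positive side up to the
representative length (default 3.5 µm, chosen so any 90–180° arc of
plausible radius fits; bins beyond the observed arc are explicit `NA`),
and recomputes the fold-increase so each profile has mean 1 over
observed bins. The operation is involution-safe and, on noiseless
input, invariant to image mirroring and 90° rotation to 10⁻⁶.

`estimate_decay_length()` fits log fold-increase against `s` by
weighted least squares. Convolution with the PSF/ribbon kernel leaves
the interior log-slope of an exponential unchanged but depresses the
bins within about one blur width (~0.2 µm) of each chromosome tip, so
the fit excludes 0.45 µm at the ori end and 0.25 µm before the far end
by default; with the defaults this recovers λ = 1.0 µm with ~1–3 %
median error over 40–50 simulated cells.

## Clusters

The nucleoid pattern is modeled as a sum of PSF-limited spots: greedy
matching pursuit places a pixel-integrated Gaussian of fixed σ = PSF at
the intensity-weighted position of the brightest residual peak,
stopping when the peak falls below 3 robust noise units (MAD of the
sub-Otsu mask pixels) or at 40 spots. Amplitudes are then re-fit jointly
by non-negative least squares (`pracma::lsqnonneg`), alternated twice
with (i) re-centering each spot on the residual that excludes the other
spots and (ii) merging spots within 1 σ of a stronger one — greedy
ghost spots collapse onto the emitter they belong to, so an isolated
rendered spot is recovered as exactly one spot with its full photon
count (±2 %), and two equal spots 3 σ apart split the signal 50:50
(±5 %). If the joint refit fails the greedy amplitudes are kept with a
warning.

Clusters are single-linkage components of the spot set at a linking
radius of one PSF **FWHM** (2.355 σ, ≈ 283 nm) — the natural reading of
"within one PSF" for optically separable groups; the radius is exposed
for users preferring 1 σ. The implementation uses
`stats::hclust(method = "single")` with `cutree(h = radius)`; the test
suite checks it against an independently written union–find oracle on
hundreds of random spot sets. Clusters are ranked by their fraction of
whole-cell signal; rank 1 is the primary cluster, with intensity ties
broken by proximity to the ParB focus (deterministic, and consistent
with the primary cluster's ori association). Note one consequence of
single linkage worth knowing when designing analyses: a contiguous
uniform arc chains into a *single* cluster holding essentially all DNA;
primary/secondary structure appears only when condensed regions are
separated by gaps wider than the linking radius, which is also how the
recovery benchmarks are constructed (a 45 % ori blob plus PSF-limited
secondaries ≥ 0.65 µm apart).

`fraction_within_radius()` reports the background-subtracted signal
share within a Euclidean disc (default 500 nm) of the origin, counting
pixels by their centers; it is computed both on the image and on the
generator's truth density, and the two agree with an independent
quadrature oracle within ~0.01–0.03 (image-side values are slightly
diffused by the PSF).

## Demographs

Each accepted cell contributes its fold-increase profile as one row;
rows are ordered by decreasing robust Michelson contrast
`(q95 − q5)/(q95 + q5)` of the fold-increase values (demograph
figures rarely state their ordering statistic; the quantile form is
scale-invariant and insensitive to single-bin outliers, and a CV
alternative is selectable). Bins a shorter chromosome does not reach
stay `NA` and are excluded from the column-wise mean profile —
zero-padding would bias the population mean downward at large `s`. The
matrix is canonical under input permutation.

## Shape classification

The blinded human raters of manual shape selection are replaced by
a deterministic feature classifier; this is required for an automated
pipeline, and rater-to-rater variability is emulated only through the
bootstrap. All features are computed on chromosome-classified pixels of
the background-subtracted DNA image, making labels invariant to
intensity rescaling:

* radius of gyration (nm) — compact if below 320 nm;
* angular coverage and relative radial spread about the fitted circle —
  toroid if coverage ≥ 330° with a hole score ≥ 0.5 (central void at
  least half as deep as the ridge is bright);
* crescent if coverage lies in [60°, 330°), radial spread ≤ 0.30, and
  the **bend** — the sagitta of a weighted quadratic fit of minor-axis
  offset versus major-axis position — is at least 75 nm. The bend is
  what separates genuinely curved arcs (sagitta ≥ 140 nm at the
  shortest simulated spans) from straight bars (≤ 11 nm), which
  coverage and radial spread alone cannot do reliably;
* anything else, including patterns whose circle fit is degenerate,
  is `other`.

Thresholds are package defaults tuned on the generator at SNR ≥ 10 and
exposed in `shape_params()`; accuracy on 100 simulated cells per class
is ≥ 95 % (typically 99–100 %). Confidence is a clamped margin-to-
threshold heuristic in [0, 1], not a calibrated probability.

`bootstrap_ratio()` mirrors the manual selection series: each of
`n_boot = 25` series draws `picks_per_series = 100` cells *without*
replacement (no cell shown twice within a series; sampling falls back to
with-replacement, with a warning, only when the population is smaller
than a series), computes toroid/(toroid + crescent), and reports the
mean and SE = sd/√n_boot. On a fixed 30/70 population the estimate sits
within three analytic hypergeometric standard errors of 0.30 and the SE
scales as 1/√n_boot. Cells classified compact/other simply do not enter
the ratio. Within-condition sampling is used throughout; cross-condition pooling
of picks is deliberately not modeled.

## Foci, the 15 % filter, and ori:ter

`detect_foci()` finds 8-neighborhood maxima above background plus 5
robust noise units, refines them to sub-pixel positions
(intensity-weighted centroid by default; a fixed-width Gaussian
least-squares fit is available), and suppresses duplicates whose refined
positions land within 1.5 σ of a brighter focus — mutual centroid pull
draws genuine pairs no closer than ~0.6 of their true separation, so
resolvable spots survive while noise bumps on a spot's skirt are
removed. Integrated intensity is the background-subtracted sum over a
window of half-width 2 σ (local background = median of the window's
border ring); this is a slightly conservative estimate (the window
truncates the far tail) but cancels in the fraction-based filter.
Noiseless localization bias is below 0.2 px, and inter-channel spot
pairs at the 126 nm scale are recovered with ~1 nm mean absolute error
at SNR ≥ 10 — comfortably inside the biological spread of such
distances.

Spots holding less than 15 % of the cell's total signal are discarded
before ter counting, reproducing the filter used for the low-SNR ter
channel. The ori:ter ratio pools counts over cells with at least one
retained ter focus (`sum(ori)/sum(ter)`); pooling is the default and
per-cell averaging is an option (`per_cell = TRUE`). Simulated halted (1:1) and replicating
(4:1) populations are recovered within 10 %.

## Pipeline, formats, determinism

`run_pipeline(pipeline_config(...))` chains the stages over simulated or
TIFF input, logs every exclusion with its stage and reason, and reports
a screening funnel that is monotone by construction
(detected ≥ round-pass ≥ single-ParB ≥ profiled). Configurations are
validated before any computation and round-trip losslessly through
YAML. Images are 16-bit multipage TIFF (z fastest within channel) storing
integer camera counts as `count/65535`, which round-trips exactly;
tables are CSV and summaries JSON. All randomness flows from explicit
seeds (per-cell seeds derived reproducibly from a master seed), so
identical configurations give bit-identical outputs. The package is a
library: the pipeline's R functions and configuration files are the
intended interface, and `scripts/acceptance.R` shows a complete headless
run.

## Numerical choices and limitations

* Coordinates are 0-based with pixel centers at integers; positions in
  nm are `px × 65.35` by default.
* Otsu thresholds are computed on 256-level histograms of range-
  normalized values; backgrounds are medians of sub-threshold mask
  pixels and noise is their MAD (floored at 10⁻¹²) — all scale-covariant.
* The problem sizes used by the tests and acceptance script — 40–50
  cells per population benchmark, 100 per class for classification,
  60–100 noise draws for metrology — were chosen as the smallest sizes
  at which the population statistics are stable; all complete in a few
  minutes on one core.
* The cluster decomposition fixes spot width to the PSF; structures
  broader than the PSF are represented by several spots, which is the
  intended description, but no model selection over spot counts is
  performed.
* Demograph comparisons across studies are relative: bin width,
  representative length and the row-ordering statistic are this
  package's definitions and are config-exposed.
* The classifier cannot distinguish single from partially replicated
  chromosomes, and time-resolved analyses (focus mobility) are out of
  scope.
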