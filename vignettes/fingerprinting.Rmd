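---
title: "Cross-species connectivity fingerprinting: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species connectivity fingerprinting: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossFC)
```

## The problem

Comparing the functional organization of brains across species is hard
because regions cannot be matched one-to-one. Connectivity fingerprinting
sidesteps direct homology: each frontal *seed* region is characterized by
the vector of its resting-state functional connectivity (FC) with a fixed
set of *target* regions that can be identified in every species. Two seeds
— possibly in different species — are then compared by the similarity of
their fingerprint vectors, not by their anatomy.

This package implements that analysis end to end for the canonical
eight-target design: primary motor (M1), insula (Ins), primary
somatosensory (S1), posterior cingulate (PCC), posterior parietal (PPC),
striatum (Str), pulvinar (Pul), and superior colliculus (SC), in exactly
this order (`canonicalTargets()`). The order is arbitrary but must be
identical in every fingerprint for cosine similarity to be meaningful, so
it is pinned package-wide and written into every output file.

## The model and procedure

For each scan (one resting-state run of one animal):

1. **Preprocessing tail** (the package consumes already-registered 4D
   volumes): isotropic Gaussian spatial smoothing of a stated FWHM;
   ordinary-least-squares regression of each series on an intercept, an
   optional linear trend, and the scan's confound regressors (e.g. the six
   rigid-body motion parameters); zero-phase Butterworth band-pass,
   order 4 per pass, default 0.01–0.1 Hz.
2. **Seed FC**: Pearson correlation `r` between the seed's mean time
   course and each target's mean time course (or every voxel, in map
   mode), then the Fisher transform `z = atanh(r)`, which
   variance-stabilizes `r` so scans can be averaged.
3. **Fingerprint**: the ordered 8-vector of a seed's z values with the
   canonical targets.

At the group level, scan fingerprints are averaged with equal weight
(scan-level fixed effects), then min–max normalized:
`(f - min f) / (max f - min f)`, so 0 marks the weakest and 1 the
strongest connection *within that fingerprint*. Normalization makes the
comparison one of connectivity *pattern* rather than absolute strength,
which differs across species, scanners, and anesthesia states.

Two normalized fingerprints `a`, `b` are compared by cosine similarity
`(a·b)/(‖a‖‖b‖)`; on normalized (nonnegative) fingerprints this lies in
[0, 1].

### Significance: the permutation test

Whether an observed cosine is *smaller than chance would allow* is decided
by a resampling null that treats scan-level fingerprints as exchangeable
units. Each iteration pools the `nA + nB` scan fingerprints of the two
seeds, shuffles them without replacement into pseudo-groups of the
original sizes, averages, normalizes, and computes the cosine. Because
pseudo-groups mix the two seeds' scans, this null concentrates near 1 (and
approaches 1 as scan noise vanishes — a property the test suite checks).
The decision rule is one-sided and strict: a comparison is *significantly
different* when the observed cosine is below the **lowest first
percentile** of the null, where the percentile is pinned to the lower
empirical order statistic at 1-based index `ceiling(q/100 · n)`
(interpolating definitions differ negligibly at n = 10,000, but a pinned
definition is needed for reproducibility). The observed null rank is also
recorded as an empirical p-value, for reporting only.

Decisions that the underlying method description leaves open, and how this
package pins them (each is also logged verbatim in every run log):

* **Correlation estimator**: Pearson. **"Z score" maps**: Fisher r-to-z
  followed by across-scan averaging (a one-sample t alternative was
  considered and rejected as the default because averaging z is the
  standard construction for seed FC and keeps scan-level and group-level
  fingerprints on one scale).
* **Aggregation**: all runs of all animals pooled with equal weight. A
  run→animal→group two-stage average would weight animals equally
  instead; with balanced designs the two coincide.
* **Normalization order**: group-average the raw z fingerprints first,
  normalize second — in both the observed and the permuted statistic, so
  the observed value is exchangeable with its null.
* **Stage order**: smooth → confound regression → band-pass → extraction.
  Order matters (the steps do not commute), so tests pin it. Extraction
  commutes with the temporal steps by linearity, which is why ROI-mode
  pipelines may extract first and then filter the 9 ROI series instead of
  ~10^5 voxel series.
* **Percentile rule**: strict inequality, one-sided, q = 1, no
  multiple-comparison correction across matrix cells (per-cell decisions
  are reported; a correction can be applied downstream if desired).

## The synthetic-data generator

Real cross-species resting-state data of this kind are not publicly
deposited, so the package ships a generator
(`syntheticSpec()`, `generateROITimeseries()`, `generateVolumes()`) whose
defaults emulate the targeted acquisition regime: **600 volumes per scan
at TR 1.5 s**, isotropic **0.5 mm** voxels, **5 scans** per species, cubic
ROIs of 1.5 mm edge laid out on a lattice.

The signal model is a latent multivariate Gaussian per scan: unit-variance
ROI signals whose correlation matrix has the planted fingerprint in the
seed row, 0.1 among targets, and 0.1 among seeds. The seed–target row is
the scientifically meaningful part; the within-target and within-seed
correlations merely close the matrix, and 0.1 represents weak background
coupling. A spec whose implied matrix is not positive semi-definite is
**rejected, never repaired** — silent repair would change the planted
truth that recovery tests compare against. Temporal structure is AR(1)
with lag-1 coefficient 0.3 for both signal and observation noise, a
typical mild autocorrelation for BOLD at this TR after high-pass
filtering.

Observation noise with SD 0.5 is added to the unit-variance latent
signals, which (a) attenuates observed correlations by a factor
`1/(1 + 0.5²) = 0.8`, uniformly across targets, and (b) was chosen so a
single-scan seed–target correlation estimate has a standard error of
about 0.04 at T = 600 — the regime in which group averaging over ~5 scans
is necessary and sufficient, matching how the real analysis is designed.
Uniform attenuation matters: min–max normalization and cosine similarity
are (approximately, through the mildly nonlinear Fisher transform)
invariant to it, which is exactly why recovery of the *normalized*
fingerprint is the right target. Confounds are a sinusoidal drift plus six
smooth motion-like regressors (mirroring stored rigid-body motion
parameters), mixed into every ROI with random loadings at amplitude 0.25
by default, and returned alongside the series so the pipeline can regress
them back out. Volume rendering paints each ROI's series into its cube's
voxels plus independent voxel noise (SD 0.5); all other voxels are pure
noise.

What the generator does **not** emulate: hemodynamic response shape,
physiological (cardiac/respiratory) noise, susceptibility distortion,
inter-subject anatomical variability, or spatially correlated noise.
Passing recovery tests therefore show that the pipeline's statistics are
implemented correctly and are well-calibrated under a plausible noise
model — not that the pipeline is robust to every artifact of real
acquisitions.

## Numerical choices

* Gaussian smoothing uses `sigma = FWHM / (2 sqrt(2 ln 2))` per axis in mm,
  converted to voxel units, applied separably with half-sample symmetric
  (reflective) boundaries; the operator has unit row sums (constant images
  are fixed points) and, being symmetric, unit column sums (total image
  mass is conserved). Kernel support is truncated at 4 sigma.
* The band-pass is `signal::butter(4, ...)` applied forward and backward
  (`filtfilt`), i.e. zero-phase, squaring the magnitude response. A
  passband sinusoid at 0.05 Hz retains more than 95% amplitude and a
  0.005 Hz drift less than 10% (the suite verifies both by FFT).
  `low = 0` degenerates to a low-pass; the DC component is removed by
  demeaning before filtering.
* Fisher z clamps `|r| > 1 - 1e-7` (with a warning) so that z stays
  finite; a clamped value marks a degenerate target (e.g. the seed
  itself), not a usable connectivity estimate.
* Constant series are errors where a correlation is requested explicitly
  (`pearsonR`), and missing-with-warning where they arise incidentally
  (a constant target among eight).
* Degenerate permutation iterations (a constant pseudo-group average,
  possible only in pathological inputs) are redrawn and counted; more
  than 1% redraws aborts the test rather than quietly biasing the null.
* All RNG consumers take explicit seeds and restore the caller's RNG
  state; pipeline stages derive their seeds from one top-level seed by a
  fixed counter scheme (`seed + 10007·k mod 2^31 - 1`), so partial reruns
  see identical streams. Floating-point outputs are written with 6
  significant digits and manifests hash that canonical text form, making
  rerun verification a byte comparison.

## Problem sizes used by the test suite

The suite exercises the full stack at deliberately chosen sizes: oracle
checks on instances of 8–600 samples; permutation calibration with 500
null datasets × 2,000 iterations (nominal 1% rule, binomial 95% band
about [0.3%, 2.2%] at 500 tests); full-volume recovery on 20 independent
studies of 5 scans × 600 volumes on a 16×16×10 grid, requiring cosine
> 0.95 against the normalized ground truth in at least 95% of repeats;
and a power sweep over planted angles of 4–30°, the range spanning the
test's power transition at these study conditions (n = 6 scans/group,
scan-level fingerprint SD 0.1) — below ~6° the test almost never rejects,
above ~20° it essentially always does.

## Known limitations

* The latent-Gaussian generator constrains how dissimilar two seeds of
  one species can be while remaining jointly positive semi-definite;
  multi-seed specs with strong, near-parallel fingerprints but low
  planted seed–seed correlation are rejected at construction.
* Fixed-effects pooling ignores animal identity; with unbalanced runs per
  animal, animals contribute unequally. The permutation test likewise
  shuffles scans unconstrained by animal.
* Map mode computes ~10^5 voxel correlations per seed per scan in plain
  R; it is intended for moderate grids, with ROI mode as the fast path.
* The translation sweep reports sensitivity to seed placement but does
  not correct fingerprints for it.
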