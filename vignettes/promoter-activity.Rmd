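---
title: "Measuring promoter activity in absolute units: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring promoter activity in absolute units: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

A promoter's strength can be stated as the flux of RNA polymerases that
productively exit it, per second and per DNA copy (RNAP/s-DNA). If a cell
holds `N` plasmid copies of the promoter, each working at rate `J`, and
transcripts decay with first-order rate `tau`, the transcript count `m`
satisfies `dm/dt = N J - tau m`. At steady state,

    J = tau * m / N,

so a joint single-cell measurement of `m` and `N`, together with one
population-level degradation rate, turns fluorescence microscopy into an
absolute promoter assay. The package computes the per-cell `J`, the total
activity `N J = tau m`, and the population mean `<J> = tau <m/N>` — exactly
the mean of the per-cell values, not the ratio of means.

Assumptions worth keeping in mind:

* **Steady state.** Cells must be in balanced growth; after perturbations
  (rifampicin, stationary phase) the identity holds only for the
  pre-perturbation counts.
* **One `tau` for all cells.** The degradation rate is a population
  constant; extrinsic variability in degradation machinery is folded into
  the spread of `J`.
* **Plasmid count = promoter count.** Cells with `N = 0` carry no
  information about `J` and are excluded from activity distributions; they
  are reported separately as the plasmid-loss fraction.

## Image analysis

All quantification runs on raw intensity images plus an integer label mask
(0 = background, `k` = cell `k`). Pixel coordinates are 1-based with pixel
centres at integer positions; `x` indexes columns and `y` rows.

**Registration.** Colour channels are aligned by exhaustive search over
integer shifts within `max_shift` (default 5 px), maximizing the Pearson
correlation of the overlapping region. Ties break toward the smaller shift,
then lexicographically, so results are reproducible. Constant images have
no defined correlation and raise an explicit error. Subpixel registration
is deliberately out of scope: downstream quantities are per-cell sums and
fitted centres, neither of which benefits at the PSF widths involved.

**Smoothing.** A Gaussian kernel of support radius 5 px (width 11) and
standard deviation `radius / 3` smooths each channel before seeding, so the
stated radius carries about three standard deviations of the kernel.
Boundaries are mirror-reflected; a constant image passes through unchanged
and total intensity is conserved away from the border. Smoothing is used
only to find seeds — fits always run on the raw image, so intensities stay
on the photon scale.

**Seeding.** Spot candidates are strict local maxima (8-connectivity) of
the smoothed image inside the cell mask whose height above the in-cell
median exceeds `min_prominence`. The default threshold is `3 * mad(in-cell
pixels)`, a robust noise floor; it is exposed because the right value
depends on camera gain and background. An empty seed list is meaningful:
cells without spots carry a molecule count of zero.

**Fitting.** Each seed is fit over a `2 * window + 1` square (default
`window = 7`) with the five-parameter model
`b + A exp(-(x - x0)^2 / (2 sx^2) - (y - y0)^2 / (2 sy^2))` by
Levenberg–Marquardt least squares (unweighted, as is standard for this kind
of data). The spot intensity is the background-free integral
`2 pi A sx sy`, an exact identity of the fitted model. Fits are rejected —
with the reason recorded, never silently — when the optimizer fails, the
centre leaves the window by more than 2 px, a width hits its bounds, or the
amplitude is below 3 residual standard deviations (a seed on flat
background). Overlapping spots are handled by intensity rather than joint
fitting: fits whose centres are closer than one PSF width are deduplicated
keeping the larger integral, and a bright spot simply counts for several
molecules after calibration. This matches the biology — plasmids cluster,
and brighter spots indicate more copies in a cluster.

**Geometry.** Cell area comes from the mask; width is the minor-axis extent
of the mask pixels (principal components of the pixel coordinates, span
plus one pixel footprint); volume is `area(um^2) * width(um)`, a
slab-of-width approximation appropriate for rod-shaped bacteria lying flat.

## Unit-intensity calibration

In a sample where most spots hold 1–4 molecules, the spot-intensity
distribution shows equidistant peaks at integer multiples of the
single-molecule intensity `u`. The calibration estimate is the mean of the
first three spacings, `u = (p4 - p1) / 3`.

Peak detection uses a kernel-density estimate. Bandwidth matters more than
anything else here, and no single rule works across the regimes we care
about, so the implementation uses a two-stage scheme: a Silverman-bandwidth
pass (falling back to 1/3, 1/9, 1/27 of it if fewer than two peaks appear)
gives a provisional spacing `u_est`, and the final pass runs at `u_est / 8`
— narrow enough to resolve minor peaks, wide enough to average tens of
spots per peak at the recommended sample sizes. A candidate peak must clear
two prominence thresholds: 5% of the density maximum, and 3 times the local
KDE sampling noise `sqrt(f * R(K) / (n h))`. The second filter is what
stops chance undulations of a single broad cluster from masquerading as
peaks; a genuinely unimodal sample then fails calibration with an
instruction to use a lower-copy calibration sample. A final sanity check
requires the first four peak spacings to agree within a factor of 1.8,
catching sparse samples where a peak was missed and the naive `(p4 - p1)/3`
would silently be 4/3 of the truth.

Counting divides each spot integral by `u` and rounds to the nearest
integer, ties away from zero. Spots below `0.5 u` are discarded as noise
(dim maxima that survived seeding); a cell whose spots are all discarded
counts zero. This rounding rule was a genuinely open choice — flooring
sub-unit spots to one molecule is defensible too — and is therefore
explicit and isolated in `counts_from_spots()`.

Calibration is per-channel and per-experiment. Day-to-day drift in
illumination and camera gain is real; reusing a unit across days is not
supported by default.

## Degradation rate

A transcription-arrest time course (sampling at 0, 4, 10, 20 and 60 min by
default) is fit with `m(t) = m0 exp(-k t)` on the per-time-point means,
initialized from a log-linear regression. The half-life is `ln 2 / k` and
`tau = k / 60` in 1/s. Uncertainty comes from a 200-resample bootstrap over
cells within each time point. Fitting means rather than per-cell counts is
deliberate: per-cell Poisson weights would need a full mixed model for
little gain at these sample sizes. Non-decaying data (fitted `k <= 0`) is
an explicit error, not a warning.

## Population statistics

`population_activity()` excludes `N = 0` cells, computes `<J>`, the pooled
population SD, the zero-activity fraction (cells with plasmid but no
transcript — a real subpopulation, reported rather than dropped), the
plasmid-loss fraction, and, when replicates are labelled, the day-to-day SD
across replicate means. Replicate poolability is assessed with the
two-sample Kolmogorov–Smirnov test; for `n_a * n_b <= 100` the p-value is
exact (permutation distribution, ties included), asymptotic otherwise.
The exactness cutoff matches where enumeration is cheap and where the
asymptotic approximation is worst.

Dose-response summaries (`bin_and_fit_hill()`) bin single cells into
equal-occupancy bins of copy number or volume and fit
`y = ymax x^h / (x50^h + x^h)` to the binned means, reporting the fitted
fold change across the observed range. Fitting binned means, not raw
points, is intentional (it is how such figures are built) but has a Jensen
cost: with a curved response, the mean of `y` in a wide bin is not the
curve at the mean `x`. Recovery is exact only for discrete covariates.

## The plasmid copy-number model

Copy-number distributions emerge from two competing stochastic processes at
division:

* **Partitioning.** A dividing cell with `x` plasmids gives `x1` to one
  daughter with probability proportional to `choose(x, x1)^a`. The
  coefficient `a` interpolates from uniform partitioning (`a -> 0`, maximal
  plasmid loss) through the unbiased binomial (`a = 1`) to a deterministic
  even split (`a -> Inf`). This one-parameter exponential tilt is the
  simplest family containing the pure binomial that spans the
  even-to-uniform range; the kernel is an isolated function and can be
  swapped for any other partitioning law.
* **Replication control.** Each daughter replicates single copies
  sequentially, continuing with probability `p(n) = 1 / (1 + (n / N0)^K)`
  at current count `n` and stopping at the first failure. As `K -> Inf`
  this is literally "replicate until `N0` is reobtained" (the outcome from
  `x < N0` concentrates on `{N0, N0 + 1}`); smaller `K` gives broader
  outcomes and higher copy-number variance. At moderate `K` the stationary
  mean sits slightly below `N0` because failures accumulate over the many
  steps a low-count daughter must take — this is a property of the model,
  not a bug, and is why fitting `K` to an observed mean matters.

Population turnover is Moran-like: pick a uniformly random plasmid-bearing
cell, divide it, insert both daughters, remove one uniformly random cell.
Plasmid-free cells persist (antibiotic selection keeps them visible in a
snapshot) but never divide; random removal sets the stationary loss
fraction. Snapshots are post-replication (division-ready) counts;
cell-cycle-phase sampling is not modelled. Runs use `generations *
pop_size` division events after an equally long burn-in; at the default
2000 cells and 15–20 generations, snapshots at one and two burn-ins are
statistically indistinguishable (KS D < 0.05) and disparate initial
conditions converge to the same distribution.

`fit_sim_params()` grid-searches `(a, K)` (defaults: 13 log-spaced points
in [0.1, 10] and [0.5, 32]) minimizing the two-sample KS statistic between
the observed counts and a simulation run at each grid point *with the same
seed*. The shared seed makes the objective deterministic, so an observation
generated on the grid is recovered exactly, and off-grid truth lands on a
neighbouring grid point. `N0` is fixed from the observed mean rather than
fitted — it is directly measured, and freeing it only blurs the other two
parameters.

The two-state (telegraph) transcription simulator is an exact Gillespie
simulation of ON/OFF switching with transcription only in ON and
first-order decay, run per cell to `t_end = 8 * max(1/tau, 1/(k_on +
k_off))` — several relaxation times of both the transcript count and the
promoter state — from the stationary promoter state. Its stationary mean is
`k_on / (k_on + k_off) * k_tx / tau`; `k_off = 0` recovers Poisson (Fano
factor 1), slow switching gives the super-Poissonian (Fano > 1.5)
distributions that rationalize observed transcript-count widths. The rate
parameterization (`k_on`, `k_off`, `k_tx`, `tau`) is this package's own.

## The synthetic-data generator

Every quantitative guarantee in the test suite is exercised on synthetic
data with exact ground truth, so it is worth being precise about what the
generator emulates:

* **Cells** are capsules (rectangles with semicircular caps), 2.5–4 um
  long and 0.8–1.1 um wide at 0.1 um/px, placed without overlap (1 px
  clearance) at small random orientations. An axis-aligned rectangle mode
  with snapped centres exists for exact-geometry tests.
* **Spots** are isotropic 2D Gaussians with `sigma = 1.5` px sampled at
  pixel centres, total integral `multiplicity * unit_intensity` (default
  1000 photons per molecule). Molecules are grouped into up to 4 clusters
  per cell by default — brighter spots mean more molecules — with centres
  uniform over the 1-px-eroded mask and a preferred minimum separation of
  5 px. A single-cluster mode (`max_spots = 1`) reproduces the regime of a
  calibration sample where each cell shows one k-molecule spot.
* **Camera**: constant background (50 photons/px), Poisson shot noise,
  additive Gaussian read noise (SD 2), each independently switchable so
  oracle tests can run noise-free. Pixel size, PSF width and gain are not
  reported quantities for the original instrument; the defaults are
  realistic for a 100x sCMOS setup and live in the config, not in the
  science.
* **Populations**: plasmid counts from a point mass, an empirical pool, a
  Poisson, or the copy-number simulator; transcripts Poisson with mean
  `11.2 * N` by default, with 5% of plasmid-bearing cells silent —
  matching the observed mean activity scale (`tau * 11.2 ~ 0.019`
  RNAP/s-DNA at a 6.8-min half-life) and zero-activity fraction.
* **Calibration samples** for recovery tests draw multiplicities 1–4 with
  geometric weights (ratio 0.6) and per-molecule multiplicative noise of
  SD `0.1 * u * sqrt(k)` for a k-molecule spot — the scaling photon shot
  noise actually follows, since each molecule's photons are independent.
  (Noise proportional to `k * u` would make the 4th mixture component
  unresolvable in principle, not just in practice: its density maximum
  disappears under the 3rd component's tail.)

What the generator does **not** emulate — and what passing tests therefore
do not certify on real data: segmentation errors (masks are ground truth
here), agar autofluorescence gradients, photobleaching, z-structure and
focus drift, spot motion during exposure, and day-to-day extrinsic
variability. The last point matters for distribution widths: real activity
distributions are substantially broader than the Poisson-based generator
produces (super-Poissonian transcription plus extrinsic noise), so the
generator's population SD should not be read as a prediction of measured
SDs, even though means, zero fractions and loss fractions transfer.

## Validation problem sizes

The shipped tests use: 100-spot fit oracles (noise-free and Poisson),
500-spot calibration samples, a 105-cell counting image (true counts 0–20)
with a 400-cell calibration image set, a 300-cell two-channel pipeline run,
copy-number populations of 2000 cells for 15–40 generations, 13 x 13
fitting grids, and 10^4–10^5-draw sampler checks. These sizes put sampling
error comfortably below the tolerances being asserted while keeping the
whole suite at a few minutes on one CPU.

## Numerical notes

* Partition weights and replication probabilities are computed in log
  space with +/-700 exponent guards; the partition pmf is exact for all
  `x` and `a` tested (to 1e-12 against direct enumeration).
* `replicate_pmf()` truncates its support where the remaining survival
  probability falls below 1e-15; the sampler carries a hard cap at
  `100 * N0 + 1000`, unreachable in practice.
* The simulator cores (division loop, telegraph SSA) are C++ (Rcpp) using
  R's RNG, so every run is bit-reproducible given a seed and seeds behave
  identically from R and C++ paths.
* Seeded functions snapshot and restore the caller's RNG state; derived
  child seeds use double arithmetic to stay below 2^31.
* Levenberg–Marquardt fits run with tight tolerances (`ftol`, `ptol`
  1e-14 for Hill fits) and bounded parameters; bounds hits are treated as
  rejections for spot fits rather than silently accepted.

## Limitations

* Counting accuracy degrades above ~10 molecules per cell as clusters
  crowd and merge; mean absolute error stays ~<= 1 up to 10 but rises for
  denser cells. Higher expression needs either dimmer labels or
  volume-based rather than spot-based quantification.
* Self-calibration needs several hundred spots dominated by 1–4-molecule
  clusters; high-copy samples should be counted with a unit calibrated on
  a dedicated low-copy sample (supply `unit_intensity` to
  `run_pipeline()`).
* The fallback Otsu segmenter is plumbing for exploration only; real
  analyses should bring masks from a dedicated segmentation tool.
* The partition and replication kernels are the simplest families with the
  right limits; mechanistic replication control (iterons, RNA I/II) and
  active partitioning systems are out of scope, though both kernels are
  single functions that can be replaced.
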