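---
title: "Quantifying dystrophic muscle with T2 mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dystrophic muscle with T2 mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myorelax)
```

## The measurement model

A spin echo acquired at long repetition time (TR = 2000 ms, treated as
much longer than muscle T1, so longitudinal weighting is neglected) decays
mono-exponentially with echo time:

$$S(TE) = \rho \, e^{-TE/T_2}.$$

Two echoes therefore determine $T_2$ in closed form,

$$T_2 = \frac{TE_2 - TE_1}{\ln\!\left(SI_{1}/SI_{2}\right)},$$

which at $TE = 14/40$ ms has the fixed numerator of 26 ms. `two_echo_t2()`
implements exactly this; it is an identity, not a fit, so on noise-free
simulated data the round trip through `simulate_dual_echo()` and
`make_t2_map()` recovers the ground-truth T2 to floating-point precision —
the property the acceptance suite checks at each of the study group means
(24.83, 27.10, 23.92 ms whole-compartment; 21.20, 23.91 ms muscle-only).

A pixel is *estimable* only when $SI_1 > SI_2 > 0$. Noise can violate this
(especially near the Rician floor), and such pixels are flagged invalid and
**excluded** from ROI statistics rather than clamped: clamping to a bound
would bias compartment means, and exclusion keeps the estimator's domain
honest. ROI summaries pool pixels across the selected slices (the analysis
unit is the pixel, not the slice), reported as mean ± sample SD; the SD of
a single-pixel ROI is reported as 0.

### Middle-slice selection

Muscle T2 is summarized over the middle slices of the stack — 6 to 8 in
the emulated protocol; this package defaults to k = 7, the midpoint, and
makes k an argument. `select_middle_slices(n, k)` centres the window and,
when parity forces a choice, shifts toward the lower index. The rule is
deterministic so reruns are identical.

## Hyperintensity classification

Inflammation and edema raise muscle T2; fibrotic collagen lowers it. The
discrimination step classifies a pixel as hyperintense when its T2
**strictly** exceeds a cutoff, by default the fixed 27 ms value (control
mean + 2 SD). A control-derived rule, `threshold_from_controls()`, pools
pixel values from all control animals and sets mean + k·SD (k = 2 default)
— pooled rather than per-animal because a single study-wide cutoff is
applied. Notably, the printed whole-compartment control statistics
(24.83 ± 0.66 ms) give 26.15 ms, not 27 ms: ROI-level SDs understate
pixel-level spread, so the cutoff was evidently derived from pixel-level
SD. The package does not guess that population; the default stays at the
printed constant, and the control-derived mode is available when pixel
data exist.

`muscle_only_t2()` reports the post-exclusion mean together with the
fraction excluded — on noise-free phantoms the latter recovers the
simulated lesion fraction exactly (to voxel-count rounding); under noise
the recovery is within binomial sampling error.

## The synthetic phantom

No imaging data are deposited for the emulated study, so the package
carries a generator whose defaults *are* the study conditions:

* dual-echo SE at TE 14/40 ms, TR 2000 ms, 128 × 256 in-plane matrix,
  1 mm slices (10 by default), 15 mm in-plane FOV (mid-range of the
  stated 10–20 mm);
* Rician noise anchored at muscle-ROI SNR 33:1 at TE 14 ms — complex
  Gaussian noise of SD σ = mean muscle signal / SNR added per quadrature
  before magnitude, so background follows the Rayleigh distribution and
  magnitude images have the characteristic positive noise floor;
* geometry: stacked ellipses for anterior and posterior compartments plus
  a small bone — schematic shapes, since only label bookkeeping and voxel
  arithmetic carry information; overlapping or out-of-FOV compartments are
  rejected;
* lesions: a requested fraction of muscle voxels reassigned to a
  hyperintense tissue (default T2 40 ms, safely above the 27 ms cutoff),
  scattered independently by default; an optional in-plane clustering
  radius grows blob-like lesions instead. The paper gives no lesion
  geometry, so scattering is the assumption-free default.
* 29-echo STEAM decays (5–200 ms, TR 9000 ms, TM 20 ms) as sums of
  exponentials with complex Gaussian noise; the STEAM voxel is treated as
  a single well-mixed signal source (its printed size, presumed mm, does
  not enter the computation).

Cohort generation (`simulate_cohort()`, `study_cohorts()`) draws
per-animal scalars from each group's stated normal distributions,
truncated at 0: weights 18.05 ± 2.91 / 10.11 ± 3.39 / 10.35 ± 1.85 g and
lesion-free muscle T2 24.83 ± 0.66 / 21.20 ± 0.68 / 23.91 ± 0.84 ms for
WT / DyW / DyW-Los at n = 6/8/4. Dystrophic lesion fractions are *derived*
rather than invented: on a per-pixel map a compartment with lesion
fraction $f$ has mean $(1-f)\,T_{2,\text{muscle}} + f\,T_{2,\text{lesion}}$,
so the reported whole-compartment/muscle-only pairs imply
$f = 0.314$ (DyW) and $f \approx 0.0006$ (DyW-Los) at lesion T2 40 ms.
Mac-1 means (3.915 / 19.33 / 8.585 cells per 40× field) are reported
without dispersion, and qPCR Ct levels are not reported numerically at
all; the generator fixes field-count SDs at 1.2 / 4.0 / 2.5 and Ct
parameters (18S at 9.5 ± 0.3 throughout; COL1a 26.0 / 23.0 / 25.8 ± 0.4,
i.e. ~8-fold dystrophic overexpression rescued by treatment) as one-time
realistic choices. Every stochastic call threads an explicit seed; equal
seeds give bit-identical output.

What the phantom does **not** emulate: k-space acquisition, coil and B1
inhomogeneity, slice-profile and stimulated-echo contamination, partial
volume at tissue boundaries, fat signal, and spatially correlated lesion
texture. Passing tests therefore demonstrate the *analysis* is correct
and self-consistent under the stated signal model — not that the scanner
chain is modelled.

## Water relaxometry

`cpca_extract()` reduces repeated complex acquisitions (samples × TEs) to
one decay by projecting each echo's data onto the first left singular
vector of the complex matrix — for rank-1 data this is exact, and a global
phase on the input cancels. The projection is phase-aligned to make the
earliest echo positive real and returned as non-negative amplitudes; the
first component's energy fraction is attached for quality control.

`fit_monoexp()` minimises the residual sum of squares of
$S_0 e^{-TE/T_2}$ with L-BFGS-B, initialised from the log-ratio of the
first and last echoes, bounded to $T_2 \in (1, 2000)$ ms with a 500
iteration cap. Non-convergence (including a fit pinned at the T2 bounds,
as happens for non-decaying input) returns the best iterate flagged
`converged = FALSE` instead of erroring; a terminating line search at a
numerically zero residual counts as converged. Fits operate on
cPCA-extracted amplitudes when quadrature data exist, else on magnitudes;
no Rician bias correction is applied to magnitude fits — at the SNRs
simulated here the bias is small, but it is a real caveat for low-SNR
magnitude data.

`fit_nnls()` inverts the decay onto a T2 grid under non-negativity
(Lawson–Hanson via `pracma::lsqnonneg`), defaulting to 40 log-spaced nodes
on [5, 500] ms with no regularisation (µ = 0; a Tikhonov term is available
but the emulated method is plain NNLS). `spectrum_summary()` reports the
amplitude-weighted geometric-mean T2, the number of contiguous positive
runs (amplitude > 1e-12 of the maximum) as resolved components, and their
amplitude fractions. One numerical subtlety: a continuous-T2
mono-exponential fit can beat NNLS by a discretisation margin when the
optimum falls between grid nodes, so the model-nesting comparison
(NNLS RSS ≤ mono-exponential RSS) is exact only on grids containing the
mono-exponential optimum — the test suite constructs exactly that grid.
Group-level water T2 values are not printed in the emulated study, so
relaxometry is validated by property (exact-model recovery, two-component
resolution within 5%, noise robustness), not by value.

## Volumetry

Compartment volumes are voxel counts times voxel volume — voxel-centre
counting, matching what a manual outline yields, with no sub-voxel
weighting. Lesion voxels carved out of a compartment are counted toward it
through the code table's parent mapping (recorded when all lesions lie in
one compartment; a single lesion code cannot track two parents), since
published compartment volumes are whole-compartment. Cross-sectional area
uses the in-plane pixel area at one axial slice, defaulting to the middle
slice (the study does not state which slice its CSA used). At the
acquisition-scale grids (128–256 in-plane) discretisation error of a
smooth elliptical region is below 1%; at coarse test grids (64²) it can
reach ~1.5%.

## Statistics

`anova_tukey()` is classical one-way ANOVA followed by Tukey's HSD on all
pairs, in the Tukey-Kramer form valid for the study's unequal group sizes
(6/8/4), at α = 0.05. Exactly-constant groups are detected explicitly
(zero within-group variance leaves F as 0/0 floating dust otherwise) and
flagged `degenerate` with F = 0 when group means also coincide. ΔΔCt fold
changes use the 18S endogenous control convention, averaging technical
replicates before differencing; Mac-1 scores average three 40× field
counts per sample. `build_report()` merges per-animal results, computes
group summaries and comparisons with stable ordering (byte-identical
reruns), and `write_report()` rounds millisecond quantities to 2 decimals
at serialisation only.

The study reports significance bands rather than exact p-values, so the
statistical layer is validated against a from-scratch sum-of-squares
oracle (agreement to 1e-10) and by a detection-rate property: at the
published group means, SDs and sample sizes, the WT-vs-DyW and
DyW-vs-treated contrasts are flagged in well over 90% of simulated
cohorts.

## Problem sizes and determinism

All phantom computations are vectorised; the test suite runs on grids of
32²–256² voxels and cohorts up to n = 10⁴ scalar animals, sizes chosen so
the full suite completes in well under a minute while keeping sampling
error far below the tolerances tested. Every stochastic path accepts a
seed; `NULL` uses (and advances) the session RNG, while an explicit seed
is applied locally and the caller's RNG state restored.

## Known limitations

* Two echoes cannot separate intra-pixel compartments; a pixel mixing
  muscle and edema reports a single intermediate T2 (the imaging-side
  NNLS analysis would need more echoes).
* Magnitude-domain fits carry Rician bias at low SNR (no correction
  applied).
* The hyperintensity rule is purely per-pixel; no spatial regularisation
  or connected-component analysis.
* The phantom's statistical realism is limited to the stated group
  distributions; it cannot stand in for scanner-specific artefacts.
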