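---
title: "isoquantr: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isoquantr: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the quantitative model implemented by isoquantr, the
meaning and defaults of every user-facing parameter, the assumptions of the
synthetic-data generator, and the numerical choices that affect results. Code
chunks are illustrative and not evaluated when the vignette is built.

## 1. Pipeline overview

For each run, quantitation proceeds in a fixed order:

1. **Identification filtering** — PSMs and protein groups are gated at a
   false-discovery-rate threshold (default 1%).
2. **Reporter-ion extraction** — one intensity per channel per MS2 scan.
3. **Isotope-impurity correction** — per-scan inversion of the reagent
   mixing matrix.
4. **Signal-to-interference (S2I) estimation and ratio-compression
   correction (RCC)** — optional, per PSM.
5. **Reporter normalization** — optional channel-median equalization.
6. **PSM → peptide → protein roll-up** under a chosen pair of ratio kernels.
7. **Ratio-level normalization** — optional median centering of peptide
   and/or protein ratio sets.

`quantify()` runs one configuration; `sweep_quant()` runs a set of them and
scores each against a ground truth.

## 2. Identification filtering

When PSMs carry a `q_value`, records with `q_value <= threshold` are kept.
Otherwise the filter uses the model-based FDR implied by posterior
probabilities: sort by probability descending and keep the longest prefix
whose running mean of $1 - p$ stays at or below the threshold. A tolerance of
$10^{-12}$ is added to the comparison because $1 - p$ is not exact in floating
point (e.g. `1 - 0.99 > 0.01` in double precision). Protein groups are
filtered by the same probability rule, and PSMs whose every mapped protein was
removed are dropped.

## 3. Reporter extraction

For each channel the intensity of the *most intense* peak within
`reporter_tol` (default 0.002 Th) of the reporter m/z is taken; the
most-intense rule is robust to small calibration offsets, unlike
nearest-m/z matching. Extraction refuses to run if the window half-width
exceeds half the minimum channel spacing of the plex (the windows would
overlap), which matters for the 6.32 mDa C/N isotopologue doublets of
10-plex reagents.

## 4. Isotope-impurity correction

A reagent certificate of analysis lists, per channel, the percentage of
signal appearing at −2, −1, +1 and +2 Da. isoquantr assembles these into a
column-stochastic-up-to-leakage matrix $M$ where $M_{ij}$ is the fraction of
channel $j$'s true signal observed in channel $i$; leakage to masses outside
the plex is dropped from the matrix but retained in the diagonal deficit
(column sums may be < 1). Placement is positional within the plex's channel
order. The correction solves $Mx = \text{observed}$ exactly via `solve()` and
clamps negative components to zero in a single pass; negatives arise only
when a channel's observed signal is below the leakage it receives, i.e. its
true signal is indistinguishable from zero.

```{r}
M <- load_correction_matrix(system.file(
  "extdata", "example_impurity_tmt6_synthetic.csv", package = "isoquantr"))
corrected <- correct_impurities(intensities, M)
```

## 5. S2I and ratio-compression correction

Co-isolated precursors contribute reporter signal that is, on average,
unregulated, compressing every measured ratio toward 1. The
signal-to-interference of a PSM is estimated from MS1:

$$\mathrm{S2I} = \frac{\sum_{k=0}^{k_\max} I(\text{precursor isotopologue } k)}
                     {\sum I(\text{all peaks in the isolation window})}$$

with `k_max = 3` isotope peaks spaced $1.00335/z$ apart and matched within
`match_ppm = 10` ppm. The ratio is computed in the MS1 scans immediately
before and after the MS2 scan and linearly interpolated at the MS2 retention
time (`interpolate = TRUE`); if the isolation window contains no peaks the
S2I defaults to 1 with a warning (no evidence of interference).

RCC then treats the interfering signal as split evenly across the $n$
channels:

$$x_j^{\text{corrected}} = \max\!\left(0,\;
   x_j - \frac{(1-\mathrm{S2I})\sum_k x_k}{n}\right)$$

The corrected channel sum equals $\mathrm{S2I} \cdot \sum_k x_k$ whenever no
channel clamps. The even-split assumption is the standard first-order model;
it is exact when interference is an aggregate of many unregulated peptides
and biased when a single strongly regulated contaminant dominates the window.

## 6. Ratio kernels and the combination lattice

Given per-PSM ratios $v_i = x_{\text{num},i} / x_{\text{den},i}$ and weights
$w_i$, the kernels are:

| Kernel | Definition | Level |
|---|---|---|
| `LinearRegression` | slope through the origin, $\sum x y / \sum x^2$, of numerator on denominator intensities | protein (PSM intensities) |
| `SumPsmIntensity` | $\sum x_{\text{num}} / \sum x_{\text{den}}$ | protein (PSM intensities) |
| `MedianPsmRatio` | median of $v_i$ | peptide or protein |
| `WeightedPsmRatio` | $\sum w_i v_i / \sum w_i$ | peptide or protein |
| `TrimmedMeanPsmRatio` | mean after trimming $\lfloor 0.2 n \rfloor$ values per side | peptide or protein |
| `MedianPepRatio` / `WeightedPepRatio` | median / weighted mean of peptide ratios | protein (peptide ratios) |

PSM weights are the numerator+denominator intensity sum (`weight_scheme =
"pair"`, default) or the all-channel sum (`"all"`); a peptide's weight is the
median of its PSM weights. PSMs at different charge states of the same
(modified) sequence share a `peptide_key` and are merged at the peptide level.

Normalization strategies are `none`, `reporter` (channel-median
equalization of the corrected intensity table; zeros are excluded from the
medians and an all-zero channel is an error), `peptide` and `protein`
(median-center the respective ratio set so its median is 1), and the three
combinations `reporter+peptide`, `reporter+protein`,
`reporter+peptide+protein`. All are idempotent.

The full lattice is 4 peptide kernels × 6 protein kernels × 7 normalizations
× RCC on/off = **336 combinations**:

```{r}
enumerate_combinations()                  # 336 rows
enumerate_combinations("none")            # 48
enumerate_combinations("none", peptide = "MedianPsmRatio")  # 12
```

Two exact invariances mean the 336 cells do not all yield distinct protein
tables: the peptide kernel is invisible to protein kernels that consume PSMs
directly, and a pure channel rescaling (reporter normalization) cancels in
any downstream ratio-level median centering. The lattice is enumerated in
full regardless, because the cells are distinct *configurations* and the
invariances hold only exactly, not after clamping or missing-data filters.

## 7. Evaluation metrics

Against a truth table of ideal ratios per protein and pair:

- **AUCCD** — area under the curve of coverage (fraction of proteins whose
  relative deviation $|x/y - 1|$ is below $d$) versus $d \in [0, 1]$,
  computed on a fixed grid; 1 is perfect.
- **ARE** — mean of $|x - y| / y$; `are_std` and `are_bg` restrict to
  proteins labeled `standard` / `background`.
- **RMSE** — root mean squared error of the ratios.
- **Jaccard** — similarity of differential-protein lists selected by a
  symmetric fold-change cutoff (`select_differential()`).

## 8. The synthetic generator

`synth_spec()` fixes the study conditions; `generate_dataset()` realizes
them. Defaults:

- **Balanced spike-in panel.** Three standard sub-classes carry the ratio
  pattern (1, 2, 4) cyclically shifted across channels, plus a flat
  background; class fractions are (0.1, 0.1, 0.1, 0.7) and the sub-classes
  share the truth label `standard`. Because the abundance-weighted channel
  totals are equal by construction, the equal-loading assumption behind
  reporter normalization holds exactly in expectation — the generator's
  defaults satisfy the model the pipeline assumes, as a validation dataset
  should.
- **Noise model.** Per-peak multiplicative log-normal noise with coefficient
  of variation `cv_noise` (default 0.1). A fraction `noise_correlation`
  (default 0.8) of the log-noise variance is shared by all channels of a
  scan, reflecting that reporter channels of one MS2 spectrum share
  injection, isolation and fragmentation; the per-channel CV is preserved.
  Scan-common noise cancels in ratios, so only the uncorrelated remainder
  propagates.
- **Intensity scale.** Protein base intensities are log-normal around
  `base_intensity` (1e5) with `base_log_sd = 0.5`.
- **Interference.** `interference_fraction` $f$ adds flat co-isolation
  signal so that every PSM's true S2I is exactly $1 - f$; the generator
  records this in the truth table, which lets tests verify `compute_s2i()`
  to machine precision.
- **Impurities.** An optional impurity matrix is folded in by forward
  multiplication, so `correct_impurities()` must recover the clean values
  exactly.
- Class sizes use largest-remainder rounding (exact counts), and all
  randomness derives from the spec's `seed`.

With `cv_noise = 0`, `interference_fraction = 0` and no impurity matrix, the
non-reporter strategies recover every true ratio exactly (to floating-point),
which the test suite asserts.

`compression_curve()` reuses the generator to trace measured vs. corrected
ratios as a function of $f$, and `write_fixture_files()` materializes a
dataset as mzML + TSV + CSV for end-to-end and CLI tests.

## 9. Numerical and design choices

- Ratios are undefined (NA) when the denominator information is zero;
  kernels propagate NA rather than fabricating values, and proteins without
  a defined ratio are omitted.
- Regression is through the origin: the model is proportional abundance, and
  an intercept would absorb exactly the compression bias RCC removes.
- Reporter extraction default of 0.002 Th assumes high-resolution MS2; widen
  it only for plexes whose channel spacing allows.
- `unique_peptides_only = TRUE` (default) discards PSMs mapping to more than
  one protein accession before roll-up.
- `require_complete_channels` optionally drops PSMs with any zero channel in
  the pair set.
- Median-based post-conditions are tested to $10^{-9}$ (intensity scale) and
  $10^{-12}$ (ratio scale).

## 10. Limitations

- S2I needs MS1 scans around each MS2 and resolvable precursor isotope
  clusters; for MS3-based acquisition the compression mechanism differs and
  RCC as implemented does not apply.
- The even-split interference model under-corrects windows dominated by one
  regulated contaminant.
- Impurity correction is only as good as the certificate-of-analysis values;
  the bundled CSV matrices are synthetic examples, not real lots.
- The generator's balanced panel is a validation design, not a model of any
  particular biological experiment; conclusions about kernel rankings on
  real data require real benchmarks.
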