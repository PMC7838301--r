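# isoquantr

Isobaric-labeling (iTRAQ/TMT) protein quantitation in R, with explicit
correction of the two systematic errors that dominate reporter-ion data:
**isotope impurities** of the labeling reagents and **ratio compression**
caused by co-isolated precursors.

## What it does

In an isobaric experiment every sample is labeled with a tag of identical
mass; after fragmentation each tag releases a low-mass reporter ion whose
intensity encodes the sample's contribution. Protein abundance ratios are
therefore read off the MS2 reporter region. Two effects bias those readings:

1. **Isotope impurities.** Each reagent lot leaks a known percentage of its
   signal into the neighboring channels (−2, −1, +1, +2 Da). isoquantr models
   this as a linear mixing system `M x = observed` and inverts it per scan
   (`load_correction_matrix()`, `correct_impurities()`).
2. **Ratio compression.** Precursors co-isolated in the same MS2 window
   contribute reporter signal at (on average) 1:1, pulling every measured
   ratio toward 1. isoquantr estimates the **signal-to-interference (S2I)**
   of each PSM from the precursor's isotope cluster in the flanking MS1 scans
   (linear interpolation in retention time), assumes the interfering signal is
   split evenly across channels, and subtracts it
   (`compute_s2i()`, `apply_rcc()`).

On top of the corrected intensities, the package rolls PSM-level ratios up to
peptides and proteins under a configurable lattice of

- 4 peptide-level ratio kernels × 6 protein-level kernels
  (linear regression through the origin, intensity sums, medians, weighted
  means, 20% trimmed means — at PSM or peptide level),
- 7 normalization strategies (reporter-channel median equalization,
  peptide-ratio and protein-ratio median centering, and their combinations),
- ratio-compression correction on or off,

for **336 combinations in total** (`enumerate_combinations()`,
`sweep_quant()`). Accuracy of each combination against a known ground truth is
scored with AUCCD (area under the coverage-vs-deviation curve), average
relative error (overall, standard-only, background-only), RMSE, and the
Jaccard similarity of differential-protein lists (`evaluate_ratios()`).

A first-class synthetic-data generator (`synth_spec()`,
`generate_dataset()`, `write_fixture_files()`) produces complete datasets —
mzML spectra, PSM/protein tables, impurity matrices, and the ground truth —
with controlled ratios, log-normal noise, impurity mixing, and co-isolation
interference, so every correction can be validated against values that are
known exactly.

Everything is tidyverse-native: tibbles in and out, `tidy()`/`glance()`
methods, and `autoplot()` for results.

## Worked example

Generate a synthetic TMT-6 dataset with 30% co-isolation interference,
quantify it with one combination, and score it against the ground truth:

```r
library(isoquantr)

spec <- synth_spec(n_proteins = 20, peptides_per_protein = c(2, 4),
                   psms_per_peptide = c(1, 3), cv_noise = 0.1,
                   interference_fraction = 0.3, seed = 7)
ds <- generate_dataset(spec)
qd <- as_quant_dataset(ds)

res <- quantify(qd, pairs = c("128/126", "131/126"),
                protein_kernel = "WeightedPepRatio",
                normalization = "protein", rcc = TRUE)
res
#> <quant_result> MedianPsmRatio~WeightedPepRatio~protein~enRCC
#>   PSMs kept: 135 | proteins quantified: 20
#>   pairs: 128/126, 131/126

head(res$proteins)
#> # A tibble: 6 × 5
#>   accession pair    value n_psms n_peptides
#>   <chr>     <chr>   <dbl>  <int>      <int>
#> 1 PROT0001  128/126 4.04       3          3
#> 2 PROT0001  131/126 4.07       3          3
#> 3 PROT0002  128/126 3.89       4          4
#> 4 PROT0002  131/126 4.04       4          4
#> 5 PROT0003  128/126 0.512      3          3
#> 6 PROT0003  131/126 0.506      3          3

truth <- ground_truth_ratios(ds$truth, c("128/126", "131/126"))
evaluate_ratios(res$proteins, truth)
#> # A tibble: 1 × 6
#>   auccd    are are_std are_bg   rmse n_ratios
#>   <dbl>  <dbl>   <dbl>  <dbl>  <dbl>    <int>
#> 1 0.979 0.0208  0.0218 0.0203 0.0321       40
```

Sweeping a slice of the lattice shows the effect of the ratio-compression
correction directly: with 30% interference, every uncorrected combination
(`disRCC`) sits near 10% average relative error, and enabling the correction
(`enRCC`) brings it down to ~2%:

```r
combos <- enumerate_combinations("none", peptide = "MedianPsmRatio")
m <- sweep_quant(qd, c("128/126", "131/126"), combos, truth = truth)
dplyr::select(m, combination_id, are, auccd, rmse)
#> # A tibble: 12 × 4
#>    combination_id                                    are auccd   rmse
#>    <chr>                                           <dbl> <dbl>  <dbl>
#>  1 MedianPsmRatio~SumPsmIntensity~none~disRCC     0.102  0.897 0.476
#>  2 MedianPsmRatio~SumPsmIntensity~none~enRCC      0.0189 0.981 0.0278
#>  3 MedianPsmRatio~MedianPsmRatio~none~disRCC      0.103  0.898 0.479
#>  4 MedianPsmRatio~MedianPsmRatio~none~enRCC       0.0200 0.98  0.0325
#>  5 MedianPsmRatio~WeightedPsmRatio~none~disRCC    0.102  0.898 0.476
#>  6 MedianPsmRatio~WeightedPsmRatio~none~enRCC     0.0191 0.981 0.0284
#>  7 MedianPsmRatio~TrimmedMeanPsmRatio~none~disRCC 0.101  0.899 0.477
#>  8 MedianPsmRatio~TrimmedMeanPsmRatio~none~enRCC  0.0164 0.983 0.0269
#>  9 MedianPsmRatio~MedianPepRatio~none~disRCC      0.106  0.894 0.484
#> 10 MedianPsmRatio~MedianPepRatio~none~enRCC       0.0235 0.976 0.0329
#> 11 MedianPsmRatio~WeightedPepRatio~none~disRCC    0.104  0.896 0.480
#> 12 MedianPsmRatio~WeightedPepRatio~none~enRCC     0.0197 0.980 0.0290
```

`autoplot(res)` draws the per-protein ratio distributions, and
`plot_compression_curve(compression_curve(...))` visualizes measured vs.
corrected ratios as a function of the interference fraction.

## Command line

A thin CLI wraps the same engine (installed under `inst/cli/`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "isoquant.R", package = "isoquantr"))')

Rscript "$CLI" synth --spec spec.yaml --out fixtures/
Rscript "$CLI" quant --config run.yaml --rcc-enabled true
Rscript "$CLI" sweep --config run.yaml --normalizations none,reporter
Rscript "$CLI" eval  --proteins out/proteins.tsv --truth fixtures/truth.tsv \
                     --pairs 128/126,131/126
```

The YAML config names the input files (`spectra`, `psms`, optional
`proteins`, `matrix_csv`, `truth`), the `plex`, the ratio `pairs`, and any
combination parameters; command-line flags override the file.

## Limitations

- S2I estimation assumes centroided spectra with resolvable precursor isotope
  clusters and MS1 scans flanking each MS2 scan.
- The interference model assumes co-isolated signal is, on average, unchanged
  across channels; strongly regulated contaminants violate this.
- Impurity correction requires the reagent lot's certificate-of-analysis
  percentages; the bundled matrices are synthetic examples.

See the vignette (`vignettes/isoquantr-methods.Rmd`) for the full model,
parameter meanings, generator assumptions, and numerical choices.
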