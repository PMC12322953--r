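# cellfrac

Reference-based immune cell-type deconvolution for bulk proteomics.

Bulk proteomes of blood, tissue or tumour samples are weighted averages of
the proteomes of the cell types they contain. **cellfrac** estimates those
weights: given a bulk protein-intensity matrix and a reference of pure
cell-type proteomes, it models each bulk sample $m$ as a non-negative
weighted sum of reference profiles,

$$ m = S f + e, \qquad f_c \ge 0, \;\; \textstyle\sum_c f_c = 1, $$

where $S$ is a marker-protein × cell-type *signature matrix* built from the
reference and $f$ the vector of cell-type fractions. It is aimed at
proteomics researchers who want transcriptomics-style immune deconvolution
(CIBERSORT/EPIC-style) to work on MS intensity tables — which means dealing
with protein groups, duplicate gene symbols, intensity-dependent missing
values, and normalization choices that can quietly destroy the linear
mixing signal the model depends on.

The toolkit covers the full loop:

* **Preprocessing** — protein-group collapse, duplicate resolution
  (slice/merge), missing-value imputation (minimum-value, kNN, random
  forest), quantile / cyclic-loess normalization, TPM-like total-intensity
  scaling (`preprocess_pipeline()`).
* **Signature construction** — Welch-t + Benjamini–Hochberg marker
  ranking, then a sweep over markers-per-type G ∈ [200, 400] that picks the
  signature with the smallest 2-norm condition number
  (`build_signature()`); plus expression/fold-change marker selection for
  marker-based scoring (`select_fold_markers()`).
* **Deconvolution** — a ν-SVR engine (CIBERSORT-style core), a constrained
  least-squares engine with optional unassigned "other" fraction and
  protein-content correction (EPIC-style core), and a marker-score
  baseline (`deconvolute()`).
* **Simulation & evaluation** — pseudobulk mixtures with known fractions
  from pure replicates (`simulate_mixtures()`), per-cell-type Pearson/RMSE
  scoring (`evaluate_against_truth()`), pure-sample purity tables, and a
  fully synthetic reference-cohort generator with MNAR missingness for
  testing without any downloads (`generate_reference_cohort()`).

Everything is tidyverse-native: functions take and return tibbles, results
have `tidy()`/`glance()` methods and `autoplot()` figures, and calls chain
with the pipe.

## Worked example

A complete synthetic round trip — generate a labelled pure-cell cohort,
build a signature, simulate mixtures with known composition, deconvolute,
and score:

```r
library(cellfrac)

cfg <- synth_config(n_cell_types = 4, n_features = 400, markers_per_type = 40,
                    n_replicates = 4, seed = 1)
cohort <- generate_reference_cohort(cfg)
reference <- scale_to_total(cohort$expression)

sig <- build_signature(reference, cohort$groups,
                       signature_config(g_min = 20, g_max = 40))
sig
#> <cellfrac signature> 156 markers x 4 cell types | chosen G = 39 | condition number = 2.04

truth <- sample_fractions(unique(cohort$groups$cell_type), 50, seed = 2)
mix <- simulate_mixtures(reference, cohort$groups, truth, seed = 3)

fit <- deconvolute(mix$bulk, sig, method = "nusvr", seed = 4)
ev <- evaluate_against_truth(fit, mix$truth)
ev
#> <cellfrac evaluation> 50 mixtures | mean Pearson = 0.994 | mean RMSE = 0.0215
#> # A tibble: 4 × 3
#>   cell_type pearson   rmse
#>   <chr>       <dbl>  <dbl>
#> 1 typeA       0.996 0.0153
#> 2 typeB       0.993 0.0228
#> 3 typeC       0.996 0.0182
#> 4 typeD       0.991 0.0297
```

The signature print shows the marker count, the G chosen by the
condition-number sweep and the condition number itself (lower = better
conditioned regression). The evaluation reports, per cell type, the
Pearson correlation between estimated and true fractions across the 50
mixtures and the RMSE on the fraction scale — here fractions are recovered
to about ±0.02.

Real data enters through `read_protein_groups()` (DIA-NN / MaxQuant-style
protein-group TSVs) followed by `preprocess_pipeline()`; a thin
command-line wrapper over the same functions lives in `inst/cli/deconv.R`
(subcommands `preprocess`, `signature`, `simulate`, `run`, `evaluate`,
`synth`, `bench`).

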