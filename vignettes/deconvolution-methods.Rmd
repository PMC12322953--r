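---
title: "Methods: reference-based deconvolution of bulk proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-based deconvolution of bulk proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cellfrac)
```

## The model

cellfrac estimates the cell-type composition of a bulk proteome by partial,
reference-based deconvolution. The bulk intensity vector $m$ (one entry per
protein, linear scale) is modelled as a weighted sum of pure cell-type
profiles:

$$ m = S f + e, \qquad f_c \ge 0, $$

where $S$ is the *signature matrix* (marker proteins × cell types, mean
linear intensities of pure reference populations), $f$ the vector of
cell-type fractions, and $e$ a residual. The model is linear on the
**linear intensity scale**: mixing cells mixes protein mass additively, so
deconvolution is always performed on un-logged intensities. Everything the
package does — preprocessing, signature construction, simulation,
evaluation — exists to make this one regression well-posed for
mass-spectrometry (MS) data, which differs from the transcriptomics setting
in three ways: ambiguous protein-group identifiers, abundant
intensity-dependent missing values, and a smaller feature space.

## Preprocessing

MS search engines report *protein groups* (sets of accessions
indistinguishable from the observed peptides). `collapse_protein_groups()`
reduces each group to its first listed gene symbol (or first accession when
no symbol exists). The resulting table can contain duplicate identifiers;
`dedupe_features()` resolves them either by keeping the occurrence with the
highest median observed intensity (`"slice"`) or by element-wise summation
(`"merge"`, missing treated as absent). Both are legitimate; on simulated
data the difference is small, so `"slice"` is the default for being
conservative with respect to quantification artifacts.

Missing values are imputed before any transform because none of the
engines tolerate gaps. Three imputers are provided (`impute_missing()`):

* **minimum value** (default): every gap becomes the minimum observed value
  of the matrix (`min_scope = "sample"` restricts to the sample). MS
  missingness is predominantly left-censoring — a gap means "below
  detection" — so a conservative low fill is the assumption-consistent
  choice.
* **kNN**: feature-wise k nearest neighbours (Euclidean distance on jointly
  observed samples, `k = 10`), gap filled with the neighbours' mean in that
  sample.
* **RF**: missForest-style iterative random-forest regression per
  feature-with-gaps (mean-initialized, trees via ranger, 100 trees per
  feature by default), sweeping until the sum of squared changes in the
  imputed values increases, or at most 10 sweeps.

Normalization (`normalize_intensities()`) runs on log2 values and is
exponentiated back, delegating to the limma implementations: quantile
normalization (rank ties averaged) and pairwise cyclic loess (span 0.7,
3 iterations by default). Zeros are replaced by half the smallest positive
value before the log transform; the factor is configurable
(`zero_pseudo_factor`) because no principled pseudo-count exists for MS
intensities. Note a consequence of normalizing on the log scale: after
quantile normalization the common column distribution is the *geometric*
mean of rank-matched values on the linear scale. Normalization is offered
mainly to quantify its effect — equalizing distributions across samples
whose compositions genuinely differ removes biological signal, and the
package's own experiments (below) show it degrades recovery.

Finally `scale_to_total()` rescales every sample to a common total
intensity (default $10^6$, the TPM-like convention), making bulk samples
and reference profiles commensurable.

The pipeline order is fixed: collapse → dedupe → impute → normalize →
scale. Imputation precedes normalization so the normalizer sees complete
columns; scaling comes last so the final totals are exact. The order is
logged on every `preprocess_pipeline()` run.

## Signature construction

`rank_markers()` scores every feature per cell type with a two-sided Welch
(unequal-variance) t-test of that type's replicates against all other
samples, on log2 intensities, with Benjamini–Hochberg correction applied
per cell type across features. Candidates must have q < 0.01 (default) and
positive log2 fold change, and are ranked by fold change. Welch + BH was
chosen over a moderated (empirical-Bayes) test to keep the statistical
contract simple and dependency-free; with the 3–4+ replicates typical of
reference proteome cohorts the difference is minor.

`build_signature()` then sweeps the number of markers per cell type,
$G \in [G_{\min}, G_{\max}]$ (defaults 200–400): for each $G$ it pools the
top-$G$ candidates of every type, forms the per-type mean linear profiles
restricted to that pool, and computes the 2-norm condition number (ratio of
extreme singular values) of the candidate matrix. The signature with the
smallest condition number wins (ties → smallest $G$). A low condition
number means the cell-type profiles are close to orthogonal and the
regression is well-posed. The condition number is computed on the raw
linear-scale signature without column standardization, matching the
classical builder. A cell type with fewer than $G_{\min}$ candidates
contributes all of them (with a warning); zero candidates is an error
naming the type.

`select_fold_markers()` implements the simpler marker rule used by
marker-scoring methods: mean intensity in the target type > 1000 and at
least 3-fold the reference level of the other types. "Relative to others"
is read strictly as the *maximum* other-type mean (a flag switches to the
mean of means); a zero reference level yields infinite fold change.

## Deconvolution engines

All engines first call `harmonize_features()`, which intersects bulk and
signature features by identifier and refuses to run below 50% signature
coverage (overridable) — with a sparse overlap the signature no longer
measures what it was optimized for.

**ν-SVR** (`deconvolute_nusvr()`), the CIBERSORT-style core: the signature
is z-scored by its global mean and standard deviation, each sample vector
by its own; a linear ν-support-vector regression (e1071, no scaling) of the
sample on the signature columns is fitted for ν ∈ {0.25, 0.5, 0.75}; the ν
minimizing the RMSE between the z-scored sample and its linear
reconstruction is kept; negative coefficients are clamped to zero and the
rest normalized to sum to one. The ε-insensitive loss makes this engine
robust to outlying features. Samples whose coefficients are all clamped (or
that have zero variance) are flagged, not silently replaced by a uniform
guess. Permutation p-values of the original algorithm are omitted — the
package's analyses never use them — while per-sample reconstruction RMSE
and Pearson r are retained.

**Constrained least squares** (`deconvolute_cls()`), the EPIC-style core:
minimizes $\lVert m - S f \rVert^2$ subject to $f \ge 0$, via quadprog.
With `allow_other = TRUE` the additional constraint $\sum_c f_c \le 1$ is
imposed and the remainder $1 - \sum_c f_c$ is reported as `other` — the
share of the sample not attributable to any modelled type. Otherwise the
non-negative solution is renormalized to the simplex. Per-feature variance
weights of the original EPIC are omitted (no analogous weight source exists
for proteomics); the unweighted objective keeps the estimator transparent,
and a weight hook can be added without interface change. An optional
protein-content correction divides each fraction by the type's protein
content per cell and renormalizes — larger cells contribute more protein
per cell, so intensity-scale fractions over-represent them; the correction
converts protein-mass fractions into cell-count fractions. When `other` is
present it is excluded from — and preserved by — that renormalization,
keeping fractions + other = 1.

**Marker score** (`deconvolute_marker_score()`), a deliberately simple
marker-based baseline: each marker is min–max scaled across samples, a cell
type's score is the mean of its markers' scaled values, and scores are
normalized per sample. It needs at least two samples to be informative; a
lone sample yields uniform fractions with a warning.

Numerical choices: the quadratic program is solved on a signature scaled by
its largest entry with a 1e-12 relative ridge to keep the Gram matrix
positive definite; fraction sums are exact to 1e-9 by construction;
negative round-off in the solver (> −1e-9) is clamped to zero; ties in the
G sweep and in `"slice"` deduplication resolve to the first occurrence, so
every routine is deterministic given its seed.

## Mixture simulation

`simulate_mixtures()` builds pseudobulk samples with known ground truth:
for each mixture one replicate per cell type is drawn uniformly at random
(with replacement across mixtures) and the bulk column is the
fraction-weighted element-wise sum of the chosen replicates — no
per-cell-type scaling factor and no added noise, because the replicates
already carry biological and technical noise. Fractions come from
`sample_fractions()`: the default `"dirichlet_uniform"` sampler draws
uniformly over the probability simplex (flat Dirichlet);
`"uniform_renormalized"` is kept for sensitivity checks. All cell types are
present in every mixture by default; sparse compositions can be produced by
passing custom fraction tables.

## Synthetic reference cohorts

`generate_reference_cohort()` defines the test distribution explicitly.
Each feature draws a baseline log2 mean from
Normal(`base_log2_mean` = 10, `feature_log2_sd` = 2) — shared across cell
types, giving the roughly four orders of magnitude of between-protein
dynamic range seen in real proteomes. Markers add `marker_log2_shift` = 4
(16-fold) in their own type. Replicate noise is Normal(0, `log2_sd` = 0.4)
on the log2 scale (~30% CV). Values are exponentiated to linear scale.
The between-feature spread matters: with a flat baseline all high-intensity
features would be markers, the M–A geometry of loess normalization would
degenerate, and normalization experiments would be meaningless.

`inject_missingness()` models left-censoring: an entry with log2 value
$x$ is deleted with probability
$r \cdot \mathrm{logistic}(-s\,(x - q_{10}))$, with plateau rate
$r = 0.4$ and steepness $s = 1$ by default, $q_{10}$ the matrix's 10th
log2 percentile. Under these defaults about 6–7% of entries go missing,
almost all in the bottom intensity decile.

What the generator does *not* emulate: correlated protein modules, shared
housekeeping programs between related cell types (spillover between CD4+
and CD8+ T cells, say), batch effects, peptide-level artifacts, or the
30–50% missingness of real DDA data. Passing the recovery tests therefore
shows the machinery is correct and well-conditioned, not that real immune
proteomes will deconvolute with r ≈ 0.99.

## Experiments and problem sizes

Three packaged experiments (`experiment_pipeline_recovery()`,
`experiment_imputation_comparison()`,
`experiment_normalization_comparison()`) run the full loop at desk scale;
the test suite and `scripts/acceptance.R` call them with seeds 1–3 and 100
mixtures per run. Cohort sizes are the package's own choices:

* pipeline recovery: 7 types × 120 markers/type × 1200 features ×
  4 replicates — large enough for 200–400-marker sweeps, small enough that
  300 ν-SVR fits complete in minutes;
* imputation comparison: 7 × 40 × 400 × 4 with MNAR injection — RF
  imputation fits one forest per gapped feature per sweep, which bounds
  this cohort;
* normalization comparison: 7 × 30 × 800 × 4 — background-dominated so the
  loess trend is anchored by non-differential proteins, as in real data.

Measured behaviour (recomputed by the acceptance script): exact recovery of
noiseless mixtures to ~1e-11; mean Pearson ≈ 0.99 and mean RMSE ≈ 0.01 for
both engines on the full synthetic pipeline; cyclic loess normalization
drops mean Pearson from ≈ 0.99 to ≈ 0.84.

## Known limitations

* Under the generator's missingness defaults the imputation methods are
  statistically indistinguishable (mean Pearson differences ~1e-4): the
  ~6% of censored entries sit in the bottom intensity decile, where
  linear-scale deconvolution carries almost no weight. The practical
  superiority of conservative minimum-value imputation on real MS data
  rests on far deeper missingness than this censoring model produces; only
  the comparison against zero-filling separates cleanly here. Treat the
  imputation experiment as machinery validation, not as evidence about
  real-data imputation.
* Cell types absent from the signature are not modelled except through the
  `other` fraction of the constrained-LS engine; complete deconvolution
  (estimating unknown profiles) is out of scope.
* The marker-score baseline is scale-free across samples and cannot be
  interpreted as absolute fractions when only one sample is scored.
* Fractions are protein-mass fractions unless a protein-content correction
  vector is supplied; no default content factors ship with the package.
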