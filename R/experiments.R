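# Desk-scale simulation experiments: each runs the full toolkit loop
# (synthetic cohort -> preprocessing variant -> signature -> pseudobulk
# mixtures -> deconvolution -> evaluation) under one seed. They are the
# package's reproducible analogs of the classic benchmark questions: can
# known fractions be recovered at all, and how do imputation and
# normalization choices change that.

#' End-to-end fraction recovery on a synthetic cohort
#'
#' Generates a pure-cell-type cohort, scales it to a common total intensity,
#' builds a condition-number-optimized signature (G swept 200-400, q < 0.01
#' by default), simulates `n_mixtures` pseudobulk mixtures with known
#' fractions, deconvolutes them, and scores the estimates.
#'
#' @param seed Integer seed driving cohort generation, mixture fractions,
#'   replicate choice and the solver.
#' @param method `"nusvr"`, `"cls"` or `"marker"`.
#' @param cfg A [synth_config()]; the default cohort has 7 cell types, 120
#'   markers per type among 1200 features and 4 replicates.
#' @param n_mixtures Number of simulated mixtures (default 100).
#' @param sig_cfg A [signature_config()].
#' @return One-row tibble: `method`, `seed`, `mean_pearson`, `mean_rmse`,
#'   `n_mixtures`, `chosen_g`, `condition_number`.
#' @export
experiment_pipeline_recovery <- function(seed, method = c("nusvr", "cls", "marker"),
                                         cfg = NULL, n_mixtures = 100L,
                                         sig_cfg = signature_config()) {
  method <- match.arg(method)
  cfg <- cfg %||% synth_config(n_cell_types = 7L, n_features = 1200L,
                               markers_per_type = 120L, n_replicates = 4L,
                               seed = seed)
  coh <- generate_reference_cohort(cfg)
  ref <- scale_to_total(coh$expression)
  sig <- suppressWarnings(build_signature(ref, coh$groups, sig_cfg))
  fr <- sample_fractions(unique(coh$groups$cell_type), n_mixtures,
                         seed = child_seed(seed, "fractions"))
  mix <- simulate_mixtures(ref, coh$groups, fr, seed = child_seed(seed, "mixtures"))
  res <- switch(method,
    nusvr = deconvolute_nusvr(mix$bulk, sig, seed = child_seed(seed, "deconv")),
    cls = deconvolute_cls(mix$bulk, sig),
    marker = deconvolute_marker_score(mix$bulk, select_fold_markers(ref, coh$groups))
  )
  ev <- evaluate_against_truth(res, mix$truth)
  tibble(method = method, seed = seed,
         mean_pearson = ev$mean_pearson, mean_rmse = ev$mean_rmse,
         n_mixtures = ev$n_mixtures,
         chosen_g = sig$chosen_g, condition_number = sig$condition_number)
}

#' Effect of missing-value imputation on fraction recovery
#'
#' Mirrors the classic imputation benchmark: a complete cohort receives
#' intensity-dependent (MNAR) missingness, each imputation method repairs
#' it, and the whole downstream pipeline (total-intensity scaling, signature
#' construction, mixture simulation from the imputed data, deconvolution)
#' runs on the repaired matrix, so imputation error propagates into both the
#' mixtures and the signature exactly as it would in a real reprocessing of
#' reference data. `"zero"` is the no-imputation baseline that fills gaps
#' with 0.
#'
#' @param seed Integer seed.
#' @param impute_methods Imputation arms to run (subset of `"min"`, `"knn"`,
#'   `"rf"`, `"zero"`).
#' @param cfg A [synth_config()]; default 7 types, 40 markers per type among
#'   400 features, 4 replicates, MNAR plateau rate 0.4.
#' @param n_mixtures Mixtures per arm (default 100).
#' @param engine Deconvolution engine, `"nusvr"` (default) or `"cls"`.
#' @return Tibble with one row per imputation arm: `impute`, `seed`,
#'   `mean_pearson`, `mean_rmse`, `missing_fraction`.
#' @export
experiment_imputation_comparison <- function(seed,
                                             impute_methods = c("min", "knn", "rf", "zero"),
                                             cfg = NULL, n_mixtures = 100L,
                                             engine = c("nusvr", "cls")) {
  engine <- match.arg(engine)
  cfg <- cfg %||% synth_config(n_cell_types = 7L, n_features = 400L,
                               markers_per_type = 40L, n_replicates = 4L,
                               missing_rate_at_low = 0.4, seed = seed)
  coh <- generate_reference_cohort(cfg)
  gappy <- inject_missingness(coh$expression, cfg, seed = child_seed(seed, "missing"))
  missing_fraction <- mean(is.na(as.matrix(gappy[-1])))
  fr <- sample_fractions(unique(coh$groups$cell_type), n_mixtures,
                         seed = child_seed(seed, "fractions"))

  purrr::map_dfr(impute_methods, function(m) {
    imp <- if (m == "zero") {
      mm <- as.matrix(gappy[-1])
      mm[is.na(mm)] <- 0
      dplyr::bind_cols(gappy[1], as_tibble(mm))
    } else {
      impute_missing(gappy, m, cfg = preprocess_config(),
                     seed = child_seed(seed, "impute"))
    }
    imp <- scale_to_total(imp)
    sig <- suppressWarnings(build_signature(imp, coh$groups))
    mix <- simulate_mixtures(imp, coh$groups, fr,
                             seed = child_seed(seed, "mixtures"))
    res <- if (engine == "nusvr") {
      deconvolute_nusvr(mix$bulk, sig, seed = child_seed(seed, "deconv"))
    } else {
      deconvolute_cls(mix$bulk, sig)
    }
    ev <- evaluate_against_truth(res, mix$truth)
    tibble(impute = m, seed = seed, mean_pearson = ev$mean_pearson,
           mean_rmse = ev$mean_rmse, missing_fraction = missing_fraction)
  })
}

#' Effect of normalization on fraction recovery
#'
#' Mixtures are simulated from the un-normalized reference (linear mixing is
#' the physical truth); each normalization arm is then applied to both the
#' reference used for the signature and the bulk mixtures, as in standard
#' practice, before deconvolution. Quantile and cyclic loess normalization
#' equalize distributions that genuinely differ between mixtures, so they
#' are expected to degrade recovery relative to no normalization.
#'
#' @param seed Integer seed.
#' @param norm_methods Normalization arms (subset of `"none"`, `"quantile"`,
#'   `"cyclic_loess"`).
#' @param cfg A [synth_config()]; default 7 types, 30 markers per type among
#'   800 features (background-dominated, so the loess trend is anchored by
#'   non-differential proteins), 4 replicates.
#' @param n_mixtures Mixtures per arm (default 100).
#' @return Tibble with one row per arm: `normalization`, `seed`,
#'   `mean_pearson`, `mean_rmse`.
#' @export
experiment_normalization_comparison <- function(seed,
                                                norm_methods = c("none", "cyclic_loess"),
                                                cfg = NULL, n_mixtures = 100L) {
  cfg <- cfg %||% synth_config(n_cell_types = 7L, n_features = 800L,
                               markers_per_type = 30L, n_replicates = 4L,
                               seed = seed)
  coh <- generate_reference_cohort(cfg)
  ref <- scale_to_total(coh$expression)
  fr <- sample_fractions(unique(coh$groups$cell_type), n_mixtures,
                         seed = child_seed(seed, "fractions"))
  mix <- simulate_mixtures(ref, coh$groups, fr, seed = child_seed(seed, "mixtures"))

  purrr::map_dfr(norm_methods, function(nm) {
    refn <- normalize_intensities(ref, nm)
    bulkn <- normalize_intensities(mix$bulk, nm)
    sig <- suppressWarnings(build_signature(refn, coh$groups))
    res <- deconvolute_nusvr(bulkn, sig, seed = child_seed(seed, "deconv"))
    ev <- evaluate_against_truth(res, mix$truth)
    tibble(normalization = nm, seed = seed,
           mean_pearson = ev$mean_pearson, mean_rmse = ev$mean_rmse)
  })
}
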