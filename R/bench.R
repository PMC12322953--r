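#' Benchmark a factor grid of processing choices on simulated mixtures
#'
#' Runs, for every combination in the grid, the full evaluation loop:
#' impute/normalize the (possibly gap-containing) reference, build or reuse
#' a signature, simulate mixtures with known truth from the complete
#' reference, deconvolute, and score. Each grid cell is averaged over
#' `n_repeats` seeded repeats; child seeds are derived from `seed` with a
#' counter so cells are independent and individually reproducible.
#'
#' @param reference Expression tibble of pure cell-type replicates (may
#'   contain missing values; imputation is part of the grid).
#' @param groups Groups tibble labelling the reference samples.
#' @param grid Tibble of factor combinations; recognised columns are
#'   `impute` (`"none"`, `"min"`, `"knn"`, `"rf"`), `normalization`
#'   (`"none"`, `"quantile"`, `"cyclic_loess"`) and `method` (`"nusvr"`,
#'   `"cls"`, `"marker"`). Missing columns default to `"min"`, `"none"`,
#'   `"cls"`.
#' @param n_mixtures Mixtures per repeat (default 100).
#' @param n_repeats Seeded repeats per grid cell (default 1).
#' @param sig_cfg A [signature_config()].
#' @param seed Master seed.
#' @return The grid with appended columns `mean_pearson`, `mean_rmse`
#'   (averaged over repeats) and `n_mixtures`.
#' @export
run_benchmark_grid <- function(reference, groups, grid,
                               n_mixtures = 100L, n_repeats = 1L,
                               sig_cfg = signature_config(), seed = 1L) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) abort_usage("`grid` must be a non-empty data frame.")
  grid <- as_tibble(grid)
  if (!"impute" %in% names(grid)) grid$impute <- "min"
  if (!"normalization" %in% names(grid)) grid$normalization <- "none"
  if (!"method" %in% names(grid)) grid$method <- "cls"
  bad <- setdiff(unique(grid$method), c("nusvr", "cls", "marker"))
  if (length(bad)) abort_usage(sprintf("unknown method(s) in grid: %s.", paste(bad, collapse = ", ")))

  scores <- purrr::pmap(grid, function(impute, normalization, method, ...) {
    reps <- purrr::map(seq_len(n_repeats), function(r) {
      cell_seed <- child_seed(seed + 1000L * r, "bench")
      ev <- benchmark_one(reference, groups, impute, normalization, method,
                          n_mixtures, sig_cfg, cell_seed)
      c(ev$mean_pearson, ev$mean_rmse)
    })
    mat <- do.call(rbind, reps)
    tibble(mean_pearson = mean(mat[, 1]), mean_rmse = mean(mat[, 2]),
           n_mixtures = n_mixtures)
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(scores))
}

benchmark_one <- function(reference, groups, impute, normalization, method,
                          n_mixtures, sig_cfg, seed) {
  pcfg <- preprocess_config(impute_method = if (impute == "none") "none" else impute,
                            normalization = normalization)
  ref <- reference
  if (anyNA(expr_to_matrix(ref))) {
    if (impute == "none") {
      # zero-fill stand-in so downstream stages can run
      m <- expr_to_matrix(ref); m[is.na(m)] <- 0; ref <- matrix_to_expr(m)
    } else {
      ref <- impute_missing(ref, method = impute, cfg = pcfg,
                            seed = child_seed(seed, "impute"))
    }
  }
  ref <- normalize_intensities(ref, method = normalization, cfg = pcfg)

  # mixtures come from the processed reference; truth is exact by construction
  fr <- sample_fractions(unique(groups$cell_type), n_mixtures,
                         seed = child_seed(seed, "fractions"))
  mix <- simulate_mixtures(ref, groups, fr, seed = child_seed(seed, "mixtures"))

  res <- if (method == "marker") {
    mk <- select_fold_markers(ref, groups)
    deconvolute_marker_score(mix$bulk, mk)
  } else {
    sig <- build_signature(ref, groups, sig_cfg)
    if (method == "nusvr") {
      deconvolute_nusvr(mix$bulk, sig, seed = child_seed(seed, "deconv"))
    } else {
      deconvolute_cls(mix$bulk, sig)
    }
  }
  evaluate_against_truth(res, mix$truth)
}

#' Write a machine-readable provenance record for a run
#'
#' Captures what is needed to replay an output byte-identically: input
#' paths, configuration, package version and seed.
#'
#' @param path Output JSON path.
#' @param inputs Named list or character vector of input file paths.
#' @param config Named list of configuration values.
#' @param seed The seed used.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, inputs = list(), config = list(), seed = NULL) {
  jsonlite::write_json(
    list(
      package = "cellfrac",
      version = as.character(utils::packageVersion("cellfrac")),
      r_version = as.character(getRversion()),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      inputs = inputs, config = config, seed = seed
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}
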