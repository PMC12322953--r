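#' Preprocessing configuration
#'
#' Bundles the tunable settings of [preprocess_pipeline()]. Defaults follow
#' common practice for MS protein-group tables: duplicate rows resolved by
#' keeping the highest-median occurrence, minimum-value imputation, no
#' normalization, and per-sample scaling to a total intensity of 1e6
#' (the TPM-like convention).
#'
#' @param dedup_strategy `"slice"` (keep the duplicate row with the highest
#'   median observed intensity) or `"merge"` (sum duplicates element-wise).
#' @param impute_method One of `"none"`, `"min"`, `"knn"`, `"rf"`.
#' @param min_scope For minimum imputation: `"global"` (matrix-wide minimum,
#'   the conservative default) or `"sample"` (per-sample minimum).
#' @param knn_k Number of nearest neighbour features for kNN imputation.
#' @param rf_trees Trees per random-forest regressor in RF imputation.
#' @param normalization One of `"none"`, `"quantile"`, `"cyclic_loess"`.
#' @param loess_span Loess span for cyclic loess normalization, in (0, 1].
#' @param loess_iterations Number of cyclic loess sweeps over sample pairs.
#' @param total_scale Per-sample total intensity after scaling (> 0).
#' @param zero_pseudo_factor Zeros are replaced by this factor times the
#'   smallest positive value before the log2 transform used in normalization.
#'
#' @return A list of class `cellfrac_preprocess_config`.
#' @export
preprocess_config <- function(dedup_strategy = c("slice", "merge"),
                              impute_method = c("min", "none", "knn", "rf"),
                              min_scope = c("global", "sample"),
                              knn_k = 10L,
                              rf_trees = 100L,
                              normalization = c("none", "quantile", "cyclic_loess"),
                              loess_span = 0.7,
                              loess_iterations = 3L,
                              total_scale = 1e6,
                              zero_pseudo_factor = 0.5) {
  cfg <- list(
    dedup_strategy = match.arg(dedup_strategy),
    impute_method = match.arg(impute_method),
    min_scope = match.arg(min_scope),
    knn_k = as.integer(knn_k),
    rf_trees = as.integer(rf_trees),
    normalization = match.arg(normalization),
    loess_span = loess_span,
    loess_iterations = as.integer(loess_iterations),
    total_scale = total_scale,
    zero_pseudo_factor = zero_pseudo_factor
  )
  if (cfg$total_scale <= 0) abort_usage("`total_scale` must be > 0.")
  if (cfg$knn_k < 1L) abort_usage("`knn_k` must be >= 1.")
  if (cfg$loess_span <= 0 || cfg$loess_span > 1) abort_usage("`loess_span` must be in (0, 1].")
  if (cfg$loess_iterations < 1L) abort_usage("`loess_iterations` must be >= 1.")
  class(cfg) <- "cellfrac_preprocess_config"
  cfg
}

#' Collapse protein groups to single feature identifiers
#'
#' Deconvolution engines need one identifier per row, but MS search engines
#' report protein groups (sets of indistinguishable accessions). Each row is
#' collapsed to the first gene symbol listed for the group when a symbol is
#' present, otherwise to the first accession of the group. Duplicate feature
#' identifiers may remain; resolve them with [dedupe_features()].
#'
#' @param x A protein-group tibble from [read_protein_groups()] (columns
#'   `group_id`, `gene_symbol`, then sample intensities).
#' @param group_delimiter Delimiter between accessions within a group;
#'   defaults to the delimiter recorded when the table was read.
#' @return An expression tibble (`gene` + sample columns), intensities
#'   unchanged.
#' @export
collapse_protein_groups <- function(x, group_delimiter = NULL) {
  if (!is.data.frame(x) || !all(c("group_id", "gene_symbol") %in% names(x))) {
    abort_validation("`x` must have columns `group_id` and `gene_symbol`.")
  }
  delim <- group_delimiter %||% attr(x, "group_delimiter") %||% ";"
  bad <- which(is.na(x$group_id) | x$group_id == "")
  if (length(bad)) {
    abort_validation(sprintf("empty group_id on row(s): %s.",
                             paste(head(bad, 5L), collapse = ", ")))
  }
  first_token <- function(v) {
    vapply(stringr::str_split(v, stringr::fixed(delim)), function(p) p[[1]], character(1))
  }
  gene <- ifelse(is.na(x$gene_symbol) | x$gene_symbol == "",
                 first_token(x$group_id), first_token(x$gene_symbol))
  sample_cols <- setdiff(names(x), c("group_id", "gene_symbol"))
  dplyr::bind_cols(tibble(gene = gene), x[sample_cols])
}

#' Resolve duplicated feature identifiers
#'
#' After protein-group collapse (or in single-protein exports) the same gene
#' symbol can occur on several rows. `"slice"` keeps, per duplicated
#' identifier, the row with the highest median over its observed intensities
#' (ties keep the first occurrence); `"merge"` sums duplicates element-wise,
#' treating missing values as absent (a slot missing in every duplicate stays
#' missing). Non-duplicated rows pass through untouched and output rows keep
#' first-occurrence order.
#'
#' @param x An expression tibble, possibly with duplicated `gene` values.
#' @param strategy `"slice"` or `"merge"`.
#' @return An expression tibble with unique `gene` values.
#' @export
dedupe_features <- function(x, strategy = c("slice", "merge")) {
  if (is.character(strategy) && length(strategy) == 1L &&
      !strategy %in% c("slice", "merge")) {
    abort_usage(sprintf("unknown dedup strategy `%s` (use \"slice\" or \"merge\").", strategy))
  }
  strategy <- match.arg(strategy)
  check_expr_table(x)
  if (!anyDuplicated(x$gene)) return(x)

  m <- as.matrix(x[, -1, drop = FALSE])
  keep_order <- !duplicated(x$gene)
  if (strategy == "slice") {
    med <- row_medians_observed(m)
    keep <- unlist(lapply(split(seq_len(nrow(x)), factor(x$gene, levels = unique(x$gene))),
                          function(idx) idx[which.max(med[idx])]), use.names = FALSE)
    out <- x[sort(keep), , drop = FALSE]
    # restore first-occurrence order of identifiers
    out <- out[match(unique(x$gene), out$gene), , drop = FALSE]
  } else {
    sums <- rowsum(ifelse(is.na(m), 0, m), group = x$gene, reorder = FALSE)
    n_obs <- rowsum((!is.na(m)) * 1L, group = x$gene, reorder = FALSE)
    sums[n_obs == 0L] <- NA_real_
    out <- dplyr::bind_cols(tibble(gene = rownames(sums)), as_tibble(sums))
  }
  as_tibble(out)
}

#' Impute missing intensities
#'
#' None of the deconvolution engines tolerate missing values, so gaps must be
#' filled first. Three imputers are provided:
#'
#' * `"min"` — every missing entry is replaced by the minimum observed value
#'   of the whole matrix (or of its sample, with `min_scope = "sample"`); the
#'   conservative choice for intensity-dependent (MNAR) missingness, where a
#'   gap most plausibly means "below detection".
#' * `"knn"` — feature-wise k-nearest-neighbours: each gap is filled with the
#'   mean, over the `knn_k` features closest in Euclidean distance on jointly
#'   observed samples, of their value in that sample.
#' * `"rf"` — missForest-style iterative random-forest regression: features
#'   with gaps are mean-initialized, then repeatedly re-predicted from all
#'   other features until the sum of squared changes increases or 10 sweeps
#'   have run.
#'
#' Observed entries are never altered.
#'
#' @param x An expression tibble, possibly with `NA` values.
#' @param method One of `"none"`, `"min"`, `"knn"`, `"rf"`.
#' @param cfg A [preprocess_config()] supplying `min_scope`, `knn_k`, `rf_trees`.
#' @param seed Integer seed making `"knn"`/`"rf"` runs reproducible.
#' @return An expression tibble with no missing values (unless `method = "none"`).
#' @export
impute_missing <- function(x, method = c("min", "none", "knn", "rf"),
                           cfg = preprocess_config(), seed = NULL) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("none", "min", "knn", "rf")) {
    abort_usage(sprintf("unknown imputation method `%s`.", method))
  }
  method <- match.arg(method)
  check_expr_table(x)
  if (method == "none") return(x)

  m <- expr_to_matrix(x)
  if (!anyNA(m)) return(x)
  if (all(is.na(m))) abort_validation("cannot impute an all-missing matrix.")

  imp <- switch(method,
    min = impute_min_mat(m, scope = cfg$min_scope),
    knn = impute_knn_mat(m, k = cfg$knn_k),
    rf = with_seed_if(seed %||% 1L, impute_rf_mat(m, num_trees = cfg$rf_trees))
  )
  stopifnot(identical(dim(imp), dim(m)))
  matrix_to_expr(imp)
}

impute_min_mat <- function(m, scope = "global") {
  if (scope == "global") {
    m[is.na(m)] <- min(m, na.rm = TRUE)
  } else {
    global_min <- min(m, na.rm = TRUE)
    for (j in seq_len(ncol(m))) {
      v <- m[, j]
      fill <- if (all(is.na(v))) global_min else min(v, na.rm = TRUE)
      v[is.na(v)] <- fill
      m[, j] <- v
    }
  }
  m
}

impute_knn_mat <- function(m, k) {
  out <- m
  has_na <- which(rowSums(is.na(m)) > 0L)
  for (i in has_na) {
    target <- m[i, ]
    obs_t <- !is.na(target)
    # distance to every other feature on jointly observed samples
    d <- rep(Inf, nrow(m))
    for (j in seq_len(nrow(m))) {
      if (j == i) next
      joint <- obs_t & !is.na(m[j, ])
      if (!any(joint)) next
      d[j] <- sqrt(sum((target[joint] - m[j, joint])^2) / sum(joint))
    }
    ord <- order(d)
    for (s in which(is.na(target))) {
      donors <- ord[!is.na(m[ord, s]) & is.finite(d[ord])]
      donors <- head(donors, k)
      out[i, s] <- if (length(donors)) mean(m[donors, s])
                   else min(m, na.rm = TRUE)  # isolated gap: conservative fallback
    }
  }
  out
}

impute_rf_mat <- function(m, num_trees = 100L, max_iter = 10L) {
  na_mask <- is.na(m)
  # mean-initialize along features; all-missing features get the global mean
  feat_means <- rowMeans(m, na.rm = TRUE)
  feat_means[is.nan(feat_means)] <- mean(m, na.rm = TRUE)
  cur <- m
  for (i in seq_len(nrow(m))) cur[i, na_mask[i, ]] <- feat_means[i]

  # predictors are the other features; observations are samples
  targets <- which(rowSums(na_mask) > 0L & rowSums(!na_mask) >= 2L)
  prev_change <- Inf
  for (iter in seq_len(max_iter)) {
    new <- cur
    for (i in targets) {
      obs <- which(!na_mask[i, ])
      mis <- which(na_mask[i, ])
      df_train <- as.data.frame(t(cur[-i, obs, drop = FALSE]))
      df_train$.y <- cur[i, obs]
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = df_train,
        num.trees = num_trees, num.threads = 1L,
        seed = sample.int(.Machine$integer.max, 1L)
      )
      df_pred <- as.data.frame(t(cur[-i, mis, drop = FALSE]))
      new[i, mis] <- predict(fit, df_pred, num.threads = 1L)$predictions
    }
    change <- sum((new[na_mask] - cur[na_mask])^2) / max(sum(new[na_mask]^2), .Machine$double.eps)
    if (change > prev_change) break  # missForest stopping rule
    cur <- new
    prev_change <- change
    if (change == 0) break
  }
  cur
}

#' Normalize intensity distributions across samples
#'
#' Normalization runs on log2-transformed values and the result is
#' exponentiated back to linear scale, so downstream deconvolution always
#' sees linear intensities. `"quantile"` forces every sample to share one
#' common value distribution (rank ties averaged); `"cyclic_loess"` fits,
#' for each unordered pair of samples, a loess curve of the log-difference M
#' against the log-average A and removes half the fitted trend from each
#' sample symmetrically, cycling over all pairs. Zeros are replaced by
#' `zero_pseudo_factor` times the smallest positive value before the log
#' transform. Both transforms are delegated to the limma implementations.
#'
#' Note that normalization generally hurts reference-based deconvolution of
#' linear-scale mixtures — it is offered to quantify that effect, not as a
#' recommended default.
#'
#' @param x An expression tibble with no missing values.
#' @param method One of `"none"`, `"quantile"`, `"cyclic_loess"`.
#' @param cfg A [preprocess_config()] supplying `loess_span`,
#'   `loess_iterations`, `zero_pseudo_factor`.
#' @return An expression tibble on linear scale.
#' @export
normalize_intensities <- function(x, method = c("none", "quantile", "cyclic_loess"),
                                  cfg = preprocess_config()) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("none", "quantile", "cyclic_loess")) {
    abort_usage(sprintf("unknown normalization method `%s`.", method))
  }
  method <- match.arg(method)
  check_expr_table(x)
  if (method == "none") return(x)
  m <- expr_to_matrix(x)
  if (anyNA(m)) abort_validation("normalization requires a complete matrix; impute first.")

  if (any(m == 0)) {
    pos_min <- suppressWarnings(min(m[m > 0]))
    if (!is.finite(pos_min)) abort_validation("all-zero matrix cannot be log-transformed.")
    m[m == 0] <- cfg$zero_pseudo_factor * pos_min
  }
  lg <- log2(m)
  norm <- switch(method,
    quantile = limma::normalizeQuantiles(lg, ties = TRUE),
    cyclic_loess = limma::normalizeCyclicLoess(
      lg, method = "pairs", span = cfg$loess_span,
      iterations = cfg$loess_iterations
    )
  )
  dimnames(norm) <- dimnames(m)
  matrix_to_expr(2^norm)
}

#' Scale each sample to a fixed total intensity
#'
#' Rescales every sample so its intensities sum to `total` (default 1e6),
#' the TPM-like convention that makes samples of different loading depth
#' comparable. Within-sample proportions are preserved and the operation is
#' idempotent. Missing values are ignored in the total.
#'
#' @param x An expression tibble.
#' @param total Target per-sample total (> 0).
#' @return The rescaled expression tibble.
#' @export
scale_to_total <- function(x, total = 1e6) {
  if (total <= 0) abort_usage("`total` must be > 0.")
  check_expr_table(x)
  m <- expr_to_matrix(x)
  sums <- colSums(m, na.rm = TRUE)
  zero <- sums <= 0
  if (any(zero)) {
    abort_validation(sprintf("sample(s) with non-positive total intensity: %s.",
                             paste(colnames(m)[zero], collapse = ", ")))
  }
  matrix_to_expr(sweep(m, 2L, sums / total, "/"))
}

#' Full preprocessing pipeline for a protein-group table
#'
#' Runs the stages in fixed order: protein-group collapse, duplicate
#' resolution, imputation, normalization, total-intensity scaling. The order
#' is logged via a message so every run records what was done.
#'
#' @param x A protein-group tibble from [read_protein_groups()].
#' @param cfg A [preprocess_config()].
#' @param seed Integer seed forwarded to the imputer.
#' @param quiet Suppress the stage log message.
#' @return A deconvolution-ready expression tibble: unique features, no
#'   missing values (when imputing), linear scale, per-sample totals equal to
#'   `cfg$total_scale`.
#' @export
preprocess_pipeline <- function(x, cfg = preprocess_config(), seed = NULL,
                                quiet = FALSE) {
  if (!inherits(cfg, "cellfrac_preprocess_config")) {
    abort_usage("`cfg` must come from preprocess_config().")
  }
  if (!quiet) {
    inform(sprintf(
      "preprocess: collapse -> dedupe(%s) -> impute(%s) -> normalize(%s) -> scale(%g)",
      cfg$dedup_strategy, cfg$impute_method, cfg$normalization, cfg$total_scale
    ))
  }
  x |>
    collapse_protein_groups() |>
    dedupe_features(strategy = cfg$dedup_strategy) |>
    impute_missing(method = cfg$impute_method, cfg = cfg,
                   seed = child_seed(seed, "impute")) |>
    normalize_intensities(method = cfg$normalization, cfg = cfg) |>
    scale_to_total(total = cfg$total_scale)
}
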