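# Internal helpers shared across modules.
#
# An expression table is a tibble whose first column, "gene", holds unique
# feature identifiers and whose remaining columns are numeric per-sample
# linear-scale intensities (NA = missing). A groups table is a tibble with
# columns "sample" and "cell_type". A fractions table is a tibble with a
# "sample" column followed by one numeric column per cell type.

abort_usage <- function(msg) abort(msg, class = "cellfrac_usage_error")
abort_validation <- function(msg) abort(msg, class = "cellfrac_validation_error")
abort_format <- function(msg) abort(msg, class = "cellfrac_format_error")

# Coerce an expression tibble to a features x samples matrix with rownames.
expr_to_matrix <- function(x) {
  check_expr_table(x)
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$gene
  m
}

matrix_to_expr <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
}

check_expr_table <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 1L || names(x)[1] != "gene") {
    abort_validation(sprintf(
      "`%s` must be a data frame whose first column is `gene`.", arg
    ))
  }
  if (anyDuplicated(names(x))) {
    abort_validation(sprintf("`%s` has duplicated sample columns.", arg))
  }
  num_ok <- vapply(x[-1], is.numeric, logical(1))
  if (ncol(x) > 1L && !all(num_ok)) {
    abort_validation(sprintf(
      "`%s`: sample columns must be numeric (offending: %s).",
      arg, paste(names(x)[-1][!num_ok], collapse = ", ")
    ))
  }
  invisible(x)
}

check_groups <- function(groups, sample_ids) {
  if (!is.data.frame(groups) || !all(c("sample", "cell_type") %in% names(groups))) {
    abort_validation("`groups` must be a data frame with columns `sample` and `cell_type`.")
  }
  missing <- setdiff(sample_ids, groups$sample)
  if (length(missing)) {
    abort_validation(sprintf(
      "`groups` lacks a cell-type label for sample(s): %s.",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(groups)
}

# Look up cell-type labels in the column order of an expression matrix.
group_vector <- function(groups, sample_ids) {
  check_groups(groups, sample_ids)
  setNames(groups$cell_type[match(sample_ids, groups$sample)], sample_ids)
}

# Run `code` under a fixed RNG state when `seed` is given, untouched otherwise.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive independent child seeds from one parent seed; keeps each pipeline
# stage decoupled so stages can be re-run in isolation. Stays below 2^31.
child_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(
    synth = 101L, missing = 211L, impute = 307L, fractions = 401L,
    mixtures = 503L, deconv = 601L, bench = 701L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 48271 + off) %% 2147483647)
}

row_medians_observed <- function(m) {
  apply(m, 1L, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) -Inf else median(v)
  })
}

# Fast per-row means/variances over a column subset, NA-free input assumed.
row_mean_var <- function(m, cols) {
  n <- length(cols)
  mu <- rowMeans(m[, cols, drop = FALSE])
  v <- if (n > 1L) {
    rowSums((m[, cols, drop = FALSE] - mu)^2) / (n - 1L)
  } else {
    rep(NA_real_, nrow(m))
  }
  list(mean = mu, var = v, n = n)
}
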