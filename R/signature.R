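#' Signature-construction configuration
#'
#' @param g_min,g_max Minimum and maximum number of marker genes taken per
#'   cell type during the condition-number sweep (defaults 200 and 400).
#' @param q_threshold Benjamini-Hochberg q-value cut-off for differential
#'   expression (default 0.01).
#' @param filter_features Optional character vector of feature identifiers to
#'   exclude before marker ranking (e.g. a user-supplied non-hematopoietic
#'   gene list). Default `NULL` retains everything.
#' @return A list of class `cellfrac_signature_config`.
#' @export
signature_config <- function(g_min = 200L, g_max = 400L, q_threshold = 0.01,
                             filter_features = NULL) {
  g_min <- as.integer(g_min); g_max <- as.integer(g_max)
  if (g_min < 1L || g_max < g_min) abort_usage("need 1 <= g_min <= g_max.")
  if (q_threshold <= 0 || q_threshold > 1) abort_usage("`q_threshold` must be in (0, 1].")
  structure(
    list(g_min = g_min, g_max = g_max, q_threshold = q_threshold,
         filter_features = filter_features),
    class = "cellfrac_signature_config"
  )
}

#' Rank candidate marker features per cell type
#'
#' For every feature and cell type, a two-sided Welch (unequal-variance)
#' t-test on log2 intensities compares that type's replicates against all
#' other samples. P-values are Benjamini-Hochberg adjusted per cell type
#' across features. Candidates are the features with `q < q_threshold` and a
#' positive log2 fold change (mean of the type minus mean of the rest),
#' ordered by decreasing fold change.
#'
#' @param reference Expression tibble of pure cell-type replicates, complete
#'   (no missing values), linear scale.
#' @param groups Groups tibble (`sample`, `cell_type`) labelling every
#'   reference sample; at least two cell types and two replicates per type.
#' @param q_threshold BH q-value cut-off (default 0.01).
#' @return A tibble with columns `cell_type`, `gene`, `log2_fc`, `t`,
#'   `p_value`, `q_value`, `rank`, containing only candidates, ranked within
#'   cell type.
#' @export
rank_markers <- function(reference, groups, q_threshold = 0.01) {
  m <- expr_to_matrix(reference)
  if (anyNA(m)) abort_validation("`reference` must have no missing values.")
  labels <- group_vector(groups, colnames(m))
  types <- unique(labels)
  if (length(types) < 2L) abort_validation("need at least two cell types.")
  tab <- table(labels)
  if (any(tab < 2L)) {
    abort_validation(sprintf("cell type(s) with fewer than 2 replicates: %s.",
                             paste(names(tab)[tab < 2L], collapse = ", ")))
  }

  lg <- log2(pmax(m, .Machine$double.xmin))
  purrr::map_dfr(types, function(ct) {
    in_ct <- which(labels == ct)
    out_ct <- which(labels != ct)
    a <- row_mean_var(lg, in_ct)
    b <- row_mean_var(lg, out_ct)
    diff <- a$mean - b$mean
    se2 <- a$var / a$n + b$var / b$n
    tstat <- diff / sqrt(se2)
    df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1L) + (b$var / b$n)^2 / (b$n - 1L))
    p <- 2 * pt(-abs(tstat), df)
    # degenerate zero-variance features: identical means are null, distinct
    # means are maximally significant
    degen <- !is.finite(se2) | se2 == 0 | !is.finite(df)
    p[degen] <- ifelse(abs(diff[degen]) < .Machine$double.eps^0.5, 1, 0)
    q <- p.adjust(p, method = "BH")
    keep <- which(q < q_threshold & diff > 0)
    keep <- keep[order(diff[keep], decreasing = TRUE)]
    tibble(
      cell_type = ct, gene = rownames(m)[keep],
      log2_fc = unname(diff[keep]), t = unname(tstat[keep]),
      p_value = unname(p[keep]), q_value = unname(q[keep]),
      rank = seq_along(keep)
    )
  })
}

#' Build a condition-number-optimized signature matrix
#'
#' The signature matrix is the design matrix of reference-based
#' deconvolution; its conditioning controls how well fractions can be
#' recovered. For every candidate size G between `g_min` and `g_max`, the
#' top-G ranked markers of each cell type are pooled, the per-type mean
#' linear intensities over that pool form a candidate signature, and its
#' 2-norm condition number (ratio of largest to smallest singular value) is
#' computed. The signature with the smallest condition number wins; ties go
#' to the smallest G. Cell types with fewer than `g_min` candidates
#' contribute all their candidates (with a warning); a cell type with no
#' candidates is an error.
#'
#' @param reference,groups As in [rank_markers()].
#' @param cfg A [signature_config()].
#' @return An object of class `cellfrac_signature` with elements `profiles`
#'   (tibble: `gene` + one column per cell type), `chosen_g`,
#'   `condition_number`, `sweep` (tibble of G vs condition number vs
#'   signature size) and `config`.
#' @export
build_signature <- function(reference, groups, cfg = signature_config()) {
  if (!inherits(cfg, "cellfrac_signature_config")) {
    abort_usage("`cfg` must come from signature_config().")
  }
  ref <- reference
  if (!is.null(cfg$filter_features)) {
    ref <- dplyr::filter(ref, !.data$gene %in% cfg$filter_features)
  }
  cand <- rank_markers(ref, groups, q_threshold = cfg$q_threshold)
  m <- expr_to_matrix(ref)
  labels <- group_vector(groups, colnames(m))
  types <- unique(labels)

  counts <- table(factor(cand$cell_type, levels = types))
  if (any(counts == 0L)) {
    abort(sprintf("no differential candidates for cell type(s): %s.",
                  paste(names(counts)[counts == 0L], collapse = ", ")),
          class = "cellfrac_construction_error")
  }
  if (any(counts < cfg$g_min)) {
    warn(sprintf("cell type(s) with fewer than g_min = %d candidates (all used): %s.",
                 cfg$g_min,
                 paste(names(counts)[counts < cfg$g_min], collapse = ", ")))
  }

  # per-type mean linear profiles, computed once over all features
  profile_mat <- vapply(types, function(ct) {
    rowMeans(m[, labels == ct, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(profile_mat) <- rownames(m)

  cand_by_type <- split(cand$gene, factor(cand$cell_type, levels = types))
  sweep_tbl <- purrr::map_dfr(seq(cfg$g_min, cfg$g_max), function(G) {
    union_g <- unique(unlist(lapply(cand_by_type, head, G), use.names = FALSE))
    sig <- profile_mat[union_g, , drop = FALSE]
    tibble(g = G, n_features = length(union_g), condition_number = cond_number(sig))
  })

  best <- sweep_tbl[which.min(sweep_tbl$condition_number), ]  # which.min takes first tie
  union_best <- unique(unlist(lapply(cand_by_type, head, best$g), use.names = FALSE))
  profiles <- matrix_to_expr(profile_mat[union_best, , drop = FALSE])

  structure(
    list(profiles = profiles, chosen_g = best$g,
         condition_number = best$condition_number,
         sweep = sweep_tbl, markers = cand, config = cfg),
    class = "cellfrac_signature"
  )
}

# 2-norm condition number via singular values
cond_number <- function(mat) {
  d <- svd(mat, nu = 0L, nv = 0L)$d
  if (min(d) <= 0 || !is.finite(min(d))) return(Inf)
  max(d) / min(d)
}

#' Select markers by expression and fold-change thresholds
#'
#' The marker rule used by marker-scoring methods: a feature is a marker for
#' cell type `c` iff its mean linear intensity in `c` exceeds
#' `min_expression` and is at least `fold` times the reference level of the
#' other types. With `compare = "max"` (the strict default) the reference
#' level is the maximum other-type mean; `compare = "mean"` uses the mean of
#' the other-type means. A zero reference level yields infinite fold change.
#' Cell types that end up with no markers are dropped with a warning.
#'
#' @param reference,groups As in [rank_markers()].
#' @param min_expression Minimum mean intensity in the target type (default 1000).
#' @param fold Minimum fold change over the other types (default 3).
#' @param compare `"max"` or `"mean"` — how the other types are summarized.
#' @return A tibble with columns `cell_type`, `gene`, `fold_change`,
#'   `mean_expression`.
#' @export
select_fold_markers <- function(reference, groups, min_expression = 1000,
                                fold = 3, compare = c("max", "mean")) {
  compare <- match.arg(compare)
  m <- expr_to_matrix(reference)
  if (anyNA(m)) abort_validation("`reference` must have no missing values.")
  labels <- group_vector(groups, colnames(m))
  types <- unique(labels)
  if (length(types) < 2L) abort_validation("need at least two cell types.")

  type_means <- vapply(types, function(ct) {
    rowMeans(m[, labels == ct, drop = FALSE])
  }, numeric(nrow(m)))

  res <- purrr::map_dfr(seq_along(types), function(i) {
    target <- type_means[, i]
    others <- type_means[, -i, drop = FALSE]
    ref_level <- if (compare == "max") apply(others, 1L, max) else rowMeans(others)
    fc <- ifelse(ref_level == 0, Inf, target / ref_level)
    keep <- target > min_expression & fc >= fold
    tibble(cell_type = types[i], gene = rownames(m)[keep],
           fold_change = unname(fc[keep]), mean_expression = unname(target[keep]))
  })

  empty <- setdiff(types, unique(res$cell_type))
  if (length(empty)) {
    warn(sprintf("no fold-change markers for cell type(s): %s (dropped).",
                 paste(empty, collapse = ", ")))
  }
  res
}

#' Write a signature matrix (TSV + JSON sidecar) and read it back
#'
#' The TSV uses the `Gene`-first layout; construction metadata (chosen G,
#' condition number, config) goes to `<path>.json`.
#'
#' @param sig A `cellfrac_signature`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path) {
  stopifnot(inherits(sig, "cellfrac_signature"))
  write_expression_matrix(sig$profiles, path)
  meta <- list(
    chosen_g = sig$chosen_g, condition_number = sig$condition_number,
    g_min = sig$config$g_min, g_max = sig$config$g_max,
    q_threshold = sig$config$q_threshold
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  profiles <- read_expression_matrix(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(
    list(profiles = profiles,
         chosen_g = meta$chosen_g %||% NA_integer_,
         condition_number = meta$condition_number %||%
           cond_number(expr_to_matrix(profiles)),
         sweep = NULL, markers = NULL,
         config = signature_config(
           g_min = meta$g_min %||% 1L,
           g_max = meta$g_max %||% max(1L, nrow(profiles)),
           q_threshold = meta$q_threshold %||% 0.01
         )),
    class = "cellfrac_signature"
  )
}

#' @export
print.cellfrac_signature <- function(x, ...) {
  cat(sprintf(
    "<cellfrac signature> %d markers x %d cell types | chosen G = %s | condition number = %.3g\n",
    nrow(x$profiles), ncol(x$profiles) - 1L,
    ifelse(is.na(x$chosen_g), "?", x$chosen_g), x$condition_number
  ))
  invisible(x)
}

#' Tidy a signature matrix into long format
#' @param x A `cellfrac_signature`.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `cell_type`, `intensity`.
#' @exportS3Method generics::tidy
tidy.cellfrac_signature <- function(x, ...) {
  tidyr::pivot_longer(x$profiles, -"gene",
                      names_to = "cell_type", values_to = "intensity")
}

#' One-row summary of a signature matrix
#' @param x A `cellfrac_signature`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cellfrac_signature <- function(x, ...) {
  tibble(
    n_features = nrow(x$profiles), n_cell_types = ncol(x$profiles) - 1L,
    chosen_g = x$chosen_g, condition_number = x$condition_number
  )
}
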