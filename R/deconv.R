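#' Restrict bulk and signature to their common features
#'
#' Deconvolution solves the bulk sample as a weighted sum of signature
#' columns, so both must live on the same feature set in the same order.
#' Features are matched by identifier; the coverage ratio
#' (common / signature features) is reported and, below `min_coverage`, the
#' call is refused — a sparse overlap means the signature no longer
#' represents what it was built to represent.
#'
#' @param bulk Expression tibble of bulk samples.
#' @param sig A `cellfrac_signature` or an expression tibble of profiles.
#' @param min_coverage Refusal threshold on the coverage ratio (default 0.5).
#' @return List with `bulk`, `sig` (both expression tibbles on the common
#'   features, same order) and `coverage`.
#' @export
harmonize_features <- function(bulk, sig, min_coverage = 0.5) {
  profiles <- if (inherits(sig, "cellfrac_signature")) sig$profiles else sig
  check_expr_table(bulk, "bulk")
  check_expr_table(profiles, "sig")
  common <- intersect(profiles$gene, bulk$gene)
  coverage <- length(common) / nrow(profiles)
  if (coverage < min_coverage) {
    abort_validation(sprintf(
      "only %.1f%% of signature features are present in the bulk matrix (threshold %.0f%%).",
      100 * coverage, 100 * min_coverage
    ))
  }
  list(
    bulk = bulk[match(common, bulk$gene), , drop = FALSE],
    sig = profiles[match(common, profiles$gene), , drop = FALSE],
    coverage = coverage
  )
}

new_deconv_result <- function(fractions, fit, method, parameters) {
  structure(
    list(fractions = fractions, fit = fit, method = method,
         parameters = parameters),
    class = "cellfrac_deconv"
  )
}

#' Deconvolute bulk proteomes against a signature matrix
#'
#' Front door for the three engines. `method = "nusvr"` is the
#' nu-support-vector-regression estimator (the CIBERSORT core),
#' `method = "cls"` the non-negativity-constrained least-squares estimator
#' (the EPIC-style core), `method = "marker"` a marker-score baseline that
#' needs a marker table from [select_fold_markers()] instead of a signature.
#'
#' @param bulk Expression tibble of bulk samples (linear scale, no missing
#'   values).
#' @param sig A `cellfrac_signature` (or profiles tibble); for
#'   `method = "marker"`, a marker tibble.
#' @param method `"nusvr"`, `"cls"` or `"marker"`.
#' @param ... Passed to the engine ([deconvolute_nusvr()],
#'   [deconvolute_cls()], [deconvolute_marker_score()]).
#' @return A `cellfrac_deconv` object: `fractions` (tibble `sample` + one
#'   column per cell type, plus `other` when applicable), `fit` (tibble
#'   `sample`, `rmse`, `pearson`), `method`, `parameters`.
#' @export
deconvolute <- function(bulk, sig, method = c("nusvr", "cls", "marker"), ...) {
  if (is.character(method) && length(method) == 1L &&
      !method %in% c("nusvr", "cls", "marker")) {
    abort_usage(sprintf("unknown deconvolution method `%s`.", method))
  }
  method <- match.arg(method)
  switch(method,
    nusvr = deconvolute_nusvr(bulk, sig, ...),
    cls = deconvolute_cls(bulk, sig, ...),
    marker = deconvolute_marker_score(bulk, sig, ...)
  )
}

#' nu-SVR deconvolution (CIBERSORT-style core)
#'
#' Per sample: the harmonized signature matrix is z-scored by its global
#' mean and standard deviation over all entries, and the sample vector by
#' its own mean and standard deviation. A linear nu-support-vector
#' regression of the z-scored sample on the z-scored signature columns is
#' fitted for each nu in `nu_grid`; the nu whose raw coefficient vector
#' minimizes the RMSE between the z-scored sample and its linear
#' reconstruction is kept. Negative coefficients are clamped to zero and the
#' rest normalized to sum to one. Fit statistics (`rmse`, `pearson`) are
#' computed on the linear-scale reconstruction.
#'
#' Samples for which every coefficient is clamped (or with zero variance)
#' yield `NA` fractions and are listed in `parameters$failed_samples`; no
#' uniform fallback is applied.
#'
#' @inheritParams deconvolute
#' @param nu_grid Candidate nu values (default `c(0.25, 0.5, 0.75)`).
#' @param standardize `"global"` (z-score the signature by its global
#'   mean/sd, the classical convention) or `"feature"` (per-feature rows).
#' @param seed Integer seed (the solver is deterministic; the seed is fixed
#'   for reproducibility of any internal shuffling).
#' @param min_coverage Passed to [harmonize_features()].
#' @return A `cellfrac_deconv` object; fractions sum to one per sample.
#' @export
deconvolute_nusvr <- function(bulk, sig, nu_grid = c(0.25, 0.5, 0.75),
                              standardize = c("global", "feature"),
                              seed = NULL, min_coverage = 0.5) {
  standardize <- match.arg(standardize)
  h <- harmonize_features(bulk, sig, min_coverage)
  B <- expr_to_matrix(h$bulk)
  S <- expr_to_matrix(h$sig)
  if (anyNA(B) || anyNA(S)) abort_validation("inputs must have no missing values.")
  types <- colnames(S)

  Sz <- if (standardize == "global") {
    (S - mean(S)) / sd(S)
  } else {
    t(scale(t(S)))
  }

  failed <- character()
  res <- with_seed_if(seed %||% 1L, lapply(colnames(B), function(sn) {
    y <- B[, sn]
    if (sd(y) == 0) return(list(fr = rep(NA_real_, length(types)), fit = c(NA, NA), fail = sn))
    yz <- (y - mean(y)) / sd(y)
    best <- NULL
    for (nu in nu_grid) {
      fit <- e1071::svm(Sz, yz, type = "nu-regression", kernel = "linear",
                        nu = nu, scale = FALSE)
      w <- drop(t(fit$coefs) %*% fit$SV)
      rmse_z <- sqrt(mean((drop(Sz %*% w) - yz)^2))
      if (is.null(best) || rmse_z < best$rmse_z) best <- list(w = w, rmse_z = rmse_z, nu = nu)
    }
    w <- pmax(best$w, 0)
    if (sum(w) == 0) {
      return(list(fr = rep(NA_real_, length(types)), fit = c(NA, NA), fail = sn))
    }
    fr <- w / sum(w)
    list(fr = fr, fit = unlist(reconstruction_stats(y, S, fr)), fail = NULL, nu = best$nu)
  }))

  failed <- unlist(lapply(res, `[[`, "fail"))
  fractions <- dplyr::bind_cols(
    tibble(sample = colnames(B)),
    as_tibble(do.call(rbind, lapply(res, `[[`, "fr")), .name_repair = ~types)
  )
  fit <- tibble(
    sample = colnames(B),
    rmse = vapply(res, function(r) r$fit[[1]], numeric(1)),
    pearson = vapply(res, function(r) r$fit[[2]], numeric(1))
  )
  new_deconv_result(fractions, fit, "nusvr", list(
    nu_grid = nu_grid, standardize = standardize, coverage = h$coverage,
    selected_nu = vapply(res, function(r) r$nu %||% NA_real_, numeric(1)),
    failed_samples = failed %||% character()
  ))
}

#' Constrained least-squares deconvolution (EPIC-style core)
#'
#' Per sample, minimizes the squared residual between the sample and the
#' signature-weighted sum subject to non-negative fractions. With
#' `allow_other = TRUE` the fractions are additionally constrained to sum to
#' at most one and the remainder `1 - sum(f)` is reported as `other` — the
#' share of the sample not explained by the modelled cell types. Otherwise
#' the non-negative solution is renormalized to sum to one.
#'
#' `content_factors` applies a protein-content bias correction: when cell
#' types differ in protein mass per cell, intensity-scale fractions
#' over-represent high-content types. Given per-type positive factors `r`
#' (protein content per cell, any common unit), the corrected fractions are
#' `(f_c / r_c) / sum_k(f_k / r_k)`, turning protein-mass fractions into
#' cell-count fractions. `other` is excluded from that renormalization.
#'
#' @inheritParams deconvolute
#' @param allow_other Permit an unassigned remainder (default `FALSE`).
#' @param content_factors Optional named positive vector (one entry per cell
#'   type) of relative protein content per cell.
#' @param min_coverage Passed to [harmonize_features()].
#' @return A `cellfrac_deconv` object.
#' @export
deconvolute_cls <- function(bulk, sig, allow_other = FALSE,
                            content_factors = NULL, min_coverage = 0.5) {
  h <- harmonize_features(bulk, sig, min_coverage)
  B <- expr_to_matrix(h$bulk)
  S <- expr_to_matrix(h$sig)
  if (anyNA(B) || anyNA(S)) abort_validation("inputs must have no missing values.")
  types <- colnames(S)
  k <- length(types)
  if (k == 0L || nrow(S) == 0L) {
    abort("empty signature matrix.", class = "cellfrac_construction_error")
  }
  if (!is.null(content_factors)) {
    if (is.null(names(content_factors)) || !all(types %in% names(content_factors)) ||
        any(content_factors <= 0)) {
      abort_usage("`content_factors` must be a named positive vector covering every cell type.")
    }
    content_factors <- content_factors[types]
  }

  # scale the system for quadprog conditioning; fractions are scale-invariant
  sc <- max(abs(S))
  if (sc == 0 || !is.finite(cond_number(S))) {
    abort("signature matrix is singular.", class = "cellfrac_construction_error")
  }
  Ss <- S / sc
  D <- crossprod(Ss)
  D <- D + diag(1e-12 * max(diag(D)), k)  # keep strictly positive definite
  Amat <- if (allow_other) cbind(diag(k), -rep(1, k)) else diag(k)
  bvec <- if (allow_other) c(rep(0, k), -1) else rep(0, k)

  solve_one <- function(y) {
    dvec <- crossprod(Ss, y / sc)
    f <- quadprog::solve.QP(D, dvec, Amat, bvec)$solution
    f[f < 0 & f > -1e-9] <- 0
    f <- pmax(f, 0)
    f
  }

  rows <- lapply(colnames(B), function(sn) {
    f <- solve_one(B[, sn])
    other <- NA_real_
    if (allow_other) {
      other <- max(0, 1 - sum(f))
      if (sum(f) > 1) f <- f / sum(f)  # guard tiny constraint overshoot
    } else {
      if (sum(f) > 0) f <- f / sum(f)
    }
    if (!is.null(content_factors)) {
      g <- f / content_factors
      if (sum(g) > 0) f <- g / sum(g) * (if (allow_other) sum(f) else 1)
    }
    list(f = f, other = other,
         fit = unlist(reconstruction_stats(B[, sn], S, f * (sum(f) > 0))))
  })

  fractions <- dplyr::bind_cols(
    tibble(sample = colnames(B)),
    as_tibble(do.call(rbind, lapply(rows, `[[`, "f")), .name_repair = ~types)
  )
  if (allow_other) fractions$other <- vapply(rows, `[[`, numeric(1), "other")
  fit <- tibble(
    sample = colnames(B),
    rmse = vapply(rows, function(r) r$fit[[1]], numeric(1)),
    pearson = vapply(rows, function(r) r$fit[[2]], numeric(1))
  )
  new_deconv_result(fractions, fit, "cls", list(
    allow_other = allow_other, content_factors = content_factors,
    coverage = h$coverage
  ))
}

#' Marker-score deconvolution baseline
#'
#' Scores each cell type independently from its markers instead of solving a
#' joint regression: every marker is min-max scaled across samples, the mean
#' scaled intensity of a type's markers is its score, and scores are
#' normalized to sum to one per sample. With a single sample (or a marker
#' constant across samples) the min-max scale is degenerate; such markers
#' score 0.5 with a warning, so a lone sample gets uniform fractions.
#'
#' @param bulk Expression tibble of bulk samples.
#' @param markers Marker tibble from [select_fold_markers()] (columns
#'   `cell_type`, `gene`).
#' @return A `cellfrac_deconv` object. Reconstruction fit statistics are not
#'   defined for this engine and are reported as `NA`.
#' @export
deconvolute_marker_score <- function(bulk, markers) {
  check_expr_table(bulk, "bulk")
  if (!is.data.frame(markers) || !all(c("cell_type", "gene") %in% names(markers))) {
    abort_validation("`markers` must have columns `cell_type` and `gene`.")
  }
  B <- expr_to_matrix(bulk)
  types <- unique(markers$cell_type)

  present <- markers$gene %in% rownames(B)
  if (any(!present)) {
    warn(sprintf("%d marker(s) absent from the bulk matrix were dropped.", sum(!present)))
  }
  markers <- markers[present, , drop = FALSE]
  lost <- setdiff(types, unique(markers$cell_type))
  if (length(lost)) {
    abort_validation(sprintf("all markers absent from bulk for cell type(s): %s.",
                             paste(lost, collapse = ", ")))
  }

  rng <- apply(B[unique(markers$gene), , drop = FALSE], 1L, function(v) diff(range(v)))
  if (ncol(B) < 2L || any(rng == 0)) {
    warn("min-max scaling is degenerate for some markers (single sample or constant marker); they score 0.5.")
  }
  scaled <- t(apply(B[unique(markers$gene), , drop = FALSE], 1L, function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(0.5, length(v)) else (v - r[1]) / (r[2] - r[1])
  }))
  if (ncol(B) == 1L) scaled <- matrix(scaled, ncol = 1L, dimnames = list(unique(markers$gene), colnames(B)))

  scores <- vapply(types, function(ct) {
    g <- markers$gene[markers$cell_type == ct]
    colMeans(scaled[g, , drop = FALSE])
  }, numeric(ncol(B)))
  if (ncol(B) == 1L) scores <- matrix(scores, nrow = 1L, dimnames = list(colnames(B), types))

  fr <- t(apply(scores, 1L, function(s) if (sum(s) == 0) rep(1 / length(s), length(s)) else s / sum(s)))
  fractions <- dplyr::bind_cols(
    tibble(sample = colnames(B)),
    as_tibble(fr, .name_repair = ~types)
  )
  fit <- tibble(sample = colnames(B), rmse = NA_real_, pearson = NA_real_)
  new_deconv_result(fractions, fit, "marker_score",
                    list(n_markers = nrow(markers)))
}

#' Reconstruction fit of a fraction estimate
#'
#' Given a bulk sample vector, a signature and estimated fractions, returns
#' the root-mean-square residual of the reconstruction `S %*% f` against the
#' sample, and their Pearson correlation (reported as `NA` when either
#' vector is constant).
#'
#' @param sample_vector Numeric vector (one bulk sample, harmonized to the
#'   signature features).
#' @param sig Signature: matrix, profiles tibble or `cellfrac_signature`.
#' @param fractions Numeric vector of fractions, one per signature column.
#' @return List with `rmse` and `pearson`.
#' @export
reconstruction_stats <- function(sample_vector, sig, fractions) {
  S <- if (is.matrix(sig)) sig else expr_to_matrix(
    if (inherits(sig, "cellfrac_signature")) sig$profiles else sig
  )
  if (length(sample_vector) != nrow(S) || length(fractions) != ncol(S)) {
    abort_validation("dimension mismatch between sample, signature and fractions.")
  }
  if (anyNA(fractions)) return(list(rmse = NA_real_, pearson = NA_real_))
  recon <- drop(S %*% fractions)
  rmse <- sqrt(mean((recon - sample_vector)^2))
  pearson <- if (sd(recon) == 0 || sd(sample_vector) == 0) NA_real_ else cor(recon, sample_vector)
  list(rmse = rmse, pearson = pearson)
}

#' @export
print.cellfrac_deconv <- function(x, ...) {
  cat(sprintf("<cellfrac deconvolution> method = %s | %d sample(s) x %d cell type(s)\n",
              x$method, nrow(x$fractions),
              ncol(x$fractions) - 1L - ("other" %in% names(x$fractions))))
  print(x$fractions, n = 5)
  invisible(x)
}

#' Tidy estimated fractions into long format
#' @param x A `cellfrac_deconv`.
#' @param ... Unused.
#' @return Tibble with columns `sample`, `cell_type`, `fraction`.
#' @exportS3Method generics::tidy
tidy.cellfrac_deconv <- function(x, ...) {
  tidyr::pivot_longer(x$fractions, -"sample",
                      names_to = "cell_type", values_to = "fraction")
}

#' One-row summary of a deconvolution run
#' @param x A `cellfrac_deconv`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cellfrac_deconv <- function(x, ...) {
  tibble(
    method = x$method,
    n_samples = nrow(x$fractions),
    n_cell_types = ncol(x$fractions) - 1L - ("other" %in% names(x$fractions)),
    mean_rmse = mean(x$fit$rmse, na.rm = TRUE),
    mean_pearson = mean(x$fit$pearson, na.rm = TRUE)
  )
}

#' Stacked-bar plot of estimated cell-type fractions
#' @param object A `cellfrac_deconv`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cellfrac_deconv <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$sample, y = .data$fraction,
                               fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Estimated fraction", fill = "Cell type",
                  title = sprintf("Deconvolution (%s)", object$method)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
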