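#' Score estimated fractions against known ground truth
#'
#' For every cell type, the Pearson correlation and root-mean-squared error
#' between estimated and true fractions are computed across mixtures, and
#' their unweighted means over cell types summarize the run. Correlation is
#' undefined for a cell type whose true or estimated fractions are constant;
#' such types get `pearson = NA`, are listed in `excluded_types`, and are
#' left out of `mean_pearson` (their RMSE is still computed and averaged).
#' Fractions are compared on the [0, 1] scale.
#'
#' @param result A `cellfrac_deconv` or a fractions tibble (`sample` + cell
#'   types).
#' @param truth Fractions tibble with the same samples and cell types
#'   (order-insensitive; matched by label). An `other` column in the
#'   estimate is ignored unless present in the truth.
#' @return An object of class `cellfrac_evaluation`: `per_cell_type`
#'   (tibble `cell_type`, `pearson`, `rmse`), `mean_pearson`, `mean_rmse`,
#'   `n_mixtures`, `excluded_types` (tibble `cell_type`, `reason`).
#' @export
evaluate_against_truth <- function(result, truth) {
  est <- if (inherits(result, "cellfrac_deconv")) result$fractions else result
  if (!is.data.frame(est) || names(est)[1] != "sample") {
    abort_validation("`result` must be a deconvolution result or fractions tibble.")
  }
  if (!is.data.frame(truth) || names(truth)[1] != "sample") {
    abort_validation("`truth` must be a fractions tibble (first column `sample`).")
  }
  types_truth <- setdiff(names(truth), "sample")
  types_est <- setdiff(names(est), c("sample", if (!"other" %in% types_truth) "other"))
  if (!setequal(types_truth, types_est)) {
    abort_validation(sprintf(
      "cell-type mismatch. only in truth: %s; only in estimate: %s.",
      paste(setdiff(types_truth, types_est), collapse = ", ") %|e|% "-",
      paste(setdiff(types_est, types_truth), collapse = ", ") %|e|% "-"
    ))
  }
  if (!setequal(truth$sample, est$sample)) {
    abort_validation("sample mismatch between estimate and truth.")
  }
  est <- est[match(truth$sample, est$sample), , drop = FALSE]

  per <- purrr::map_dfr(types_truth, function(ct) {
    e <- est[[ct]]; t_ <- truth[[ct]]
    rmse <- sqrt(mean((e - t_)^2))
    const <- sd(t_) == 0 || is.na(sd(e)) || sd(e) == 0 || anyNA(e)
    tibble(cell_type = ct,
           pearson = if (const) NA_real_ else cor(e, t_),
           rmse = rmse)
  })
  excluded <- dplyr::filter(per, is.na(.data$pearson)) |>
    dplyr::transmute(.data$cell_type, reason = "constant or undefined fraction vector")

  structure(
    list(
      per_cell_type = per,
      mean_pearson = mean(per$pearson, na.rm = TRUE),
      mean_rmse = mean(per$rmse, na.rm = TRUE),
      n_mixtures = nrow(truth),
      excluded_types = excluded
    ),
    class = "cellfrac_evaluation"
  )
}

# "" -> fallback, used for readable error messages
`%|e|%` <- function(x, y) if (identical(x, "")) y else x

#' Purity of deconvoluted pure samples
#'
#' For samples that contain a single expected cell type (e.g. sorted pure
#' populations), reports per sample the estimated fraction of the expected
#' type (the purity) and the largest misassigned type, plus per-type mean
#' purity.
#'
#' @param result A `cellfrac_deconv` or fractions tibble.
#' @param expected_labels Tibble (`sample`, `cell_type`) giving each
#'   sample's expected type, or a named character vector.
#' @return A list with `per_sample` (tibble `sample`, `expected`, `purity`,
#'   `top_misassigned`, `top_misassigned_fraction`) and `per_cell_type`
#'   (tibble `cell_type`, `mean_purity`, `n_samples`).
#' @export
pure_sample_purity <- function(result, expected_labels) {
  est <- if (inherits(result, "cellfrac_deconv")) result$fractions else result
  if (is.character(expected_labels)) {
    expected_labels <- tibble(sample = names(expected_labels),
                              cell_type = unname(expected_labels))
  }
  check_groups(expected_labels, est$sample)
  types <- setdiff(names(est), c("sample", "other"))
  unknown <- setdiff(unique(expected_labels$cell_type), types)
  if (length(unknown)) {
    abort_validation(sprintf("expected label(s) not among result cell types: %s.",
                             paste(unknown, collapse = ", ")))
  }

  per_sample <- purrr::map_dfr(seq_len(nrow(est)), function(i) {
    sn <- est$sample[i]
    exp_ct <- expected_labels$cell_type[match(sn, expected_labels$sample)]
    fr <- unlist(est[i, types])
    mis <- fr[names(fr) != exp_ct]
    top <- if (length(mis)) names(mis)[which.max(mis)] else NA_character_
    tibble(sample = sn, expected = exp_ct, purity = unname(fr[exp_ct]),
           top_misassigned = top,
           top_misassigned_fraction = if (length(mis)) max(mis) else NA_real_)
  })
  per_cell_type <- per_sample |>
    dplyr::group_by(cell_type = .data$expected) |>
    dplyr::summarise(mean_purity = mean(.data$purity), n_samples = dplyr::n(),
                     .groups = "drop")
  list(per_sample = per_sample, per_cell_type = per_cell_type)
}

#' @export
print.cellfrac_evaluation <- function(x, ...) {
  cat(sprintf("<cellfrac evaluation> %d mixtures | mean Pearson = %.3f | mean RMSE = %.4f\n",
              x$n_mixtures, x$mean_pearson, x$mean_rmse))
  print(x$per_cell_type)
  if (nrow(x$excluded_types)) {
    cat("excluded from mean Pearson:", paste(x$excluded_types$cell_type, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-cell-type evaluation table
#' @param x A `cellfrac_evaluation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cellfrac_evaluation <- function(x, ...) x$per_cell_type

#' One-row evaluation summary
#' @param x A `cellfrac_evaluation`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.cellfrac_evaluation <- function(x, ...) {
  tibble(mean_pearson = x$mean_pearson, mean_rmse = x$mean_rmse,
         n_mixtures = x$n_mixtures, n_excluded = nrow(x$excluded_types))
}

#' Per-cell-type Pearson/RMSE bar chart
#' @param object A `cellfrac_evaluation`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cellfrac_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_cell_type, c("pearson", "rmse"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Deconvolution accuracy by cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write an evaluation report as JSON
#' @param x A `cellfrac_evaluation`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(x, path) {
  stopifnot(inherits(x, "cellfrac_evaluation"))
  jsonlite::write_json(
    list(
      mean_pearson = x$mean_pearson, mean_rmse = x$mean_rmse,
      n_mixtures = x$n_mixtures,
      per_cell_type = x$per_cell_type,
      excluded_types = x$excluded_types
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}
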