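#' Draw random ground-truth fraction vectors
#'
#' Each row is a point on the probability simplex over the given cell types.
#' `"dirichlet_uniform"` draws from the flat Dirichlet (all concentration
#' parameters 1), i.e. uniformly over the simplex; `"uniform_renormalized"`
#' draws independent U(0,1) values and divides by their sum, which
#' concentrates mass toward equal fractions.
#'
#' @param cell_types Character vector of cell-type labels.
#' @param n_mixtures Number of mixtures to draw (>= 1).
#' @param sampler `"dirichlet_uniform"` (default) or `"uniform_renormalized"`.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return A tibble with columns `sample` (`mix_001`, ...) and one column per
#'   cell type; every row sums to 1.
#' @export
sample_fractions <- function(cell_types, n_mixtures,
                             sampler = c("dirichlet_uniform", "uniform_renormalized"),
                             seed = NULL) {
  sampler <- match.arg(sampler)
  if (length(cell_types) < 1L) abort_usage("need at least one cell type.")
  if (n_mixtures < 1L) abort_usage("`n_mixtures` must be >= 1.")
  k <- length(cell_types)
  draws <- with_seed_if(seed, {
    if (sampler == "dirichlet_uniform") {
      # flat Dirichlet via normalized unit-rate Gamma draws
      g <- matrix(rgamma(n_mixtures * k, shape = 1), n_mixtures, k)
    } else {
      g <- matrix(runif(n_mixtures * k), n_mixtures, k)
    }
    g / rowSums(g)
  })
  if (k == 1L) draws <- matrix(1, n_mixtures, 1L)
  colnames(draws) <- cell_types
  dplyr::bind_cols(
    tibble(sample = sprintf("mix_%03d", seq_len(n_mixtures))),
    as_tibble(draws)
  )
}

#' Simulate pseudobulk mixtures from pure cell-type replicates
#'
#' Builds artificial bulk proteomes with known composition: for every
#' mixture, one replicate of each cell type is drawn uniformly at random
#' (with replacement across mixtures) from the reference cohort, and the
#' bulk column is the fraction-weighted element-wise sum of the chosen
#' replicate profiles. No per-cell-type scaling factor is applied and no
#' extra noise is added — the biological and technical noise carried by the
#' replicates is the noise model.
#'
#' @param reference Expression tibble of pure cell-type replicates, complete
#'   (no missing values), linear scale.
#' @param groups Groups tibble labelling the reference samples.
#' @param fractions Fractions tibble from [sample_fractions()] (`sample` +
#'   one column per cell type, rows summing to 1).
#' @param seed Integer seed controlling replicate choice.
#' @return An object of class `cellfrac_mixtures`: `bulk` (expression
#'   tibble, one column per mixture), `truth` (the fractions tibble),
#'   `replicate_choices` (tibble `sample`, `cell_type`, `source_sample`) and
#'   `seed`.
#' @export
simulate_mixtures <- function(reference, groups, fractions, seed = NULL) {
  m <- expr_to_matrix(reference)
  if (anyNA(m)) abort_validation("`reference` must have no missing values.")
  labels <- group_vector(groups, colnames(m))
  if (!is.data.frame(fractions) || names(fractions)[1] != "sample") {
    abort_validation("`fractions` must be a tibble with first column `sample`.")
  }
  types <- setdiff(names(fractions), "sample")
  absent <- setdiff(types, unique(labels))
  if (length(absent)) {
    abort_validation(sprintf("cell type(s) absent from the reference: %s.",
                             paste(absent, collapse = ", ")))
  }
  fr <- as.matrix(fractions[, types, drop = FALSE])
  if (any(fr < 0) || any(abs(rowSums(fr) - 1) > 1e-9)) {
    abort_validation("fraction rows must be non-negative and sum to 1.")
  }

  reps_by_type <- split(colnames(m), labels)[types]
  n_mix <- nrow(fractions)
  choices <- with_seed_if(seed, {
    vapply(types, function(ct) {
      pool <- reps_by_type[[ct]]
      pool[sample.int(length(pool), n_mix, replace = TRUE)]
    }, character(n_mix)) |> matrix(nrow = n_mix, ncol = length(types),
                                   dimnames = list(NULL, types))
  })

  bulk <- vapply(seq_len(n_mix), function(i) {
    cols <- m[, choices[i, ], drop = FALSE]
    drop(cols %*% fr[i, ])
  }, numeric(nrow(m)))
  colnames(bulk) <- fractions$sample
  rownames(bulk) <- rownames(m)

  structure(
    list(
      bulk = matrix_to_expr(bulk),
      truth = fractions,
      replicate_choices = tibble(
        sample = rep(fractions$sample, times = length(types)),
        cell_type = rep(types, each = n_mix),
        source_sample = as.vector(choices)
      ),
      seed = seed
    ),
    class = "cellfrac_mixtures"
  )
}

#' @export
print.cellfrac_mixtures <- function(x, ...) {
  cat(sprintf("<cellfrac mixtures> %d mixture(s) x %d cell type(s), %d features\n",
              nrow(x$truth), ncol(x$truth) - 1L, nrow(x$bulk)))
  invisible(x)
}
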