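# A well-conditioned random signature plus exact mixtures of it.
random_signature <- function(k = 4, n_feat = 60, seed = 21) {
  withr::with_seed(seed, {
    S <- matrix(2^stats::rnorm(n_feat * k, mean = 8, sd = 1.5), n_feat, k)
  })
  colnames(S) <- paste0("C", seq_len(k))
  rownames(S) <- sprintf("G%03d", seq_len(n_feat))
  S
}

mix_bulk <- function(S, fracs) {
  b <- S %*% t(fracs)
  colnames(b) <- rownames(fracs) %||% sprintf("m%d", seq_len(nrow(fracs)))
  b
}

`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("feature harmonization intersects by identifier and reports coverage", {
  S <- random_signature()
  sig <- expr_tbl(S, genes = rownames(S), samples = colnames(S))
  bulk <- expr_tbl(S[, 1, drop = FALSE], genes = rownames(S), samples = "b1")

  h <- harmonize_features(bulk, sig)
  expect_equal(h$coverage, 1)
  expect_equal(h$sig$gene, h$bulk$gene)

  half <- bulk[seq_len(nrow(bulk) / 2), ]
  h2 <- harmonize_features(half, sig)
  expect_equal(h2$coverage, 0.5)
  expect_equal(nrow(h2$sig), nrow(S) / 2)

  disjoint <- expr_tbl(matrix(1, 2, 1), genes = c("X1", "X2"))
  expect_error(harmonize_features(disjoint, sig), class = "cellfrac_validation_error")
})

test_that("constrained least squares recovers exact convex mixtures", {
  S <- random_signature(k = 5, n_feat = 80)
  fr <- withr::with_seed(3, {
    g <- matrix(stats::rgamma(20 * 5, 1), 20, 5); g / rowSums(g)
  })
  bulk <- expr_tbl(mix_bulk(S, fr), genes = rownames(S))
  sig <- expr_tbl(S, genes = rownames(S), samples = colnames(S))

  res <- deconvolute_cls(bulk, sig)
  est <- as.matrix(res$fractions[, colnames(S)])
  expect_lt(max(abs(est - fr)), 1e-6)
  expect_rows_sum_to_one(res$fractions)
  expect_true(all(res$fit$rmse < 1e-6))
})

test_that("cls handles vertex, other-fraction and KKT edge cases", {
  S <- random_signature(k = 3)
  sig <- expr_tbl(S, genes = rownames(S), samples = colnames(S))

  # pure sample -> vertex solution
  pure <- expr_tbl(S[, 2, drop = FALSE], genes = rownames(S), samples = "p")
  res <- deconvolute_cls(pure, sig)
  expect_equal(unlist(res$fractions[1, -1], use.names = FALSE), c(0, 1, 0),
               tolerance = 1e-8)

  # half-intensity pure sample with other allowed: f = [0.5, 0, 0], other 0.5
  half <- expr_tbl(0.5 * S[, 1, drop = FALSE], genes = rownames(S), samples = "h")
  res2 <- deconvolute_cls(half, sig, allow_other = TRUE)
  expect_equal(res2$fractions$C1, 0.5, tolerance = 1e-8)
  expect_equal(res2$fractions$other, 0.5, tolerance = 1e-8)
  expect_equal(res2$fractions$C2 + res2$fractions$C3, 0, tolerance = 1e-8)

  # scale equivariance without other
  big <- expr_tbl(3.7 * S[, 2, drop = FALSE], genes = rownames(S), samples = "b")
  res3 <- deconvolute_cls(big, sig)
  expect_equal(unlist(res3$fractions[1, -1], use.names = FALSE),
               unlist(res$fractions[1, -1], use.names = FALSE), tolerance = 1e-8)
})

test_that("content-factor correction is a no-op at ones and reweights otherwise", {
  S <- random_signature(k = 3)
  sig <- expr_tbl(S, genes = rownames(S), samples = colnames(S))
  fr <- matrix(c(0.2, 0.3, 0.5), 1)
  bulk <- expr_tbl(mix_bulk(S, fr), genes = rownames(S))

  plain <- deconvolute_cls(bulk, sig)
  ones <- deconvolute_cls(bulk, sig, content_factors = c(C1 = 1, C2 = 1, C3 = 1))
  expect_equal(plain$fractions, ones$fractions, tolerance = 1e-9)

  r <- c(C1 = 2, C2 = 1, C3 = 0.5)
  corr <- deconvolute_cls(bulk, sig, content_factors = r)
  expected <- (fr / r) / sum(fr / r)
  expect_equal(unlist(corr$fractions[1, -1], use.names = FALSE),
               as.vector(expected), tolerance = 1e-6)

  expect_error(deconvolute_cls(bulk, sig, content_factors = c(C1 = 1)),
               class = "cellfrac_usage_error")
})

test_that("permuting signature columns permutes cls results identically", {
  S <- random_signature(k = 4)
  sig <- expr_tbl(S, genes = rownames(S), samples = colnames(S))
  sig_perm <- sig[, c("gene", "C3", "C1", "C4", "C2")]
  fr <- matrix(c(0.1, 0.2, 0.3, 0.4), 1)
  bulk <- expr_tbl(mix_bulk(S, fr), genes = rownames(S))

  a <- deconvolute_cls(bulk, sig)$fractions
  b <- deconvolute_cls(bulk, sig_perm)$fractions
  expect_equal(b[names(a)], a, tolerance = 1e-9)
})

test_that("nu-SVR recovers pure and balanced two-component mixtures", {
  ref <- block_reference(k = 3, reps = 2, block = 8, background = 16,
                         high = 900, low = 1)
  sig_mat <- vapply(ref$types, function(ct) {
    rowMeans(as.matrix(ref$expression[-1])[, ref$groups$cell_type == ct])
  }, numeric(nrow(ref$expression)))
  rownames(sig_mat) <- ref$expression$gene
  sig <- expr_tbl(sig_mat, genes = rownames(sig_mat), samples = colnames(sig_mat))

  pure <- expr_tbl(sig_mat[, 1, drop = FALSE], genes = rownames(sig_mat))
  res <- deconvolute_nusvr(pure, sig, seed = 1)
  expect_gte(res$fractions$T1[1], 0.99)
  expect_lte(max(res$fractions$T2[1], res$fractions$T3[1]), 0.01)
  expect_rows_sum_to_one(res$fractions)

  fifty <- expr_tbl(0.5 * sig_mat[, 1] + 0.5 * sig_mat[, 2],
                    genes = rownames(sig_mat))
  res2 <- deconvolute_nusvr(fifty, sig, seed = 1)
  expect_equal(res2$fractions$T1[1], 0.5, tolerance = 0.02)
  expect_equal(res2$fractions$T2[1], 0.5, tolerance = 0.02)

  # cross-check against the independent constrained-regression engine
  oracle <- deconvolute_cls(fifty, sig)
  expect_equal(unlist(res2$fractions[1, -1], use.names = FALSE),
               unlist(oracle$fractions[1, -1], use.names = FALSE),
               tolerance = 0.02)
})

test_that("nu-SVR flags degenerate samples instead of guessing", {
  S <- random_signature(k = 3)
  sig <- expr_tbl(S, genes = rownames(S), samples = colnames(S))
  flat <- expr_tbl(matrix(5, nrow(S), 1), genes = rownames(S), samples = "flat")
  res <- deconvolute_nusvr(flat, sig, seed = 1)
  expect_true("flat" %in% res$parameters$failed_samples)
  expect_true(all(is.na(res$fractions[1, -1])))
})

test_that("marker scoring ranks samples by scaled marker intensity", {
  # two samples: sample 1 maximizes all A markers, minimizes all B markers
  m <- rbind(c(10, 2), c(8, 1), c(1, 5), c(2, 9))
  x <- expr_tbl(m, genes = c("a1", "a2", "b1", "b2"), samples = c("S1", "S2"))
  markers <- tibble::tibble(cell_type = c("A", "A", "B", "B"),
                            gene = c("a1", "a2", "b1", "b2"))
  res <- deconvolute_marker_score(x, markers)
  expect_equal(unlist(res$fractions[1, c("A", "B")], use.names = FALSE), c(1, 0))
  expect_equal(unlist(res$fractions[2, c("A", "B")], use.names = FALSE), c(0, 1))
  expect_rows_sum_to_one(res$fractions)

  # single sample: degenerate min-max -> uniform with a warning
  single <- x[, 1:2]
  expect_warning(res1 <- deconvolute_marker_score(single, markers), "degenerate")
  expect_equal(unlist(res1$fractions[1, c("A", "B")], use.names = FALSE), c(0.5, 0.5))

  # absent markers: dropped with warning, all-absent type errors
  markers_extra <- dplyr::bind_rows(markers,
                                    tibble::tibble(cell_type = "A", gene = "zz"))
  expect_warning(deconvolute_marker_score(x, markers_extra), "dropped")
  markers_bad <- tibble::tibble(cell_type = c("A", "C"), gene = c("a1", "nope"))
  expect_error(suppressWarnings(deconvolute_marker_score(x, markers_bad)),
               class = "cellfrac_validation_error")
})

test_that("reconstruction statistics behave at the edges", {
  S <- random_signature(k = 2, n_feat = 10)
  f <- c(0.4, 0.6)
  y <- drop(S %*% f)
  st <- reconstruction_stats(y, S, f)
  expect_equal(st$rmse, 0, tolerance = 1e-10)
  expect_equal(st$pearson, 1, tolerance = 1e-10)

  st0 <- reconstruction_stats(y, S, c(0, 0))
  expect_equal(st0$rmse, sqrt(mean(y^2)))
  expect_true(is.na(st0$pearson))

  stc <- reconstruction_stats(rep(1, 10), S, f)
  expect_true(is.finite(stc$rmse))

  expect_error(reconstruction_stats(y[1:3], S, f), class = "cellfrac_validation_error")
})

test_that("the deconvolute front door dispatches and rejects unknown methods", {
  S <- random_signature(k = 2, n_feat = 20)
  sig <- expr_tbl(S, genes = rownames(S), samples = colnames(S))
  bulk <- expr_tbl(S[, 1, drop = FALSE], genes = rownames(S), samples = "b")
  expect_s3_class(deconvolute(bulk, sig, "cls"), "cellfrac_deconv")
  expect_error(deconvolute(bulk, sig, "magic"), class = "cellfrac_usage_error")
})
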