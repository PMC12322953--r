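make_pg <- function(group_id, gene_symbol, ...) {
  out <- tibble::tibble(group_id = group_id, gene_symbol = gene_symbol, ...)
  attr(out, "group_delimiter") <- ";"
  out
}

test_that("protein groups collapse to the first listed symbol or accession", {
  pg <- make_pg(c("P01;P02", "P10"), c("MS4A1;MS4A1B", NA),
                S1 = c(1, 2), S2 = c(3, 4))
  out <- collapse_protein_groups(pg)
  expect_equal(out$gene, c("MS4A1", "P10"))
  expect_equal(out$S1, c(1, 2))   # intensities untouched

  bad <- make_pg(c("P01", ""), c(NA, NA), S1 = c(1, 2))
  expect_error(collapse_protein_groups(bad), class = "cellfrac_validation_error")
})

test_that("slice keeps the highest-median duplicate, merge sums them", {
  x <- expr_tbl(rbind(c(1, 2, 3), c(10, 20, 30), c(5, 5, 5)),
                genes = c("G", "G", "H"), samples = c("S1", "S2", "S3"))
  sliced <- dedupe_features(x, "slice")
  expect_equal(sliced$gene, c("G", "H"))
  expect_equal(unlist(sliced[1, -1], use.names = FALSE), c(10, 20, 30))

  merged <- dedupe_features(x, "merge")
  expect_equal(unlist(merged[1, -1], use.names = FALSE), c(11, 22, 33))

  expect_error(dedupe_features(x, "unknown"), class = "cellfrac_usage_error")
})

test_that("merge treats missing as absent and conserves observed totals", {
  x <- expr_tbl(rbind(c(1, NA, NA), c(2, 5, NA)), genes = c("G", "G"))
  merged <- dedupe_features(x, "merge")
  expect_equal(unlist(merged[1, -1], use.names = FALSE), c(3, 5, NA))
  expect_equal(sum(merged[, -1], na.rm = TRUE),
               sum(x[, -1], na.rm = TRUE))  # intensity conserved

  unique_x <- expr_tbl(matrix(1:4, 2))
  expect_identical(dedupe_features(unique_x, "slice"), unique_x)
  expect_identical(dedupe_features(unique_x, "merge"), unique_x)
})

test_that("slice ties keep the first-occurring row", {
  x <- expr_tbl(rbind(c(7, 1, 2), c(2, 1, 7)), genes = c("G", "G"))
  out <- dedupe_features(x, "slice")
  expect_equal(unlist(out[1, -1], use.names = FALSE), c(7, 1, 2))
})

test_that("minimum imputation fills gaps with the observed minimum", {
  x <- expr_tbl(rbind(c(1, NA), c(4, 2)))
  out <- impute_missing(x, "min")
  expect_equal(out$S2[1], 1)  # global observed minimum
  expect_false(anyNA(out[-1]))

  per_sample <- impute_missing(x, "min", cfg = preprocess_config(min_scope = "sample"))
  expect_equal(per_sample$S2[1], 2)

  complete <- expr_tbl(matrix(1:4, 2))
  for (m in c("min", "knn", "rf")) {
    expect_identical(impute_missing(complete, m, seed = 1), complete)
  }
  all_na <- expr_tbl(matrix(NA_real_, 2, 2))
  expect_error(impute_missing(all_na, "min"), class = "cellfrac_validation_error")
})

test_that("kNN imputation averages the k nearest features in the gap's sample", {
  # F1 has a gap in S3; F2 and F3 are its close neighbours, F4 is distant.
  m <- rbind(
    c(10, 10, NA),
    c(10, 10, 8),
    c(10, 10, 12),
    c(1000, 1000, 1000)
  )
  x <- expr_tbl(m, genes = paste0("F", 1:4))
  out <- impute_missing(x, "knn", cfg = preprocess_config(knn_k = 2))
  expect_equal(out$S3[1], mean(c(8, 12)))
  expect_equal(out$S1, x$S1)  # observed entries unchanged
})

test_that("imputation never alters observed entries", {
  coh <- small_cohort(seed = 7, n_features = 60, markers_per_type = 5,
                      n_cell_types = 3, n_replicates = 3)
  gappy <- inject_missingness(coh$expression, coh$cfg, seed = 8)
  obs <- !is.na(as.matrix(gappy[-1]))
  for (m in c("min", "knn", "rf")) {
    out <- impute_missing(gappy, m, cfg = preprocess_config(rf_trees = 20), seed = 9)
    expect_false(anyNA(out[-1]))
    expect_equal(as.matrix(out[-1])[obs], as.matrix(gappy[-1])[obs])
  }
})

test_that("rf imputation is deterministic given a seed", {
  coh <- small_cohort(seed = 3, n_features = 40, markers_per_type = 4,
                      n_cell_types = 3, n_replicates = 3)
  gappy <- inject_missingness(coh$expression, coh$cfg, seed = 4)
  cfg <- preprocess_config(rf_trees = 20)
  a <- impute_missing(gappy, "rf", cfg = cfg, seed = 11)
  b <- impute_missing(gappy, "rf", cfg = cfg, seed = 11)
  expect_identical(a, b)
})

test_that("quantile normalization equalizes log2 distributions", {
  x <- expr_tbl(cbind(c(1, 2, 3), c(4, 5, 6)))
  out <- normalize_intensities(x, "quantile")
  # rank means are taken on log2 values, so the common column is the
  # geometric mean of rank-matched values: sqrt(1*4), sqrt(2*5), sqrt(3*6)
  expected <- sqrt(c(4, 10, 18))
  expect_equal(out$S1, expected, tolerance = 1e-12)
  expect_equal(out$S2, expected, tolerance = 1e-12)

  # property: output columns share one value multiset
  coh <- small_cohort(seed = 5, n_features = 80, markers_per_type = 8,
                      n_cell_types = 3, n_replicates = 3)
  q <- normalize_intensities(coh$expression, "quantile")
  qm <- as.matrix(q[-1])
  ref_sorted <- sort(qm[, 1])
  for (j in 2:ncol(qm)) expect_equal(sort(qm[, j]), ref_sorted, tolerance = 1e-9)
})

test_that("cyclic loess leaves identical columns unchanged and none is identity", {
  x <- expr_tbl(cbind(c(1, 2, 3), c(1, 2, 3)))
  out <- normalize_intensities(x, "cyclic_loess")
  expect_equal(as.matrix(out[-1]), as.matrix(x[-1]), tolerance = 1e-9)

  expect_identical(normalize_intensities(x, "none"), x)
  gap <- expr_tbl(rbind(c(1, NA), c(2, 3)))
  expect_error(normalize_intensities(gap, "quantile"),
               class = "cellfrac_validation_error")
  expect_error(normalize_intensities(x, "banana"), class = "cellfrac_usage_error")
})

test_that("total scaling hits the target exactly and is idempotent", {
  x <- expr_tbl(matrix(c(1, 1, 2), 3, 1))
  out <- scale_to_total(x, 1e6)
  expect_equal(out$S1, c(250000, 250000, 500000))

  again <- scale_to_total(out, 1e6)
  expect_equal(again, out, tolerance = 1e-12)

  zero <- expr_tbl(matrix(0, 2, 1))
  expect_error(scale_to_total(zero), class = "cellfrac_validation_error")
})

test_that("the pipeline composes the stage postconditions", {
  pg <- make_protein_group_fixture(seed = 2)
  out <- preprocess_pipeline(pg, preprocess_config(), seed = 1, quiet = TRUE)
  expect_false(anyNA(out[-1]))
  expect_false(anyDuplicated(out$gene) > 0)
  expect_equal(unname(colSums(out[-1])), rep(1e6, ncol(out) - 1), tolerance = 1e-6)

  # with quantile normalization the columns share a distribution up to tie
  # averaging (the imputed minima are tied), so compare above the tied ranks
  qout <- preprocess_pipeline(pg, preprocess_config(normalization = "quantile"),
                              seed = 1, quiet = TRUE)
  qm <- as.matrix(qout[-1])
  upper <- -(1:5)
  for (j in 2:ncol(qm)) {
    expect_equal(sort(qm[, j])[upper], sort(qm[, 1])[upper], tolerance = 0.01)
  }

  expect_error(preprocess_config(impute_method = "magic"))
})
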