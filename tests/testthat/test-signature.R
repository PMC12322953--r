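test_that("marker ranking matches an independent Welch t + BH oracle", {
  ref <- block_reference(k = 3, reps = 4, block = 3, background = 8, sd = 0.05)
  got <- rank_markers(ref$expression, ref$groups, q_threshold = 0.01)

  # independent oracle: per-feature stats::t.test of type vs rest on log2
  m <- log2(as.matrix(ref$expression[-1]))
  rownames(m) <- ref$expression$gene
  labels <- ref$groups$cell_type[match(colnames(m), ref$groups$sample)]
  for (ct in ref$types) {
    p_oracle <- apply(m, 1, function(v) {
      tryCatch(stats::t.test(v[labels == ct], v[labels != ct])$p.value,
               error = function(e) NA_real_)
    })
    lfc <- rowMeans(m[, labels == ct]) - rowMeans(m[, labels != ct])
    q_oracle <- stats::p.adjust(p_oracle, "BH")
    expected <- names(sort(lfc[which(q_oracle < 0.01 & lfc > 0)], decreasing = TRUE))
    expect_equal(got$gene[got$cell_type == ct], expected)
    sub <- got[got$cell_type == ct, ]
    expect_equal(sub$q_value, unname(q_oracle[sub$gene]), tolerance = 1e-10)
  }
})

test_that("a strong planted marker ranks first at q < 0.01", {
  ref <- block_reference(k = 2, reps = 4, block = 1, background = 30,
                         high = 100, low = 1, sd = 0.015)
  got <- rank_markers(ref$expression, ref$groups)
  top_a <- got[got$cell_type == "T1", ][1, ]
  expect_equal(top_a$gene, "G001")
  expect_lt(top_a$q_value, 0.01)
})

test_that("constant features are never candidates and small groups error", {
  ref <- block_reference(k = 2, reps = 3, block = 2, background = 5, sd = 0.1)
  const_id <- ref$expression$gene[nrow(ref$expression)]
  x <- ref$expression
  x[x$gene == const_id, -1] <- 50  # exactly constant everywhere
  got <- rank_markers(x, ref$groups)
  expect_false(const_id %in% got$gene)

  lone <- ref$groups
  lone$cell_type[lone$sample == "T1_r1"] <- "T9"
  expect_error(rank_markers(ref$expression, lone),
               class = "cellfrac_validation_error")
})

test_that("raising the q threshold never shrinks candidate lists", {
  ref <- block_reference(k = 3, reps = 3, block = 3, background = 20, sd = 0.3)
  strict <- rank_markers(ref$expression, ref$groups, q_threshold = 0.005)
  loose <- rank_markers(ref$expression, ref$groups, q_threshold = 0.05)
  for (ct in ref$types) {
    expect_true(all(strict$gene[strict$cell_type == ct] %in%
                      loose$gene[loose$cell_type == ct]))
  }
})

test_that("disjoint equal-magnitude marker blocks give a condition number of 1", {
  ref <- block_reference(k = 2, reps = 2, block = 3, background = 0,
                         high = 100, low = 0)
  sig <- suppressWarnings(
    build_signature(ref$expression, ref$groups,
                    signature_config(g_min = 3, g_max = 3, q_threshold = 0.05))
  )
  expect_equal(sig$condition_number, 1, tolerance = 1e-9)
  profiles <- as.matrix(sig$profiles[-1])
  expect_equal(unname(crossprod(profiles))[1, 2], 0)  # orthogonal columns
})

test_that("the sweep picks the condition-number-minimizing G", {
  coh <- small_cohort(seed = 11, n_features = 300, markers_per_type = 30,
                      n_cell_types = 4, n_replicates = 4)
  cfg <- signature_config(g_min = 5, g_max = 25, q_threshold = 0.01)
  sig <- build_signature(coh$expression, coh$groups, cfg)
  expect_true(sig$chosen_g >= 5 && sig$chosen_g <= 25)

  # exhaustive oracle over the same sweep
  expect_equal(sig$condition_number, min(sig$sweep$condition_number))
  expect_true(all(sig$sweep$condition_number >= sig$condition_number))

  # self-consistency: reported value equals an independent SVD-based check
  expect_equal(sig$condition_number,
               kappa(as.matrix(sig$profiles[-1]), exact = TRUE),
               tolerance = 1e-9)

  # degenerate single-point sweep takes exactly top-G per type
  one <- build_signature(coh$expression, coh$groups,
                         signature_config(g_min = 10, g_max = 10))
  expect_equal(one$chosen_g, 10L)
  expect_true(nrow(one$profiles) <= 10 * 4)
})

test_that("signatures round-trip through TSV + JSON sidecar", {
  ref <- block_reference(k = 2, reps = 3, block = 3, background = 6, sd = 0.1)
  sig <- suppressWarnings(
    build_signature(ref$expression, ref$groups,
                    signature_config(g_min = 2, g_max = 4, q_threshold = 0.05))
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$profiles, sig$profiles, tolerance = 1e-10)
  expect_equal(back$chosen_g, sig$chosen_g)
  expect_equal(back$condition_number, sig$condition_number, tolerance = 1e-10)
})

test_that("fold-change marker selection applies both thresholds strictly", {
  # three types, one feature per rule case
  m <- rbind(
    c(3000, 3000, 1000, 1000, 500, 500),   # exactly 3-fold, >1000 -> marker
    c(900, 900, 1, 1, 1, 1),               # fails min expression
    c(5000, 5000, 0, 0, 0, 0),             # zero elsewhere -> infinite fold
    c(2999, 2999, 1000, 1000, 1000, 1000)  # just under 3-fold -> excluded
  )
  x <- expr_tbl(m, genes = c("EXACT", "LOW", "INF", "UNDER"))
  groups <- tibble::tibble(sample = paste0("S", 1:6),
                           cell_type = rep(c("A", "B", "C"), each = 2))
  mk <- suppressWarnings(select_fold_markers(x, groups))
  a <- mk[mk$cell_type == "A", ]
  expect_setequal(a$gene, c("EXACT", "INF"))
  expect_equal(a$fold_change[a$gene == "EXACT"], 3)
  expect_equal(a$fold_change[a$gene == "INF"], Inf)
})

test_that("fold markers are invariant to joint rescaling of data and threshold", {
  ref <- block_reference(k = 3, reps = 3, block = 3, background = 10,
                         high = 5000, low = 10, sd = 0.2)
  mk1 <- suppressWarnings(select_fold_markers(ref$expression, ref$groups,
                                              min_expression = 1000))
  scaled <- ref$expression
  scaled[-1] <- scaled[-1] * 10
  mk2 <- suppressWarnings(select_fold_markers(scaled, ref$groups,
                                              min_expression = 10000))
  expect_equal(mk1[c("cell_type", "gene", "fold_change")],
               mk2[c("cell_type", "gene", "fold_change")])
})
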