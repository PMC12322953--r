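# Shared in-code fixtures. Everything is generated at test time; nothing is
# stored on disk.

# Minimal expression tibble from a features x samples matrix definition.
expr_tbl <- function(values, genes = NULL, samples = NULL) {
  m <- as.matrix(values)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  dplyr::bind_cols(tibble::tibble(gene = genes), tibble::as_tibble(m))
}

# Tiny labelled reference: `k` cell types x `reps` replicates, each type with
# a disjoint block of `block` high markers over a low background. Noise-free
# unless `sd` > 0.
block_reference <- function(k = 3, reps = 3, block = 4, background = 10,
                            high = 1000, low = 1, sd = 0, seed = 42) {
  types <- paste0("T", seq_len(k))
  sample_type <- rep(types, each = reps)
  samples <- as.vector(vapply(types, function(t) paste0(t, "_r", seq_len(reps)),
                              character(reps)))
  n_feat <- k * block + background
  m <- matrix(low, n_feat, length(samples))
  for (i in seq_len(k)) {
    rows <- ((i - 1) * block + 1):(i * block)
    m[rows, sample_type == types[i]] <- high
  }
  if (sd > 0) {
    withr::with_seed(seed, m <- m * 2^matrix(stats::rnorm(length(m), sd = sd),
                                             nrow(m), ncol(m)))
  }
  list(
    expression = expr_tbl(m, samples = samples),
    groups = tibble::tibble(sample = samples, cell_type = sample_type),
    types = types
  )
}

# Small synthetic cohort used by several acceptance-style checks.
small_cohort <- function(seed = 1, n_cell_types = 7, n_features = 400,
                         markers_per_type = 40, n_replicates = 4, ...) {
  cfg <- cellfrac::synth_config(
    n_cell_types = n_cell_types, n_features = n_features,
    markers_per_type = markers_per_type, n_replicates = n_replicates,
    seed = seed, ...
  )
  c(cellfrac::generate_reference_cohort(cfg), list(cfg = cfg))
}

expect_rows_sum_to_one <- function(fractions, tol = 1e-9) {
  num <- as.matrix(fractions[setdiff(names(fractions), "sample")])
  expect_true(all(abs(rowSums(num) - 1) < tol))
}
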