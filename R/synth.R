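#' Synthetic reference-cohort configuration
#'
#' Parameters of the generative model used for testing and benchmarking
#' without real data. Intensities are log-normal: the log2 intensity of
#' feature i in a replicate of cell type c is Normal(`base_log2_mean` +
#' `marker_log2_shift` * \[i is a marker of c\], `log2_sd`), exponentiated to
#' linear scale. Defaults give a ~16-fold marker enrichment over a
#' background of ~1000 (2^10) with ~30% CV, in the range typical for MS
#' protein intensities after total-intensity scaling.
#'
#' @param n_cell_types Number of cell types (>= 2).
#' @param n_features Total number of features.
#' @param markers_per_type Cell-type-specific markers per type
#'   (`markers_per_type * n_cell_types <= n_features`).
#' @param n_replicates Replicates per cell type (>= 2).
#' @param base_log2_mean Centre of the per-feature baseline log2 intensities
#'   (default 10).
#' @param feature_log2_sd Between-feature spread of baseline log2 intensity
#'   (default 2, i.e. a dynamic range of roughly four orders of magnitude
#'   across features, as in real proteomes).
#' @param log2_sd Replicate-to-replicate log2 standard deviation (default 0.4).
#' @param marker_log2_shift Additive log2 shift of a marker in its own type
#'   (default 4, i.e. 16-fold).
#' @param missing_rate_at_low Missingness probability plateau for the lowest
#'   intensities, in \[0, 1\] (default 0.4).
#' @param mnar_steepness Slope of the logistic intensity-dependence of
#'   missingness (default 1).
#' @param seed Integer seed.
#' @return A list of class `cellfrac_synth_config`.
#' @export
synth_config <- function(n_cell_types = 7L, n_features = 3000L,
                         markers_per_type = 300L, n_replicates = 4L,
                         base_log2_mean = 10, feature_log2_sd = 2,
                         log2_sd = 0.4,
                         marker_log2_shift = 4,
                         missing_rate_at_low = 0.4, mnar_steepness = 1,
                         seed = 1L) {
  cfg <- list(
    n_cell_types = as.integer(n_cell_types),
    n_features = as.integer(n_features),
    markers_per_type = as.integer(markers_per_type),
    n_replicates = as.integer(n_replicates),
    base_log2_mean = base_log2_mean, feature_log2_sd = feature_log2_sd,
    log2_sd = log2_sd,
    marker_log2_shift = marker_log2_shift,
    missing_rate_at_low = missing_rate_at_low,
    mnar_steepness = mnar_steepness,
    seed = as.integer(seed)
  )
  if (cfg$n_cell_types < 2L) abort_validation("need at least 2 cell types.")
  if (cfg$n_replicates < 2L) abort_validation("need at least 2 replicates per type.")
  if (cfg$markers_per_type * cfg$n_cell_types > cfg$n_features) {
    abort_validation("markers_per_type * n_cell_types must not exceed n_features.")
  }
  if (cfg$missing_rate_at_low < 0 || cfg$missing_rate_at_low > 1) {
    abort_validation("`missing_rate_at_low` must be in [0, 1].")
  }
  class(cfg) <- "cellfrac_synth_config"
  cfg
}

#' Generate a synthetic pure-cell-type reference cohort
#'
#' Features are partitioned into one marker block per cell type plus a
#' shared background. Every feature gets a baseline log2 mean drawn once
#' from Normal(`base_log2_mean`, `feature_log2_sd`) — shared by all cell
#' types, giving the wide between-protein dynamic range of real proteomes —
#' and markers add `marker_log2_shift` in their own type; replicate noise is
#' Normal(0, `log2_sd`) on log2 scale. Output is complete (inject gaps with
#' [inject_missingness()]) and byte-deterministic given the seed.
#'
#' @param cfg A [synth_config()].
#' @return A list with `expression` (expression tibble, samples named
#'   `<type>_r<j>`), `groups` (groups tibble) and `marker_truth` (tibble
#'   `gene`, `cell_type` for the planted markers; background features are
#'   absent).
#' @export
generate_reference_cohort <- function(cfg = synth_config()) {
  if (!inherits(cfg, "cellfrac_synth_config")) {
    abort_usage("`cfg` must come from synth_config().")
  }
  types <- paste0("type", LETTERS[seq_len(cfg$n_cell_types)])
  genes <- sprintf("G%05d", seq_len(cfg$n_features))
  marker_of <- rep(NA_character_, cfg$n_features)
  marker_of[seq_len(cfg$markers_per_type * cfg$n_cell_types)] <-
    rep(types, each = cfg$markers_per_type)

  samples <- as.vector(vapply(types, function(ct) {
    paste0(ct, "_r", seq_len(cfg$n_replicates))
  }, character(cfg$n_replicates)))
  sample_type <- rep(types, each = cfg$n_replicates)

  m <- with_seed_if(cfg$seed, {
    baseline <- rnorm(cfg$n_features, mean = cfg$base_log2_mean,
                      sd = cfg$feature_log2_sd)
    mu <- outer(baseline, rep(0, length(samples)), "+")
    for (j in seq_along(samples)) {
      shift <- !is.na(marker_of) & marker_of == sample_type[j]
      mu[shift, j] <- mu[shift, j] + cfg$marker_log2_shift
    }
    2^(mu + matrix(rnorm(length(mu), sd = cfg$log2_sd), nrow(mu), ncol(mu)))
  })
  dimnames(m) <- list(genes, samples)

  list(
    expression = matrix_to_expr(m),
    groups = tibble(sample = samples, cell_type = sample_type),
    marker_truth = tibble(gene = genes[!is.na(marker_of)],
                          cell_type = marker_of[!is.na(marker_of)])
  )
}

#' Inject intensity-dependent (MNAR) missingness
#'
#' Models the left-censoring typical of MS intensities: an entry with linear
#' value x is set missing with probability
#' `missing_rate_at_low * plogis(-mnar_steepness * (log2(x) - q10))`, where
#' `q10` is the 10th percentile of the matrix's log2 values — so the lowest
#' intensities approach the plateau rate while abundant proteins are rarely
#' lost.
#'
#' @param x A complete expression tibble.
#' @param cfg A [synth_config()] supplying `missing_rate_at_low` and
#'   `mnar_steepness`.
#' @param seed Integer seed (defaults to `cfg$seed`).
#' @return The expression tibble with `NA`s injected.
#' @export
inject_missingness <- function(x, cfg = synth_config(), seed = cfg$seed) {
  m <- expr_to_matrix(x)
  if (anyNA(m)) abort_validation("`x` must be complete before injecting missingness.")
  if (cfg$missing_rate_at_low == 0) return(x)
  lg <- log2(pmax(m, .Machine$double.xmin))
  q10 <- quantile(lg, 0.10)
  p <- cfg$missing_rate_at_low * plogis(-cfg$mnar_steepness * (lg - q10))
  drop_mask <- with_seed_if(seed, matrix(runif(length(p)) < p, nrow(p), ncol(p)))
  m[drop_mask] <- NA_real_
  matrix_to_expr(m)
}

# closed-form expected missing fraction of the MNAR model on a given matrix
expected_missing_fraction <- function(x, cfg) {
  lg <- log2(pmax(expr_to_matrix(x), .Machine$double.xmin))
  q10 <- quantile(lg, 0.10)
  mean(cfg$missing_rate_at_low * plogis(-cfg$mnar_steepness * (lg - q10)))
}

#' Small protein-group table exercising every preprocessing branch
#'
#' Builds a ~30-row protein-group tibble containing multi-accession groups,
#' duplicated gene symbols (to exercise slice/merge deduplication), missing
#' cells and a zero intensity, then writes and re-reads nothing — it is an
#' in-memory fixture generator for tests and examples.
#'
#' @param seed Integer seed.
#' @param n_samples Number of intensity columns (default 4).
#' @return A protein-group tibble as returned by [read_protein_groups()].
#' @export
make_protein_group_fixture <- function(seed = 1L, n_samples = 4L) {
  n <- 30L
  with_seed_if(seed, {
    group_id <- sprintf("P%05d", seq_len(n))
    gene <- sprintf("GENE%02d", seq_len(n))
    # multi-accession groups with multi-symbol genes
    multi <- 1:6
    group_id[multi] <- paste(group_id[multi], sprintf("Q%05d", multi), sep = ";")
    gene[multi] <- paste(gene[multi], paste0(gene[multi], "B"), sep = ";")
    # duplicated symbols: rows 7/8 and 9/10 collapse to the same gene
    gene[8] <- gene[7]
    gene[10] <- gene[9]
    # a row with no gene symbol at all
    gene[11] <- NA_character_

    out <- tibble(group_id = group_id, gene_symbol = gene)
    for (j in seq_len(n_samples)) {
      v <- round(2^rnorm(n, mean = 10, sd = 1), 2)
      out[[paste0("S", j)]] <- v
    }
    # sprinkle missing values and one zero
    out$S1[c(3, 12, 20)] <- NA_real_
    out$S2[15] <- NA_real_
    out[[paste0("S", n_samples)]][25] <- 0
    attr(out, "group_delimiter") <- ";"
    out
  })
}
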