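#' Read a protein-group intensity export
#'
#' Parses a tab-separated protein-group table as produced by DIA-NN or
#' MaxQuant: one row per protein group, a group-identifier column holding
#' delimiter-separated accessions, an optional gene-symbol column, and one
#' numeric intensity column per sample.
#'
#' Intensities are linear-scale and non-negative. The literal tokens `NA`,
#' `NaN` and the empty string are read as missing, as is any cell that does
#' not parse as a number. By default an intensity of exactly 0 is also
#' recorded as missing, following the convention that zeros in MS
#' protein-group tables denote non-detection rather than measured absence;
#' set `zero_as_missing = FALSE` to keep zeros.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param id_column Name of the protein-group identifier column.
#' @param gene_column Optional name of the gene-symbol column (`NULL` if the
#'   export has none).
#' @param sample_columns Optional character vector naming the sample columns.
#'   When `NULL`, every numeric column other than `id_column`/`gene_column`
#'   is taken as a sample.
#' @param zero_as_missing Treat intensity 0 as a missing value (default `TRUE`).
#' @param group_delimiter Delimiter separating accessions inside a group
#'   (default `";"`, the UniProt-style convention). Stored on the result as
#'   attribute `"group_delimiter"` for downstream collapse.
#'
#' @return A tibble with columns `group_id`, `gene_symbol` (`NA` when absent)
#'   and one numeric column per sample, in file order.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("Protein.Group\tGenes\tS1\tS2",
#'              "P1;P2\tGENE1;GENE2\t100\t200",
#'              "P3\tGENE3\tNA\t50"), tsv)
#' read_protein_groups(tsv, id_column = "Protein.Group", gene_column = "Genes")
read_protein_groups <- function(path, id_column = "Protein.Group",
                                gene_column = NULL, sample_columns = NULL,
                                zero_as_missing = TRUE,
                                group_delimiter = ";") {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = character(), progress = FALSE,
                         name_repair = "minimal")
  hdr <- names(raw)
  if (anyDuplicated(hdr)) {
    abort_format(sprintf("%s: duplicate column headers (%s).", path,
                         paste(unique(hdr[duplicated(hdr)]), collapse = ", ")))
  }
  if (!id_column %in% hdr) {
    abort_format(sprintf("%s: id column `%s` not found.", path, id_column))
  }
  if (!is.null(gene_column) && !gene_column %in% hdr) {
    abort_format(sprintf("%s: gene column `%s` not found.", path, gene_column))
  }

  parse_cell <- function(v) {
    v[v %in% c("NA", "NaN", "")] <- NA_character_
    x <- suppressWarnings(as.numeric(v))
    if (zero_as_missing) x[!is.na(x) & x == 0] <- NA_real_
    x
  }

  if (is.null(sample_columns)) {
    candidates <- setdiff(hdr, c(id_column, gene_column))
    # a column counts as a sample when at least half of its informative cells
    # parse as numbers; stray unparseable cells become missing values instead
    # of disqualifying the column
    numericish <- vapply(candidates, function(cn) {
      v <- raw[[cn]]
      v <- v[!v %in% c("NA", "NaN", "")]
      length(v) == 0L ||
        mean(!is.na(suppressWarnings(as.numeric(v)))) >= 0.5
    }, logical(1))
    sample_columns <- candidates[numericish]
  } else {
    absent <- setdiff(sample_columns, hdr)
    if (length(absent)) {
      abort_format(sprintf("%s: sample column(s) not found: %s.", path,
                           paste(absent, collapse = ", ")))
    }
  }
  if (!length(sample_columns)) {
    abort_format(sprintf("%s: no sample columns detected.", path))
  }

  out <- tibble(
    group_id = raw[[id_column]],
    gene_symbol = if (is.null(gene_column)) NA_character_ else raw[[gene_column]]
  )
  out$gene_symbol[!is.na(out$gene_symbol) & out$gene_symbol == ""] <- NA_character_
  for (cn in sample_columns) out[[cn]] <- parse_cell(raw[[cn]])

  neg <- vapply(out[sample_columns], function(v) any(!is.na(v) & v < 0), logical(1))
  if (any(neg)) {
    abort_format(sprintf("%s: negative intensities in column(s): %s.", path,
                         paste(sample_columns[neg], collapse = ", ")))
  }
  attr(out, "group_delimiter") <- group_delimiter
  out
}

#' Write / read an expression matrix as TSV
#'
#' The on-disk layout is the CIBERSORT-compatible one: a first column named
#' `Gene` holding feature identifiers, then one column per sample, tab
#' separated, UTF-8, Unix newlines. Missing values are written as `NA`.
#' Values round-trip at 12 significant digits.
#'
#' @param x An expression tibble (first column `gene`, then numeric samples).
#' @param path Output (or input) file path.
#' @return `write_expression_matrix()` returns `path` invisibly;
#'   `read_expression_matrix()` returns an expression tibble.
#' @export
write_expression_matrix <- function(x, path) {
  check_expr_table(x)
  out <- x
  names(out)[1] <- "Gene"
  for (cn in names(out)[-1]) {
    out[[cn]] <- ifelse(is.na(out[[cn]]), "NA",
                        formatC(out[[cn]], digits = 12, format = "g"))
  }
  tryCatch(
    readr::write_tsv(out, path, na = "NA", progress = FALSE),
    error = function(e) abort_format(sprintf("failed to write %s: %s", path, conditionMessage(e)))
  )
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  x <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(
      .default = readr::col_double(),
      Gene = readr::col_character()
    ), na = c("NA", "NaN", ""), progress = FALSE),
    error = function(e) abort_format(sprintf("failed to read %s: %s", path, conditionMessage(e)))
  )
  if (!"Gene" %in% names(x) || names(x)[1] != "Gene") {
    abort_format(sprintf("%s: expected first column `Gene`.", path))
  }
  names(x)[1] <- "gene"
  check_expr_table(x)
  x
}

#' Write estimated cell-type fractions as TSV
#'
#' Rows are samples, columns are cell types (plus `other` when the result
#' carries an unassigned fraction); values are rendered with 6+ significant
#' digits.
#'
#' @param result A [deconvolute()] result or a plain fractions tibble whose
#'   first column is `sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fractions <- function(result, path) {
  fr <- if (inherits(result, "cellfrac_deconv")) result$fractions else result
  if (!is.data.frame(fr) || names(fr)[1] != "sample") {
    abort_validation("`result` must be a deconvolution result or a fractions tibble (first column `sample`).")
  }
  out <- fr
  for (cn in names(out)[-1]) {
    out[[cn]] <- formatC(out[[cn]], digits = 8, format = "g")
  }
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a fractions table written by [write_fractions()]
#' @param path Input file path.
#' @return A tibble with a `sample` column and one numeric column per cell type.
#' @export
read_fractions <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(), sample = readr::col_character()
  ), na = c("NA", "NaN", ""), progress = FALSE)
  if (names(x)[1] != "sample") {
    abort_format(sprintf("%s: expected first column `sample`.", path))
  }
  x
}
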