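#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene (or probe) ids
#' named arbitrarily, and a numeric body. Blank cells are treated as missing;
#' any row containing a missing value is dropped (the count is reported),
#' so every downstream pairwise correlation uses the same sample set.
#'
#' @param path Path to a tab-separated file.
#' @return An expression tibble: first column `gene_id`, one numeric column
#'   per sample.
#' @seealso [write_expression_matrix()], [collapse_probes()],
#'   [filter_uninformative()]
#' @export
read_expression_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("", "NA"))
  if (ncol(raw) < 2L) abort_format(sprintf("'%s' needs a gene id column and >= 1 sample column.", path))
  names(raw)[1L] <- "gene_id"
  if (anyDuplicated(names(raw)[-1L])) abort_format(sprintf("'%s' has duplicate sample ids.", path))
  if (anyDuplicated(raw$gene_id)) {
    dups <- unique(raw$gene_id[duplicated(raw$gene_id)])
    abort_format(sprintf("'%s' has duplicate gene ids (%s); collapse probes first.",
                         path, paste(head(dups, 5L), collapse = ", ")))
  }
  body <- raw[, -1L, drop = FALSE]
  parsed <- lapply(seq_along(body), function(j) {
    v <- body[[j]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad)) {
      abort_format(sprintf(
        "non-numeric value '%s' at row %d, column '%s' of '%s'.",
        v[bad[1L]], bad[1L], names(body)[j], path))
    }
    num
  })
  names(parsed) <- names(body)
  out <- dplyr::bind_cols(tibble(gene_id = raw$gene_id), as_tibble(parsed))
  keep <- stats::complete.cases(out[, -1L, drop = FALSE])
  if (any(!keep)) {
    inform(sprintf("dropped %d row(s) with missing values from '%s'.", sum(!keep), path))
    out <- out[keep, , drop = FALSE]
  }
  check_expression_tbl(out, "matrix")
  out
}

#' Write an expression matrix as TSV
#'
#' @param x An expression tibble (`gene_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  check_expression_tbl(x)
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a probe-to-symbol platform map
#'
#' Two-column TSV (`probe_id<TAB>gene_symbol`), no header.
#'
#' @param path Path to the map file.
#' @return A tibble with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  map <- readr::read_tsv(path, col_names = c("probe_id", "gene_symbol"),
                         col_types = "cc", comment = "#")
  if (anyDuplicated(map$probe_id)) {
    abort_format(sprintf("'%s' maps some probes more than once.", path))
  }
  map
}

#' Collapse probe-level rows to one row per gene symbol
#'
#' Probes absent from the map are dropped. When several probes map to the
#' same symbol, the probe with the highest mean expression across samples is
#' retained; ties are broken by lexicographic probe id. Row ids of the result
#' are gene symbols.
#'
#' @param x A probe-level expression tibble (`gene_id` holds probe ids).
#' @param probe_map A tibble with columns `probe_id` and `gene_symbol`
#'   (see [read_probe_map()]).
#' @return An expression tibble keyed by gene symbol.
#' @export
collapse_probes <- function(x, probe_map) {
  check_expression_tbl(x)
  if (!all(c("probe_id", "gene_symbol") %in% names(probe_map))) {
    abort_config("`probe_map` needs columns `probe_id` and `gene_symbol`.")
  }
  mapped <- dplyr::inner_join(
    dplyr::rename(x, probe_id = "gene_id"),
    probe_map[, c("probe_id", "gene_symbol")],
    by = "probe_id")
  if (nrow(mapped) == 0L) {
    abort_empty("no probe ids in the matrix are covered by the probe map.")
  }
  sample_cols <- setdiff(names(x), "gene_id")
  mapped$.mean <- rowMeans(as.matrix(mapped[, sample_cols, drop = FALSE]))
  picked <- mapped |>
    dplyr::arrange(.data$gene_symbol, dplyr::desc(.data$.mean), .data$probe_id) |>
    dplyr::distinct(.data$gene_symbol, .keep_all = TRUE)
  out <- dplyr::bind_cols(
    tibble(gene_id = picked$gene_symbol),
    picked[, sample_cols, drop = FALSE])
  dplyr::arrange(out, .data$gene_id)
}

#' Drop constant (zero-variance) genes
#'
#' Rank correlation is undefined for a constant row, so these genes cannot
#' participate in network construction; they are removed and the count is
#' reported.
#'
#' @param x An expression tibble.
#' @return The tibble without constant rows.
#' @export
filter_uninformative <- function(x) {
  check_expression_tbl(x)
  m <- expr_to_matrix(x)
  constant <- apply(m, 1L, function(r) max(r) == min(r))
  if (all(constant)) abort_empty("all genes are constant; nothing left to correlate.")
  if (any(constant)) {
    inform(sprintf("removed %d constant gene(s).", sum(constant)))
    x <- x[!constant, , drop = FALSE]
  }
  x
}
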