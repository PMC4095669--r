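#' Read a GMT annotation collection
#'
#' Standard GMT dialect: one term per line,
#' `term_id<TAB>description<TAB>gene1<TAB>gene2...`. Genes duplicated within
#' a line are counted once; blank lines are skipped.
#'
#' @param path Path to a `.gmt` file.
#' @param source_label Name recorded for the collection; defaults to the
#'   file name.
#' @return An `annotation_collection`: a tibble with columns `term_id`,
#'   `term_name` and a list-column `genes`.
#' @export
read_gmt <- function(path, source_label = basename(path)) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    abort_format(sprintf("line %d of '%s' has fewer than 3 tab-separated fields.",
                         line_no[which(short)[1L]], path))
  }
  terms <- tibble(
    term_id = vapply(fields, `[[`, "", 1L),
    term_name = vapply(fields, `[[`, "", 2L),
    genes = lapply(fields, function(f) sort(unique(f[-(1:2)]))))
  if (anyDuplicated(terms$term_id)) {
    abort_format(sprintf("duplicate term id(s) in '%s': %s", path,
                         paste(unique(terms$term_id[duplicated(terms$term_id)]), collapse = ", ")))
  }
  if (any(lengths(terms$genes) == 0L)) {
    abort_format(sprintf("term(s) with empty gene set in '%s'.", path))
  }
  structure(terms, class = c("annotation_collection", class(terms)),
            source_label = source_label)
}

#' Write an annotation collection as GMT
#'
#' @param collection An `annotation_collection` (see [read_gmt()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "annotation_collection"))
  writeLines(vapply(seq_len(nrow(collection)), function(i) {
    paste(c(collection$term_id[i], collection$term_name[i],
            collection$genes[[i]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' One-sided Fisher exact probability for over-representation
#'
#' Probability of drawing at least `count` annotated genes when `list_size`
#' genes are sampled without replacement from a population of `pop_size`
#' genes containing `pop_hits` annotated ones — the upper-tail
#' hypergeometric probability of the 2x2 table. With `ease = TRUE` the
#' conservative EASE variant is computed instead: one observed success is
#' removed (`count - 1`, floored at 0) before taking the tail, so singleton
#' overlaps can never look significant.
#'
#' @param count Overlap between the query list and the term.
#' @param list_size Query list size.
#' @param pop_hits Term size within the population.
#' @param pop_size Population size.
#' @param ease Apply the EASE modification (default `FALSE`).
#' @return The one-sided enrichment probability in `(0, 1]`.
#' @export
fisher_onesided <- function(count, list_size, pop_hits, pop_size, ease = FALSE) {
  k <- if (isTRUE(ease)) pmax(count - 1, 0) else count
  hypergeometric_upper_tail(k, list_size, pop_hits, pop_size)
}

#' Over-representation analysis of a gene list
#'
#' Tests each term of an annotation collection for enrichment in `query`
#' relative to `population`. Term gene sets are first restricted to the
#' population (`pop_hits = |term %in% population|`), terms overlapping the
#' query by fewer than `min_count` genes are dropped, and
#' Benjamini-Hochberg adjustment is applied over the reported rows.
#'
#' The default test is the EASE-modified one-sided Fisher exact test (the
#' convention of the DAVID annotation tool); set `ease = FALSE` for the
#' plain Fisher probability.
#'
#' @param query Character vector of genes of interest; must lie inside
#'   `population`.
#' @param population Character vector: the assessed gene universe (for
#'   network-derived lists, the network universe).
#' @param annotations An `annotation_collection` (see [read_gmt()]).
#' @param ease Use the EASE modification (default `TRUE`).
#' @param min_count Minimum query-term overlap to report (default 2).
#' @return A tibble with one row per reported term: `term_id`, `term_name`,
#'   `count`, `pop_hits`, `list_size`, `pop_size`, `p_value`, `adjusted_p`
#'   and a list-column `genes` of the overlapping ids, sorted by ascending
#'   `p_value` (ties by term id).
#' @export
enrich <- function(query, population, annotations, ease = TRUE, min_count = 2) {
  stopifnot(inherits(annotations, "annotation_collection"))
  query <- unique(as.character(query))
  population <- unique(as.character(population))
  if (!length(population)) abort_empty("`population` is empty.")
  stray <- setdiff(query, population)
  if (length(stray)) {
    abort_domain(sprintf("query gene(s) outside the population: %s%s",
                         paste(head(stray, 10L), collapse = ", "),
                         if (length(stray) > 10L) ", ..." else ""))
  }
  min_count <- scalar_count(min_count, "min_count", min = 0L)
  rows <- purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    in_pop <- intersect(annotations$genes[[i]], population)
    overlap <- intersect(in_pop, query)
    tibble(term_id = annotations$term_id[i],
           term_name = annotations$term_name[i],
           count = length(overlap), pop_hits = length(in_pop),
           genes = list(sort(overlap)))
  })
  rows <- rows[rows$pop_hits > 0L & rows$count >= min_count, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(tibble(term_id = character(0), term_name = character(0),
                  count = integer(0), pop_hits = integer(0),
                  list_size = integer(0), pop_size = integer(0),
                  p_value = numeric(0), adjusted_p = numeric(0),
                  genes = list()))
  }
  rows |>
    dplyr::mutate(
      list_size = length(query), pop_size = length(population),
      p_value = fisher_onesided(.data$count, .data$list_size,
                                .data$pop_hits, .data$pop_size, ease = ease),
      adjusted_p = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::arrange(.data$p_value, .data$term_id) |>
    dplyr::select("term_id", "term_name", "count", "pop_hits", "list_size",
                  "pop_size", "p_value", "adjusted_p", "genes")
}

#' Write an enrichment table as TSV
#'
#' Columns `term_id`, `term_name`, `count`, `pop_hits`, `list_size`,
#' `pop_size`, `p_value`, `adjusted_p`, `genes` (comma-joined, sorted) —
#' the layout of a standard over-representation report (term, overlap
#' count, population hits, p-value, member genes).
#'
#' @param rows An enrichment tibble from [enrich()].
#' @param path File path.
#' @return `write_enrichment()` returns `path` invisibly;
#'   `read_enrichment()` returns the tibble (genes as a list-column).
#' @export
write_enrichment <- function(rows, path) {
  out <- rows
  out$genes <- vapply(rows$genes, function(g) paste(sort(g), collapse = ","), "")
  out$p_value <- sprintf("%.10e", rows$p_value)
  out$adjusted_p <- sprintf("%.10e", rows$adjusted_p)
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    term_id = readr::col_character(), term_name = readr::col_character(),
    count = readr::col_integer(), pop_hits = readr::col_integer(),
    list_size = readr::col_integer(), pop_size = readr::col_integer(),
    p_value = readr::col_double(), adjusted_p = readr::col_double(),
    genes = readr::col_character()))
  tbl$genes <- lapply(strsplit(ifelse(is.na(tbl$genes), "", tbl$genes), ",",
                               fixed = TRUE),
                      function(g) sort(g[nzchar(g)]))
  tbl
}
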