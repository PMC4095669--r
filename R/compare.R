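#' Compare friend sets between two conditions
#'
#' Partitions two friend sets into genes significant in both conditions, in
#' the first only, and in the second only. A friend of one condition that
#' was never assessed in the other (absent from that network's universe) is
#' flagged `unassessable` rather than counted as condition-specific, since
#' absence of evidence is not loss of coexpression; when the two universes
#' coincide the three categories exactly partition the union of the sets.
#'
#' @param a,b `friend_set` objects (see [call_friends()]).
#' @param label_a,label_b Condition names; default to the sets' own labels.
#' @return A `friend_comparison`: a tibble (`gene`, `category` with levels
#'   `both`, `only_a`, `only_b`, `unassessable`) plus the labels and counts.
#' @examples
#' fs <- function(m, lab) structure(list(label = lab, alpha = 1e-8,
#'   members = m, universe = c("g1", "g2", "g3", "g4"),
#'   table = tibble::tibble()), class = "friend_set")
#' compare_friend_sets(fs(c("g1", "g2", "g3"), "normal"), fs(c("g3", "g4"), "treated"))
#' @export
compare_friend_sets <- function(a, b, label_a = NULL, label_b = NULL) {
  stopifnot(inherits(a, "friend_set"), inherits(b, "friend_set"))
  label_a <- label_a %||% a$label
  label_b <- label_b %||% b$label
  if (!isTRUE(all.equal(a$alpha, b$alpha))) {
    warn(sprintf("friend sets were called at different cutoffs (%g vs %g).",
                 a$alpha, b$alpha))
  }
  un_a <- setdiff(a$members, b$universe)
  un_b <- setdiff(b$members, a$universe)
  A <- setdiff(a$members, un_a)
  B <- setdiff(b$members, un_b)
  new_friend_comparison(
    in_both = intersect(A, B), only_a = setdiff(A, B), only_b = setdiff(B, A),
    unassessable = union(un_a, un_b), label_a = label_a, label_b = label_b)
}

new_friend_comparison <- function(in_both, only_a, only_b,
                                  unassessable = character(0),
                                  label_a = "a", label_b = "b") {
  tbl <- tibble(
    gene = c(sort(in_both), sort(only_a), sort(only_b), sort(unassessable)),
    category = rep(c("both", "only_a", "only_b", "unassessable"),
                   c(length(in_both), length(only_a), length(only_b),
                     length(unassessable))))
  structure(list(table = tbl, label_a = label_a, label_b = label_b),
            class = "friend_comparison")
}

#' Extract one category of a friend comparison
#'
#' @param cmp A `friend_comparison`.
#' @param category One of `"both"`, `"only_a"`, `"only_b"`, `"unassessable"`.
#' @return Sorted character vector of gene ids.
#' @export
comparison_genes <- function(cmp, category = c("both", "only_a", "only_b",
                                               "unassessable")) {
  stopifnot(inherits(cmp, "friend_comparison"))
  category <- match.arg(category)
  cmp$table$gene[cmp$table$category == category]
}

#' @export
print.friend_comparison <- function(x, ...) {
  n <- table(factor(x$table$category,
                    levels = c("both", "only_a", "only_b", "unassessable")))
  cat(sprintf("<friend_comparison> %s vs %s\n", x$label_a, x$label_b))
  cat(sprintf("  both: %d  only %s: %d  only %s: %d  unassessable: %d\n",
              n[["both"]], x$label_a, n[["only_a"]], x$label_b, n[["only_b"]],
              n[["unassessable"]]))
  invisible(x)
}

#' @describeIn compare_friend_sets Gene-by-category table.
#' @param x A `friend_comparison`.
#' @param ... Unused.
#' @export
tidy.friend_comparison <- function(x, ...) x$table

#' @describeIn compare_friend_sets One-row count summary.
#' @export
glance.friend_comparison <- function(x, ...) {
  n <- table(factor(x$table$category,
                    levels = c("both", "only_a", "only_b", "unassessable")))
  tibble(label_a = x$label_a, label_b = x$label_b,
         n_both = n[["both"]], n_only_a = n[["only_a"]],
         n_only_b = n[["only_b"]], n_unassessable = n[["unassessable"]])
}

#' Compare seed self-connectivity between two conditions
#'
#' Same partition semantics as [compare_friend_sets()], restricted to seed
#' genes: which seeds remain self-connected after treatment, which lose
#' their connectivity, and which gain it.
#'
#' @param a,b Character vectors of self-connected seed genes per condition
#'   (see [seed_self_connectivity()]); both must be subsets of `seed`.
#' @param seed Character vector: the full seed set.
#' @param label_a,label_b Condition names.
#' @return A `friend_comparison` over seed genes.
#' @export
compare_seed_self_connectivity <- function(a, b, seed,
                                           label_a = "a", label_b = "b") {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  extra <- union(setdiff(a, seed), setdiff(b, seed))
  if (length(extra)) {
    abort_domain(sprintf("genes outside the seed set: %s",
                         paste(head(extra, 5L), collapse = ", ")))
  }
  new_friend_comparison(in_both = intersect(a, b), only_a = setdiff(a, b),
                        only_b = setdiff(b, a),
                        label_a = label_a, label_b = label_b)
}

#' Side-by-side p-values for two conditions
#'
#' Supplementary report pairing each gene's seed-connectivity p-value in the
#' two conditions, for inspecting how strongly individual genes change (for
#' example a gene whose p-value rises from far below the cutoff to near 1
#' after treatment).
#'
#' @param a,b `seed_friend_test` objects for the two conditions.
#' @param label_a,label_b Condition names used as column suffixes.
#' @return A tibble (`gene`, `p_<a>`, `p_<b>`, `log10_ratio`) over the
#'   common universe, sorted by descending `log10_ratio`
#'   (`log10(p_b) - log10(p_a)`: large values lost significance in `b`).
#' @export
compare_pvalues <- function(a, b, label_a = "a", label_b = "b") {
  stopifnot(inherits(a, "seed_friend_test"), inherits(b, "seed_friend_test"))
  ta <- a$results[, c("gene", "log10_p", "p_value")]
  tb <- b$results[, c("gene", "log10_p", "p_value")]
  out <- dplyr::inner_join(ta, tb, by = "gene", suffix = c("_a", "_b")) |>
    dplyr::transmute(
      gene = .data$gene,
      !!paste0("p_", label_a) := .data$p_value_a,
      !!paste0("p_", label_b) := .data$p_value_b,
      log10_ratio = .data$log10_p_b - .data$log10_p_a) |>
    dplyr::arrange(dplyr::desc(.data$log10_ratio), .data$gene)
  out
}

#' Write or read a friend-set comparison
#'
#' TSV (`gene`, `category`) preceded by a `#` summary line with the three
#' category counts (and any unassessable genes).
#'
#' @param cmp A `friend_comparison`.
#' @param path File path.
#' @return `write_comparison()` returns `path` invisibly;
#'   `read_comparison()` the reconstructed `friend_comparison`.
#' @export
write_comparison <- function(cmp, path) {
  stopifnot(inherits(cmp, "friend_comparison"))
  n <- table(factor(cmp$table$category,
                    levels = c("both", "only_a", "only_b", "unassessable")))
  header <- sprintf("# label_a=%s label_b=%s both=%d only_a=%d only_b=%d unassessable=%d",
                    cmp$label_a, cmp$label_b, n[["both"]], n[["only_a"]],
                    n[["only_b"]], n[["unassessable"]])
  writeLines(c(header, "gene\tcategory",
               sprintf("%s\t%s", cmp$table$gene, cmp$table$category)), path)
  invisible(path)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  first <- readLines(path, n = 1L)
  labels <- c(a = "a", b = "b")
  if (startsWith(first, "#")) {
    kv <- strsplit(trimws(sub("^#", "", first)), "[ =]+")[[1L]]
    vals <- setNames(kv[seq(2L, length(kv), 2L)], kv[seq(1L, length(kv), 2L)])
    if (!is.na(vals["label_a"])) labels[["a"]] <- vals[["label_a"]]
    if (!is.na(vals["label_b"])) labels[["b"]] <- vals[["label_b"]]
  }
  tbl <- readr::read_tsv(path, comment = "#", col_types = "cc")
  bad <- setdiff(unique(tbl$category),
                 c("both", "only_a", "only_b", "unassessable"))
  if (length(bad)) abort_format(sprintf("unknown category: %s", paste(bad, collapse = ", ")))
  new_friend_comparison(
    in_both = tbl$gene[tbl$category == "both"],
    only_a = tbl$gene[tbl$category == "only_a"],
    only_b = tbl$gene[tbl$category == "only_b"],
    unassessable = tbl$gene[tbl$category == "unassessable"],
    label_a = labels[["a"]], label_b = labels[["b"]])
}
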