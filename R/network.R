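#' Spearman rank correlation of two expression profiles
#'
#' Pearson correlation of average-ranked values; ties receive the mean of the
#' ranks they span. A thin, argument-checked front for [stats::cor()] that
#' enforces the preconditions network construction relies on.
#'
#' @param x,y Numeric vectors of equal length (>= 3), each with at least two
#'   distinct values.
#' @return The coefficient, in `[-1, 1]`.
#' @examples
#' spearman_rho(1:10, (1:10)^3)  # monotone transform: exactly 1
#' @export
spearman_rho <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort_domain("`x` and `y` must be numeric vectors of equal length.")
  }
  if (length(x) < 3L) abort_domain("need at least 3 paired observations.")
  if (anyNA(x) || anyNA(y)) abort_domain("missing values are not allowed.")
  if (max(x) == min(x) || max(y) == min(y)) {
    abort_domain("correlation undefined for a constant vector; see filter_uninformative().")
  }
  stats::cor(x, y, method = "spearman")
}

#' Construct a coexpression network
#'
#' Build a thresholded coexpression network from an expression matrix:
#' nodes are all genes in the matrix (isolated genes stay in the universe,
#' so the hypergeometric universe size `N` equals the number of genes
#' assessed), and an edge joins genes `g` and `h` when their correlation
#' passes the edge rule. The default rule, `signed`, places an edge when
#' `rho >= threshold` — the literal "coefficient >= 0.3" convention — while
#' `absolute` uses `|rho| >= threshold` and so also admits strong negative
#' correlations.
#'
#' @param x An expression tibble that has passed [filter_uninformative()].
#' @param threshold Correlation cutoff, in `(0, 1]`. Default 0.3.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param edge_rule `"signed"` (default) or `"absolute"`.
#' @return A `coex_network` object: the gene universe, an edge tibble
#'   (`gene_a`, `gene_b`, `rho`; pairs stored with `gene_a < gene_b`) and the
#'   build settings.
#' @examples
#' mat <- tibble::tibble(gene_id = c("a", "b", "c"),
#'   s1 = c(1, 1, 5), s2 = c(2, 2, 4), s3 = c(3, 3, 2), s4 = c(4, 4, 1))
#' build_network(mat, threshold = 0.5)
#' @export
build_network <- function(x, threshold = 0.3,
                          method = c("spearman", "pearson"),
                          edge_rule = c("signed", "absolute")) {
  check_expression_tbl(x)
  method <- match.arg(method)
  edge_rule <- match.arg(edge_rule)
  threshold <- scalar_number(threshold, "threshold", 0, 1, lower_open = TRUE)
  m <- expr_to_matrix(x)
  if (ncol(m) < 3L) abort_config("need at least 3 samples to correlate.")
  constant <- apply(m, 1L, function(r) max(r) == min(r))
  if (any(constant)) {
    abort_domain(sprintf(
      "%d constant gene(s) present; run filter_uninformative() first.", sum(constant)))
  }
  rho <- stats::cor(t(m), method = method)
  keep <- if (edge_rule == "signed") rho >= threshold else abs(rho) >= threshold
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  g1 <- rownames(m)[idx[, 1L]]
  g2 <- rownames(m)[idx[, 2L]]
  edges <- tibble(
    gene_a = pmin(g1, g2),
    gene_b = pmax(g1, g2),
    rho = rho[idx]) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  new_coex_network(edges, universe = sort(rownames(m)),
                   threshold = threshold, method = method, edge_rule = edge_rule)
}

#' Assemble a coexpression network from parts
#'
#' Low-level constructor validating the network invariants: no self-loops,
#' each unordered pair at most once, endpoints inside the universe, and every
#' stored coefficient satisfying the declared edge rule.
#'
#' @param edges Tibble or data frame with columns `gene_a`, `gene_b`, `rho`.
#' @param universe Character vector of gene ids (includes isolated genes).
#' @param threshold,method,edge_rule Build settings (see [build_network()]).
#' @return A `coex_network` object.
#' @export
coex_network <- function(edges, universe, threshold = 0.3,
                         method = "spearman", edge_rule = "signed") {
  edges <- as_tibble(edges)
  if (!all(c("gene_a", "gene_b", "rho") %in% names(edges))) {
    abort_format("`edges` needs columns gene_a, gene_b, rho.")
  }
  if (anyDuplicated(universe)) abort_format("`universe` has duplicate gene ids.")
  edges <- tibble(
    gene_a = pmin(edges$gene_a, edges$gene_b),
    gene_b = pmax(edges$gene_a, edges$gene_b),
    rho = as.numeric(edges$rho)) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  if (any(edges$gene_a == edges$gene_b)) abort_format("self-loops are not allowed.")
  if (anyDuplicated(edges[, c("gene_a", "gene_b")])) {
    abort_format("duplicate edges for the same gene pair.")
  }
  missing <- setdiff(unique(c(edges$gene_a, edges$gene_b)), universe)
  if (length(missing)) {
    abort_format(sprintf("edge endpoint(s) outside the universe: %s",
                         paste(head(missing, 5L), collapse = ", ")))
  }
  ok <- if (edge_rule == "signed") edges$rho >= threshold else abs(edges$rho) >= threshold
  if (!all(ok)) abort_format("some edge coefficients violate the declared edge rule.")
  structure(
    list(edges = edges, universe = sort(universe), threshold = threshold,
         method = method, edge_rule = edge_rule),
    class = "coex_network")
}

new_coex_network <- coex_network

#' @export
print.coex_network <- function(x, ...) {
  cat("<coex_network>\n")
  cat(sprintf("  %d genes, %d edges (%s, %s rule, threshold %.3g)\n",
              length(x$universe), nrow(x$edges), x$method, x$edge_rule, x$threshold))
  invisible(x)
}

#' @describeIn coex_network Tidy the edge table.
#' @param x A `coex_network`.
#' @param ... Unused.
#' @export
tidy.coex_network <- function(x, ...) x$edges

#' @describeIn coex_network One-row network summary (genes, edges, density).
#' @export
glance.coex_network <- function(x, ...) {
  n <- length(x$universe)
  tibble(n_genes = n, n_edges = nrow(x$edges),
         density = if (n > 1) nrow(x$edges) / (n * (n - 1) / 2) else NA_real_,
         threshold = x$threshold, method = x$method, edge_rule = x$edge_rule)
}

#' Node degrees of a coexpression network
#'
#' @param network A `coex_network`.
#' @return A tibble (`gene`, `degree`) covering every universe gene,
#'   isolated genes included.
#' @export
network_degrees <- function(network) {
  stopifnot(inherits(network, "coex_network"))
  counts <- table(factor(c(network$edges$gene_a, network$edges$gene_b),
                         levels = network$universe))
  tibble(gene = network$universe, degree = as.integer(counts))
}

#' Write or read a coexpression network
#'
#' The edge list is a TSV (`gene_a`, `gene_b`, `rho`) with pairs in
#' lexicographic order, preceded by a `#` comment line recording the build
#' settings; the universe is a one-column node file so isolated genes
#' survive the round trip.
#'
#' @param network A `coex_network`.
#' @param edges_path,nodes_path File paths for the edge list and node list.
#' @return `write_edge_list()` returns `edges_path` invisibly;
#'   `read_edge_list()` returns the reconstructed `coex_network`.
#' @export
write_edge_list <- function(network, edges_path, nodes_path) {
  stopifnot(inherits(network, "coex_network"))
  header <- sprintf("# threshold=%s method=%s edge_rule=%s",
                    format(network$threshold, digits = 15),
                    network$method, network$edge_rule)
  writeLines(c(header, "gene_a\tgene_b\trho",
               sprintf("%s\t%s\t%s", network$edges$gene_a, network$edges$gene_b,
                       vapply(network$edges$rho, format, "", digits = 15,
                              scientific = FALSE))),
             edges_path)
  writeLines(network$universe, nodes_path)
  invisible(edges_path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(edges_path, nodes_path) {
  first <- readLines(edges_path, n = 1L)
  meta <- list(threshold = 0.3, method = "spearman", edge_rule = "signed")
  if (startsWith(first, "#")) {
    kv <- strsplit(trimws(sub("^#", "", first)), "[ =]+")[[1L]]
    if (length(kv) >= 2L) {
      vals <- setNames(kv[seq(2L, length(kv), 2L)], kv[seq(1L, length(kv), 2L)])
      if (!is.na(vals["threshold"])) meta$threshold <- as.numeric(vals[["threshold"]])
      if (!is.na(vals["method"])) meta$method <- vals[["method"]]
      if (!is.na(vals["edge_rule"])) meta$edge_rule <- vals[["edge_rule"]]
    }
  }
  edges <- readr::read_tsv(edges_path, comment = "#",
                           col_types = readr::cols(
                             gene_a = readr::col_character(),
                             gene_b = readr::col_character(),
                             rho = readr::col_double()))
  universe <- readLines(nodes_path)
  coex_network(edges, universe, threshold = meta$threshold,
               method = meta$method, edge_rule = meta$edge_rule)
}
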