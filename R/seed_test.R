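#' Read a seed gene list
#'
#' One symbol per line; `#` starts a comment; blank lines are skipped.
#' Duplicates are removed with a warning.
#'
#' @param path Path to the list file.
#' @return Character vector of seed symbols.
#' @export
read_seed_list <- function(path) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  if (anyDuplicated(lines)) {
    warn(sprintf("seed list '%s' contains duplicates; keeping unique symbols.", path))
    lines <- unique(lines)
  }
  if (!length(lines)) abort_empty(sprintf("seed list '%s' is empty.", path))
  lines
}

#' Count seed neighbours and total degree for every gene
#'
#' For each gene in the network universe (isolated genes included), `n` is
#' its degree and `k` the number of its neighbours inside the seed set
#' restricted to the universe. A gene is never its own neighbour.
#'
#' @param network A `coex_network`.
#' @param seed Character vector of seed gene ids.
#' @return A tibble (`gene`, `k`, `n`) sorted by gene id.
#' @export
seed_neighbor_counts <- function(network, seed) {
  stopifnot(inherits(network, "coex_network"))
  seed <- unique(as.character(seed))
  if (!length(seed)) abort_empty("seed set is empty.")
  eff_seed <- intersect(seed, network$universe)
  if (!length(eff_seed)) {
    abort_empty(sprintf(
      "no seed genes present in the network universe; missing: %s%s",
      paste(head(setdiff(seed, network$universe), 10L), collapse = ", "),
      if (length(seed) > 10L) ", ..." else ""))
  }
  lev <- network$universe
  deg <- table(factor(c(network$edges$gene_a, network$edges$gene_b), levels = lev))
  a_in <- network$edges$gene_a %in% eff_seed
  b_in <- network$edges$gene_b %in% eff_seed
  k <- table(factor(c(network$edges$gene_b[a_in], network$edges$gene_a[b_in]),
                    levels = lev))
  tibble(gene = lev, k = as.integer(k), n = as.integer(deg))
}

#' Test every gene's connectivity to the seed set
#'
#' Scores each gene in the universe with the upper-tail hypergeometric
#' probability of its seed-neighbour count: a gene with degree `n`, of which
#' `k` neighbours are seed genes, is compared against drawing `n` genes at
#' random from the `N_eff` other genes of the universe, `K_eff` of which are
#' seeds. The tested gene is excluded from its own population
#' (`N_eff = N - 1`) and, when it is itself a seed gene, from the seed set
#' (`K_eff = K - 1`), so seed genes are scored against the *other* seeds —
#' the basis of the seed self-connectivity analysis.
#'
#' Benjamini-Hochberg adjusted values are attached as a convenience column
#' (`q_value`); friend calling itself uses the raw fixed cutoff (see
#' [call_friends()]).
#'
#' @param network A `coex_network`.
#' @param seed Character vector of seed gene ids.
#' @param seed_name Label recorded on the result.
#' @return A `seed_friend_test` object whose `tidy()` table has one row per
#'   universe gene: `gene`, `is_seed`, `k`, `n`, `K_eff`, `N_eff`,
#'   `p_value`, `log10_p`, `q_value`, sorted by ascending `p_value`
#'   (ties by gene id).
#' @examples
#' net <- coex_network(
#'   tibble::tibble(gene_a = "hub", gene_b = c("s1", "s2", "x"), rho = 0.9),
#'   universe = c("hub", "s1", "s2", "x", "iso"))
#' tidy(test_all_genes(net, seed = c("s1", "s2")))
#' @export
test_all_genes <- function(network, seed, seed_name = "seed") {
  counts <- seed_neighbor_counts(network, seed)
  eff_seed <- intersect(unique(as.character(seed)), network$universe)
  K <- length(eff_seed)
  N <- length(network$universe)
  res <- counts |>
    dplyr::mutate(
      is_seed = .data$gene %in% eff_seed,
      K_eff = K - as.integer(.data$is_seed),
      N_eff = N - 1L)

  # p-values gene by gene in log space; cache tails per (n, K_eff) since many
  # genes share a degree.
  key <- paste(res$n, res$K_eff)
  logp <- numeric(nrow(res))
  for (kk in unique(key)) {
    rows <- which(key == kk)
    n_i <- res$n[rows[1L]]
    K_i <- res$K_eff[rows[1L]]
    tails <- hyper_tail_log_all(n_i, K_i, N - 1L)
    logp[rows] <- tails[res$k[rows] + 1L]
  }
  res <- res |>
    dplyr::mutate(
      p_value = exp(logp),
      log10_p = logp / log(10),
      q_value = p.adjust(.data$p_value, method = "BH")) |>
    dplyr::select("gene", "is_seed", "k", "n", "K_eff", "N_eff",
                  "p_value", "log10_p", "q_value") |>
    dplyr::arrange(.data$p_value, .data$gene)

  structure(
    list(results = res, seed = sort(eff_seed), seed_name = seed_name,
         universe_size = N, threshold = network$threshold,
         method = network$method, edge_rule = network$edge_rule),
    class = "seed_friend_test")
}

#' @export
print.seed_friend_test <- function(x, ...) {
  cat("<seed_friend_test>\n")
  cat(sprintf("  %d genes tested against %d '%s' genes\n",
              nrow(x$results), length(x$seed), x$seed_name))
  cat(sprintf("  smallest p: %.3g (%s)\n", x$results$p_value[1L], x$results$gene[1L]))
  invisible(x)
}

#' @describeIn test_all_genes Per-gene result table.
#' @param x A `seed_friend_test`.
#' @param ... Unused.
#' @export
tidy.seed_friend_test <- function(x, ...) x$results

#' @describeIn test_all_genes One-row summary: genes tested, effective seed
#'   size, genes below the conventional `1e-8` cutoff, and the minimum p.
#' @export
glance.seed_friend_test <- function(x, ...) {
  tibble(n_genes = nrow(x$results),
         seed_size_effective = length(x$seed),
         n_below_1e8 = sum(x$results$p_value < 1e-8),
         min_p = min(x$results$p_value),
         threshold = x$threshold, method = x$method)
}

results_table <- function(x) {
  if (inherits(x, "seed_friend_test")) return(x$results)
  if (is.data.frame(x)) {
    need <- c("gene", "is_seed", "p_value")
    if (!all(need %in% names(x))) {
      abort_config(sprintf("results table needs columns: %s.", paste(need, collapse = ", ")))
    }
    return(as_tibble(x))
  }
  abort_config("`results` must be a seed_friend_test or its tidy() table.")
}

#' Call coexpression friends of the seed set
#'
#' Friends are genes whose seed-connectivity p-value falls strictly below
#' `alpha` (default `1e-8`, the conventional genome-wide cutoff for this
#' statistic). Seed genes themselves are excluded by default — their
#' significance is reported separately by [seed_self_connectivity()].
#'
#' @param results A `seed_friend_test` or its `tidy()` table.
#' @param alpha P-value cutoff in `(0, 1]`; membership is `p_value < alpha`.
#' @param exclude_seed Drop seed genes from the friend list (default `TRUE`).
#' @param label Condition label recorded on the result.
#' @return A `friend_set`: member gene ids, the cutoff, the condition label,
#'   the universe the call was made in, and the members' result rows.
#' @export
call_friends <- function(results, alpha = 1e-8, exclude_seed = TRUE,
                         label = "condition") {
  tbl <- results_table(results)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    abort_config("`alpha` must be a single value in (0, 1].")
  }
  hits <- tbl[tbl$p_value < alpha, , drop = FALSE]
  if (exclude_seed) hits <- hits[!hits$is_seed, , drop = FALSE]
  universe <- if (inherits(results, "seed_friend_test")) {
    sort(results$results$gene)
  } else sort(tbl$gene)
  structure(
    list(label = label, alpha = alpha, members = sort(hits$gene),
         universe = universe, table = hits),
    class = "friend_set")
}

#' @export
print.friend_set <- function(x, ...) {
  cat(sprintf("<friend_set '%s'> %d genes at p < %g (universe %d)\n",
              x$label, length(x$members), x$alpha, length(x$universe)))
  invisible(x)
}

#' @describeIn call_friends Member rows of the friend set.
#' @param x A `friend_set`.
#' @param ... Unused.
#' @export
tidy.friend_set <- function(x, ...) x$table

#' Seed genes significantly coexpressed with the rest of the seed set
#'
#' Each seed gene is tested against the other `K - 1` seeds (the
#' self-exclusion built into [test_all_genes()]); those below `alpha` form
#' the self-connected core of the seed module.
#'
#' @param results A `seed_friend_test` or its `tidy()` table.
#' @param alpha P-value cutoff (default `1e-8`).
#' @return Sorted character vector of self-connected seed gene ids.
#' @export
seed_self_connectivity <- function(results, alpha = 1e-8) {
  tbl <- results_table(results)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    abort_config("`alpha` must be a single value in (0, 1].")
  }
  sort(tbl$gene[tbl$is_seed & tbl$p_value < alpha])
}

#' Write or read a per-gene friend table
#'
#' TSV with columns `gene`, `is_seed`, `k`, `n`, `K_eff`, `N_eff`,
#' `p_value`, `log10_p`, `q_value`, rows in ascending `p_value` order;
#' p-values are written in scientific notation with 10 significant digits,
#' and `log10_p` preserves magnitudes beyond floating-point underflow.
#'
#' @param results A `seed_friend_test` or its `tidy()` table.
#' @param path File path.
#' @return `write_friend_table()` returns `path` invisibly;
#'   `read_friend_table()` returns the tibble.
#' @export
write_friend_table <- function(results, path) {
  tbl <- results_table(results)
  out <- tbl |>
    dplyr::mutate(
      is_seed = as.integer(.data$is_seed),
      p_value = sprintf("%.10e", .data$p_value),
      log10_p = sprintf("%.10g", .data$log10_p),
      q_value = sprintf("%.10e", .data$q_value))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_friend_table
#' @export
read_friend_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(),
    is_seed = readr::col_integer(),
    k = readr::col_integer(),
    n = readr::col_integer(),
    K_eff = readr::col_integer(),
    N_eff = readr::col_integer(),
    p_value = readr::col_double(),
    log10_p = readr::col_double(),
    q_value = readr::col_double())) |>
    dplyr::mutate(is_seed = as.logical(.data$is_seed))
}
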