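# Small in-code fixtures shared across test files.

# Expression tibble from a named list of gene profiles.
make_expr <- function(profiles, sample_prefix = "s") {
  n <- length(profiles[[1L]])
  out <- tibble::tibble(gene_id = names(profiles))
  m <- do.call(rbind, profiles)
  colnames(m) <- paste0(sample_prefix, seq_len(n))
  dplyr::bind_cols(out, tibble::as_tibble(m))
}

# Random expression tibble (independent noise) for property tests.
random_expr <- function(n_genes, n_samples, seed = 1) {
  withr_seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_samples))))
  seedcoex:::matrix_to_expr(m)
}

# set.seed without clobbering subsequent tests' expectations (each test that
# uses randomness sets its own seed anyway).
withr_seed <- function(seed) set.seed(seed)

# Star network: `hub` joined to each of `leaves`.
star_network <- function(hub = "hub", leaves, rho = 0.9, extra_nodes = character(0)) {
  coex_network(
    tibble::tibble(gene_a = hub, gene_b = leaves, rho = rho),
    universe = c(hub, leaves, extra_nodes))
}

# Complete graph over `nodes`.
complete_network <- function(nodes, rho = 0.9) {
  pairs <- t(utils::combn(nodes, 2L))
  coex_network(
    tibble::tibble(gene_a = pairs[, 1L], gene_b = pairs[, 2L], rho = rho),
    universe = nodes)
}

# A tiny GMT collection written to a temp file; returns the path.
write_tmp_gmt <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gmt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

local_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
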