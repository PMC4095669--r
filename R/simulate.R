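#' Configure a paired synthetic expression study
#'
#' Describes a single-factor generative model for two paired expression
#' matrices: a "normal" condition in which a planted seed module (emulating
#' the mitochondrial respiratory complex subunits) and a set of true friend
#' genes load on one shared latent factor, and a "treated" condition in which
#' a chosen fraction of those module genes is decoupled from the factor.
#'
#' Per sample, the latent factor is standard normal and each gene's
#' expression is `a * f + e` with `e ~ Normal(0, noise_sd^2)`; the loading `a`
#' is `loading_seed` for seed genes, `loading_friend` for friend genes and 0
#' for background genes. Two intact module genes with loadings `a` and `b`
#' therefore have population Pearson correlation
#' `a * b / sqrt((a^2 + noise_sd^2) * (b^2 + noise_sd^2))`.
#'
#' In the treated condition the loading of every *disrupted* gene is set to
#' 0. Disruption is deterministic: the first `ceiling(f * seed_size)` seed
#' genes and the first `ceiling(f * n_true_friends)` friend genes in sorted
#' gene-id order, so a partial disruption always leaves both intact and
#' disrupted genes in each role.
#'
#' Defaults mirror the scale of the real study design the generator stands in
#' for: 65 tissue samples against 130 chemically treated samples, a 56-gene
#' seed set, and a universe large enough that background genes dominate.
#'
#' @param n_genes Total genes in the universe.
#' @param n_samples_normal Samples in the normal condition.
#' @param n_samples_treated Samples in the treated condition.
#' @param seed_size Number of planted seed genes.
#' @param n_true_friends Number of non-seed genes loading on the module factor.
#' @param loading_seed Factor loading of seed genes, in `[0, 1]`.
#' @param loading_friend Factor loading of friend genes, in `[0, 1]`.
#' @param noise_sd Standard deviation of independent gene-level noise (> 0).
#' @param disruption_fraction Fraction of module genes decoupled in the
#'   treated condition, in `[0, 1]`.
#' @param rng_seed Integer seed; identical configs generate identical data.
#' @return A `simulation_config` object (a named list).
#' @seealso [generate_paired_dataset()]
#' @export
simulation_config <- function(n_genes = 2000,
                              n_samples_normal = 65,
                              n_samples_treated = 130,
                              seed_size = 56,
                              n_true_friends = 200,
                              loading_seed = 0.9,
                              loading_friend = 0.8,
                              noise_sd = 1,
                              disruption_fraction = 0.5,
                              rng_seed = 1L) {
  cfg <- list(
    n_genes = scalar_count(n_genes, "n_genes", min = 1L),
    n_samples_normal = scalar_count(n_samples_normal, "n_samples_normal", min = 3L),
    n_samples_treated = scalar_count(n_samples_treated, "n_samples_treated", min = 3L),
    seed_size = scalar_count(seed_size, "seed_size", min = 1L),
    n_true_friends = scalar_count(n_true_friends, "n_true_friends", min = 0L),
    loading_seed = scalar_number(loading_seed, "loading_seed", 0, 1),
    loading_friend = scalar_number(loading_friend, "loading_friend", 0, 1),
    noise_sd = scalar_number(noise_sd, "noise_sd", 0, Inf, lower_open = TRUE),
    disruption_fraction = scalar_number(disruption_fraction, "disruption_fraction", 0, 1),
    rng_seed = scalar_count(rng_seed, "rng_seed", min = 0L)
  )
  if (cfg$seed_size + cfg$n_true_friends > cfg$n_genes) {
    abort_config(sprintf(
      "seed_size + n_true_friends must be <= n_genes (%d + %d > %d).",
      cfg$seed_size, cfg$n_true_friends, cfg$n_genes))
  }
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  universe: %d genes (%d seed, %d friend, %d background)\n",
              x$n_genes, x$seed_size, x$n_true_friends,
              x$n_genes - x$seed_size - x$n_true_friends))
  cat(sprintf("  samples: %d normal / %d treated\n",
              x$n_samples_normal, x$n_samples_treated))
  cat(sprintf("  loadings: seed %.2f, friend %.2f; noise sd %.2f\n",
              x$loading_seed, x$loading_friend, x$noise_sd))
  cat(sprintf("  disruption fraction: %.2f; rng seed: %d\n",
              x$disruption_fraction, x$rng_seed))
  invisible(x)
}

#' Generate paired expression matrices with a planted seed module
#'
#' Draws the two conditions described by a [simulation_config()]: every
#' sample gets one latent factor value, module genes load on it, background
#' genes are pure noise, and disrupted genes lose their loading in the
#' treated matrix. Gene and sample identifiers are deterministic, and the
#' whole draw is reproducible from `rng_seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with elements:
#'   * `normal`, `treated`: expression tibbles (`gene_id` + one column per
#'     sample), sharing identical gene ids;
#'   * `truth`: a `simulation_truth` object with `seed_genes`,
#'     `true_friends`, `disrupted_genes` and `background_genes`.
#' @examples
#' sim <- generate_paired_dataset(simulation_config(n_genes = 50,
#'   seed_size = 8, n_true_friends = 5, rng_seed = 7))
#' dim(sim$normal)
#' @export
generate_paired_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_config("`config` must be created by simulation_config().")
  }
  width <- max(5L, nchar(as.character(config$n_genes)))
  gene_ids <- sprintf(paste0("g%0", width, "d"), seq_len(config$n_genes))
  seed_genes <- gene_ids[seq_len(config$seed_size)]
  true_friends <- if (config$n_true_friends > 0)
    gene_ids[config$seed_size + seq_len(config$n_true_friends)] else character(0)
  background <- setdiff(gene_ids, c(seed_genes, true_friends))

  n_dis_seed <- ceiling(config$disruption_fraction * config$seed_size)
  n_dis_friend <- ceiling(config$disruption_fraction * config$n_true_friends)
  disrupted <- c(head(sort(seed_genes), n_dis_seed),
                 head(sort(true_friends), n_dis_friend))

  loadings <- setNames(numeric(config$n_genes), gene_ids)
  loadings[seed_genes] <- config$loading_seed
  loadings[true_friends] <- config$loading_friend
  loadings_treated <- loadings
  loadings_treated[disrupted] <- 0

  draw <- function(a, n_samples, prefix) {
    f <- rnorm(n_samples)
    eps <- matrix(rnorm(length(a) * n_samples, sd = config$noise_sd),
                  nrow = length(a))
    m <- outer(unname(a), f) + eps
    dimnames(m) <- list(gene_ids, sprintf("%s%03d", prefix, seq_len(n_samples)))
    matrix_to_expr(m)
  }

  out <- with_rng_seed(config$rng_seed, {
    normal <- draw(loadings, config$n_samples_normal, "n")
    treated <- draw(loadings_treated, config$n_samples_treated, "t")
    list(normal = normal, treated = treated)
  })

  truth <- structure(
    list(seed_genes = seed_genes,
         true_friends = true_friends,
         disrupted_genes = disrupted,
         background_genes = background),
    class = "simulation_truth")
  c(out, list(truth = truth))
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("<simulation_truth>\n")
  cat(sprintf("  %d seed, %d friend, %d background genes; %d disrupted\n",
              length(x$seed_genes), length(x$true_friends),
              length(x$background_genes), length(x$disrupted_genes)))
  invisible(x)
}

#' Tidy the ground-truth gene roles of a simulation
#'
#' @param x A `simulation_truth` object.
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `role` (`seed`, `friend`,
#'   `background`) and `disrupted` (0/1), sorted by gene id.
#' @export
tidy.simulation_truth <- function(x, ...) {
  tbl <- tibble(
    gene_id = c(x$seed_genes, x$true_friends, x$background_genes),
    role = rep(c("seed", "friend", "background"),
               c(length(x$seed_genes), length(x$true_friends),
                 length(x$background_genes))),
    disrupted = as.integer(.data$gene_id %in% x$disrupted_genes)
  )
  dplyr::arrange(tbl, .data$gene_id)
}

#' Write or read a simulation ground-truth table
#'
#' The on-disk form is a 3-column TSV (`gene_id`, `role`, `disrupted`) that
#' round-trips losslessly through [read_truth()].
#'
#' @param truth A `simulation_truth` object.
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` returns a
#'   `simulation_truth` object.
#' @export
write_truth <- function(truth, path) {
  if (!inherits(truth, "simulation_truth")) {
    abort_config("`truth` must be a simulation_truth object.")
  }
  readr::write_tsv(tidy(truth), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    role = readr::col_character(),
    disrupted = readr::col_integer()))
  bad <- setdiff(unique(tbl$role), c("seed", "friend", "background"))
  if (length(bad)) abort_format(sprintf("unknown role(s): %s", paste(bad, collapse = ", ")))
  structure(
    list(seed_genes = tbl$gene_id[tbl$role == "seed"],
         true_friends = tbl$gene_id[tbl$role == "friend"],
         disrupted_genes = tbl$gene_id[tbl$disrupted == 1L],
         background_genes = tbl$gene_id[tbl$role == "background"]),
    class = "simulation_truth")
}
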