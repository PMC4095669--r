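#' Configure an end-to-end seed coexpression study
#'
#' A pipeline run takes exactly one of two input modes: a pair of expression
#' matrices on disk (`matrix_a`, `matrix_b`, optionally probe-collapsed via
#' `probe_map` and with a `seed_list` file), or a `simulation` block
#' (see [simulation_config()]) whose planted seed genes then serve as the
#' seed set unless a `seed_list` is also given.
#'
#' @param output_dir Directory for all outputs (created if needed).
#' @param matrix_a,matrix_b Paths to the two conditions' expression TSVs.
#' @param probe_map Optional path to a probe-to-symbol map.
#' @param seed_list Optional path to a seed gene list.
#' @param gmt Optional path to a GMT collection; enables enrichment of the
#'   comparison gene lists.
#' @param label_a,label_b Condition labels (default `normal` / `treated`).
#' @param threshold,method,edge_rule Network settings (see [build_network()]).
#' @param alpha Friend-calling cutoff (default `1e-8`).
#' @param ease Use the EASE-modified Fisher test for enrichment.
#' @param min_count Minimum term overlap reported by enrichment.
#' @param simulation Optional [simulation_config()].
#' @param rng_seed Seed recorded in the manifest; overrides the simulation
#'   block's own seed so one value controls the whole run.
#' @return A `pipeline_config` object.
#' @seealso [run_pipeline()]
#' @export
pipeline_config <- function(output_dir,
                            matrix_a = NULL, matrix_b = NULL,
                            probe_map = NULL, seed_list = NULL, gmt = NULL,
                            label_a = "normal", label_b = "treated",
                            threshold = 0.3,
                            method = c("spearman", "pearson"),
                            edge_rule = c("signed", "absolute"),
                            alpha = 1e-8, ease = TRUE, min_count = 2,
                            simulation = NULL, rng_seed = NULL) {
  method <- match.arg(method)
  edge_rule <- match.arg(edge_rule)
  have_matrices <- !is.null(matrix_a) || !is.null(matrix_b)
  have_sim <- !is.null(simulation)
  if (have_matrices == have_sim) {
    abort_config("exactly one of {matrix_a/matrix_b, simulation} must be given.")
  }
  if (have_matrices && (is.null(matrix_a) || is.null(matrix_b))) {
    abort_config("both matrix_a and matrix_b are required in matrix mode.")
  }
  if (have_matrices && is.null(seed_list)) {
    abort_config("`seed_list` is required in matrix mode.")
  }
  if (have_sim && !inherits(simulation, "simulation_config")) {
    abort_config("`simulation` must be a simulation_config().")
  }
  if (have_sim && !is.null(rng_seed)) {
    simulation$rng_seed <- scalar_count(rng_seed, "rng_seed", min = 0L)
  }
  structure(list(
    output_dir = output_dir, matrix_a = matrix_a, matrix_b = matrix_b,
    probe_map = probe_map, seed_list = seed_list, gmt = gmt,
    label_a = label_a, label_b = label_b,
    threshold = scalar_number(threshold, "threshold", 0, 1, lower_open = TRUE),
    method = method, edge_rule = edge_rule,
    alpha = scalar_number(alpha, "alpha", 0, 1, lower_open = TRUE),
    ease = isTRUE(ease),
    min_count = scalar_count(min_count, "min_count", min = 0L),
    simulation = simulation,
    rng_seed = if (have_sim) simulation$rng_seed else rng_seed
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirror the arguments of [pipeline_config()]; an optional nested
#' `simulation:` block holds [simulation_config()] fields.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw <- modifyList(raw, overrides[!vapply(overrides, is.null, TRUE)])
  sim <- raw$simulation
  if (!is.null(sim)) sim <- do.call(simulation_config, sim)
  args <- raw[setdiff(names(raw), "simulation")]
  args$simulation <- sim
  do.call(pipeline_config, args)
}

#' Run the full seed coexpression study
#'
#' Executes every stage in order — obtain the two expression matrices
#' (simulate or read, with optional probe collapse), filter constant genes,
#' build both networks, test every gene against the seed set, call friends
#' and seed self-connectivity, compare the two conditions, and (when a GMT
#' collection is configured) run enrichment of the shared and
#' condition-specific gene lists — writing every result as TSV plus a
#' machine-readable JSON manifest. Re-running with the same configuration
#' and inputs reproduces identical outputs.
#'
#' Files written to `output_dir`: per condition `edges_<label>.tsv`,
#' `nodes_<label>.txt`, `friends_<label>.tsv`,
#' `seed_self_connectivity_<label>.txt`; the cross-condition
#' `comparison_friends.tsv`, `comparison_seed.tsv`, `pvalue_shift.tsv`;
#' `enrichment_<category>.tsv` when enabled; in simulation mode
#' `matrix_<label>.tsv` and `truth.tsv`; and `manifest.json` plus `run.log`.
#'
#' @param config A `pipeline_config` (or path to a YAML file for
#'   [read_pipeline_config()]).
#' @param quiet Suppress stage messages (they are still logged to
#'   `run.log`).
#' @return The manifest, invisibly (a named list also written as JSON).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort_config("`config` must be a pipeline_config() or a YAML path.")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  if (file.exists(log_path)) unlink(log_path)
  say <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    cat(line, "\n", file = log_path, sep = "", append = TRUE)
    if (!quiet) inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = class(e)[1L], parent = e)
    })
  }
  out <- function(...) file.path(config$output_dir, ...)
  labels <- c(a = config$label_a, b = config$label_b)

  # --- inputs -----------------------------------------------------------
  truth <- NULL
  checksums <- list()
  if (!is.null(config$simulation)) {
    sim <- stage("simulate", generate_paired_dataset(config$simulation))
    mats <- list(a = sim$normal, b = sim$treated)
    truth <- sim$truth
    seed <- if (is.null(config$seed_list)) truth$seed_genes else
      stage("seed", read_seed_list(config$seed_list))
    stage("simulate", {
      write_expression_matrix(mats$a, out(sprintf("matrix_%s.tsv", labels["a"])))
      write_expression_matrix(mats$b, out(sprintf("matrix_%s.tsv", labels["b"])))
      write_truth(truth, out("truth.tsv"))
    })
    say("simulate", "generated %d genes x (%d + %d) samples, rng_seed %d",
        config$simulation$n_genes, config$simulation$n_samples_normal,
        config$simulation$n_samples_treated, config$simulation$rng_seed)
  } else {
    mats <- stage("read", list(a = read_expression_matrix(config$matrix_a),
                               b = read_expression_matrix(config$matrix_b)))
    for (p in c(config$matrix_a, config$matrix_b, config$probe_map,
                config$seed_list, config$gmt)) {
      checksums[[basename(p)]] <- unname(tools::md5sum(p))
    }
    if (!is.null(config$probe_map)) {
      map <- stage("collapse", read_probe_map(config$probe_map))
      mats <- stage("collapse", lapply(mats, collapse_probes, probe_map = map))
      say("collapse", "collapsed to %d / %d symbols", nrow(mats$a), nrow(mats$b))
    }
    seed <- stage("seed", read_seed_list(config$seed_list))
    say("read", "matrices: %d x %d and %d x %d",
        nrow(mats$a), ncol(mats$a) - 1L, nrow(mats$b), ncol(mats$b) - 1L)
  }
  say("seed", "seed set: %d genes", length(seed))

  # --- per-condition network + test ------------------------------------
  nets <- list(); tests <- list(); friends <- list(); selfconn <- list()
  for (cond in c("a", "b")) {
    lab <- labels[[cond]]
    m <- stage("filter", filter_uninformative(mats[[cond]]))
    net <- stage("network", build_network(
      m, threshold = config$threshold, method = config$method,
      edge_rule = config$edge_rule))
    say("network", "%s: %d genes, %d edges", lab, length(net$universe),
        nrow(net$edges))
    tst <- stage("test", test_all_genes(net, seed, seed_name = "seed"))
    fr <- call_friends(tst, alpha = config$alpha, label = lab)
    sc <- seed_self_connectivity(tst, alpha = config$alpha)
    say("test", "%s: %d friends, %d/%d self-connected seeds", lab,
        length(fr$members), length(sc), length(tst$seed))
    stage("write", {
      write_edge_list(net, out(sprintf("edges_%s.tsv", lab)),
                      out(sprintf("nodes_%s.txt", lab)))
      write_friend_table(tst, out(sprintf("friends_%s.tsv", lab)))
      writeLines(sc, out(sprintf("seed_self_connectivity_%s.txt", lab)))
    })
    nets[[cond]] <- net; tests[[cond]] <- tst
    friends[[cond]] <- fr; selfconn[[cond]] <- sc
  }

  # --- comparison -------------------------------------------------------
  cmp <- stage("compare", compare_friend_sets(
    friends$a, friends$b, label_a = labels[["a"]], label_b = labels[["b"]]))
  seed_cmp <- stage("compare", compare_seed_self_connectivity(
    selfconn$a, selfconn$b, seed = intersect(seed, union(nets$a$universe, nets$b$universe)),
    label_a = labels[["a"]], label_b = labels[["b"]]))
  shifts <- stage("compare", compare_pvalues(tests$a, tests$b,
                                             label_a = labels[["a"]],
                                             label_b = labels[["b"]]))
  stage("write", {
    write_comparison(cmp, out("comparison_friends.tsv"))
    write_comparison(seed_cmp, out("comparison_seed.tsv"))
    sh <- shifts
    for (cl in setdiff(names(sh), "gene")) sh[[cl]] <- sprintf("%.10e", sh[[cl]])
    readr::write_tsv(sh, out("pvalue_shift.tsv"))
  })
  cmp_counts <- glance(cmp)
  say("compare", "friends both=%d only_%s=%d only_%s=%d",
      cmp_counts$n_both, labels[["a"]], cmp_counts$n_only_a,
      labels[["b"]], cmp_counts$n_only_b)

  # --- enrichment -------------------------------------------------------
  enrichment_files <- character(0)
  if (!is.null(config$gmt)) {
    ann <- stage("enrich", read_gmt(config$gmt))
    population <- intersect(nets$a$universe, nets$b$universe)
    lists <- list(both = comparison_genes(cmp, "both"),
                  only_a = comparison_genes(cmp, "only_a"),
                  only_b = comparison_genes(cmp, "only_b"))
    for (nm in names(lists)) {
      genes <- intersect(lists[[nm]], population)
      rows <- stage("enrich", enrich(genes, population, ann,
                                     ease = config$ease,
                                     min_count = config$min_count))
      f <- out(sprintf("enrichment_%s.tsv", nm))
      write_enrichment(rows, f)
      enrichment_files <- c(enrichment_files, f)
      say("enrich", "%s: %d genes, %d terms reported", nm, length(genes), nrow(rows))
    }
  }

  # --- manifest ---------------------------------------------------------
  cfg_echo <- config
  cfg_echo$simulation <- if (is.null(config$simulation)) NULL else
    unclass(config$simulation)
  manifest <- list(
    package = "seedcoex",
    version = as.character(utils::packageVersion("seedcoex")),
    config = unclass(cfg_echo),
    rng_seed = config$rng_seed,
    input_checksums = checksums,
    seed_size = length(seed),
    conditions = setNames(lapply(c("a", "b"), function(cond) {
      list(n_genes = length(nets[[cond]]$universe),
           n_edges = nrow(nets[[cond]]$edges),
           n_friends = length(friends[[cond]]$members),
           n_self_connected_seeds = length(selfconn[[cond]]),
           seed_size_effective = length(tests[[cond]]$seed))
    }), unname(labels)),
    comparison = as.list(cmp_counts),
    truth = if (is.null(truth)) NULL else
      list(n_seed = length(truth$seed_genes),
           n_friends = length(truth$true_friends),
           n_disrupted = length(truth$disrupted_genes))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  say("done", "outputs in %s", config$output_dir)
  invisible(manifest)
}
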