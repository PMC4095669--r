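test_that("seed neighbour counts follow the edge structure", {
  net <- star_network(leaves = c("m1", "m2", "m3", "x", "y"),
                      extra_nodes = "iso")
  counts <- seed_neighbor_counts(net, c("m1", "m2", "m3"))
  hub <- counts[counts$gene == "hub", ]
  expect_identical(c(hub$k, hub$n), c(3L, 5L))
  iso <- counts[counts$gene == "iso", ]
  expect_identical(c(iso$k, iso$n), c(0L, 0L))
  # a seed gene does not count itself; here m1 touches only the hub
  m1 <- counts[counts$gene == "m1", ]
  expect_identical(c(m1$k, m1$n), c(0L, 1L))
})

test_that("a seed gene connected only to other seeds gets k = n", {
  net <- coex_network(
    tibble::tibble(gene_a = c("s1", "s1"), gene_b = c("s2", "s3"),
                   rho = c(0.5, 0.6)),
    universe = c("s1", "s2", "s3", "bg"))
  counts <- seed_neighbor_counts(net, c("s1", "s2", "s3"))
  s1 <- counts[counts$gene == "s1", ]
  expect_identical(c(s1$k, s1$n), c(2L, 2L))
  tst <- tidy(test_all_genes(net, c("s1", "s2", "s3")))
  expect_identical(unique(tst$K_eff[tst$is_seed]), 2L)    # K - 1
  expect_identical(unique(tst$K_eff[!tst$is_seed]), 3L)
  expect_identical(unique(tst$N_eff), 3L)                 # N - 1
})

test_that("seeds absent from the universe shrink K and an empty overlap errors", {
  net <- star_network(leaves = c("m1", "x"))
  tst <- test_all_genes(net, c("m1", "not_measured"))
  expect_identical(tst$seed, "m1")
  expect_identical(unique(tst$results$K_eff[!tst$results$is_seed]), 1L)
  expect_error(seed_neighbor_counts(net, c("q1", "q2")),
               class = "seedcoex_empty_error")
  expect_error(seed_neighbor_counts(net, character(0)),
               class = "seedcoex_empty_error")
})

test_that("p-values reduce to the exact tail and degenerate cases hit 1", {
  # complete graph on 10 nodes, 4 seeds: a non-seed gene draws everything
  nodes <- sprintf("n%02d", 1:10)
  net <- complete_network(nodes)
  seeds <- nodes[1:4]
  tst <- tidy(test_all_genes(net, seeds))
  non_seed <- tst[!tst$is_seed, ]
  expect_true(all(non_seed$k == 4L & non_seed$n == 9L))
  expect_equal(non_seed$p_value, rep(1, 6))   # C(4,4)C(5,5)/C(9,9)
  # isolated gene: no draws, p = 1
  net2 <- star_network(leaves = c("m1", "x"), extra_nodes = "iso")
  tst2 <- tidy(test_all_genes(net2, "m1"))
  expect_equal(tst2$p_value[tst2$gene == "iso"], 1)
  # every p matches a direct oracle evaluation
  for (i in seq_len(nrow(tst2))) {
    expect_equal(tst2$p_value[i],
                 oracle_hyper_tail(tst2$k[i], tst2$n[i], tst2$K_eff[i], tst2$N_eff[i]),
                 tolerance = 1e-12)
  }
})

test_that("results are sorted by p then gene, with BH and log10 columns", {
  net <- star_network(leaves = c("m1", "m2", "x", "y", "z"))
  tst <- tidy(test_all_genes(net, c("m1", "m2")))
  expect_false(is.unsorted(tst$p_value))
  expect_true(all(tst$q_value >= tst$p_value - 1e-15))
  expect_equal(tst$log10_p, log10(tst$p_value), tolerance = 1e-9)
  ordered_ties <- tst$gene[tst$p_value == 1]
  expect_identical(ordered_ties, sort(ordered_ties))
})

test_that("friend calling applies a strict cutoff and seed exclusion", {
  tbl <- tibble::tibble(
    gene = c("s1", "f1", "f2", "b1"),
    is_seed = c(TRUE, FALSE, FALSE, FALSE),
    p_value = c(1e-12, 1e-10, 1e-8, 0.2))
  fr <- call_friends(tbl, alpha = 1e-8)
  expect_identical(fr$members, "f1")            # p == alpha excluded (strict <)
  fr2 <- call_friends(tbl, alpha = 1e-8, exclude_seed = FALSE)
  expect_setequal(fr2$members, c("s1", "f1"))
  all_one <- tibble::tibble(gene = letters[1:3], is_seed = FALSE, p_value = 1)
  expect_length(call_friends(all_one)$members, 0L)
  expect_length(call_friends(all_one, alpha = 1)$members, 0L)  # p < 1 only
  expect_error(call_friends(tbl, alpha = 0), class = "seedcoex_config_error")
  expect_error(call_friends(tbl, alpha = 2), class = "seedcoex_config_error")
})

test_that("seed self-connectivity returns significant seeds only", {
  tbl <- tibble::tibble(
    gene = c("s1", "s2", "s3", "f1"),
    is_seed = c(TRUE, TRUE, TRUE, FALSE),
    p_value = c(1e-12, 0.5, 1e-9, 1e-20))
  expect_identical(seed_self_connectivity(tbl), c("s1", "s3"))
  # a seed with degree 0 has p = 1 and is never returned
  net <- star_network(leaves = c("m1", "x"), extra_nodes = "m2")
  tst <- test_all_genes(net, c("m1", "m2"))
  expect_false("m2" %in% seed_self_connectivity(tst, alpha = 0.9999))
})

test_that("fully self-connected seeds in sparse background are all recovered", {
  seeds <- sprintf("s%02d", 1:8)
  bg <- sprintf("b%03d", 1:192)
  pairs <- t(utils::combn(seeds, 2L))
  net <- coex_network(
    tibble::tibble(gene_a = pairs[, 1], gene_b = pairs[, 2], rho = 0.8),
    universe = c(seeds, bg))
  tst <- test_all_genes(net, seeds)
  # oracle check: each seed has k = n = 7 of K_eff = 7 in N_eff = 199
  p_exp <- oracle_hyper_tail(7, 7, 7, 100)  # sanity shape at N = 100
  expect_true(p_exp < 1e-8)
  expect_identical(seed_self_connectivity(tst), seeds)
})

test_that("p-values are invariant under a common permutation of samples", {
  x <- random_expr(30, 15, seed = 55)
  perm <- sample(2:ncol(x))  # permutes sample columns identically for all genes
  xp <- x[, c(1L, perm)]
  names(xp) <- names(x)
  seeds <- x$gene_id[1:5]
  t1 <- tidy(test_all_genes(build_network(x), seeds))
  t2 <- tidy(test_all_genes(build_network(xp), seeds))
  expect_equal(t1, t2)
})

test_that("null simulations produce no friends and roughly calibrated tails", {
  false_hits <- 0L
  for (rep in 1:20) {
    cfg <- simulation_config(n_genes = 120, n_samples_normal = 40,
                             n_samples_treated = 3, seed_size = 10,
                             n_true_friends = 0, loading_seed = 0,
                             disruption_fraction = 0, rng_seed = 500 + rep)
    sim <- generate_paired_dataset(cfg)
    tst <- test_all_genes(build_network(sim$normal), sim$truth$seed_genes)
    false_hits <- false_hits + sum(tst$results$p_value < 1e-8)
  }
  expect_identical(false_hits, 0L)
})

test_that("friend tables round-trip through disk in sorted order", {
  net <- star_network(leaves = c("m1", "m2", "x", "y"))
  tst <- test_all_genes(net, c("m1", "m2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_friend_table(tst, path)
  back <- read_friend_table(path)
  expect_equal(back, tidy(tst), tolerance = 1e-9)
  expect_false(is.unsorted(back$p_value))
  # empty results: header only
  empty <- tidy(tst)[0, ]
  write_friend_table(empty, path)
  expect_length(readLines(path), 1L)
})

test_that("seed lists parse comments and blanks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# respiratory complex subunits", "NDUFB5", "", "SDHC  # complex II", "UQCRC2"), path)
  expect_identical(read_seed_list(path), c("NDUFB5", "SDHC", "UQCRC2"))
  writeLines(c("A", "A", "B"), path)
  expect_warning(s <- read_seed_list(path), "duplicates")
  expect_identical(s, c("A", "B"))
  writeLines("# nothing", path)
  expect_error(read_seed_list(path), class = "seedcoex_empty_error")
})
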