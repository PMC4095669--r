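fs <- function(members, label = "x", universe = NULL, alpha = 1e-8) {
  structure(list(label = label, alpha = alpha, members = sort(members),
                 universe = sort(universe %||% members),
                 table = tibble::tibble()),
            class = "friend_set")
}

test_that("friend comparison is plain set arithmetic on a shared universe", {
  uni <- sprintf("g%d", 1:6)
  cmp <- compare_friend_sets(fs(c("g1", "g2", "g3"), "normal", uni),
                             fs(c("g3", "g4"), "treated", uni))
  expect_identical(comparison_genes(cmp, "both"), "g3")
  expect_identical(comparison_genes(cmp, "only_a"), c("g1", "g2"))
  expect_identical(comparison_genes(cmp, "only_b"), "g4")
  g <- glance(cmp)
  expect_identical(c(g$n_both, g$n_only_a, g$n_only_b), c(1L, 2L, 1L))

  same <- compare_friend_sets(fs(c("a", "b"), universe = letters),
                              fs(c("a", "b"), universe = letters))
  expect_length(comparison_genes(same, "only_a"), 0L)
  expect_identical(comparison_genes(same, "both"), c("a", "b"))

  disjoint <- compare_friend_sets(fs("a", universe = letters),
                                  fs("b", universe = letters))
  expect_length(comparison_genes(disjoint, "both"), 0L)
})

test_that("partition identities hold for random friend sets", {
  set.seed(19)
  uni <- sprintf("g%03d", 1:200)
  for (i in 1:20) {
    a <- sample(uni, sample(0:80, 1))
    b <- sample(uni, sample(0:80, 1))
    cmp <- compare_friend_sets(fs(a, "a", uni), fs(b, "b", uni))
    both <- comparison_genes(cmp, "both")
    oa <- comparison_genes(cmp, "only_a")
    ob <- comparison_genes(cmp, "only_b")
    expect_length(intersect(oa, ob), 0L)
    expect_length(intersect(both, c(oa, ob)), 0L)
    expect_setequal(c(both, oa), a)
    expect_setequal(c(both, ob), b)
    # mirror image
    rev_cmp <- compare_friend_sets(fs(b, "b", uni), fs(a, "a", uni))
    expect_setequal(comparison_genes(rev_cmp, "only_a"), ob)
    expect_setequal(comparison_genes(rev_cmp, "only_b"), oa)
  }
})

test_that("friends unassessable in the other condition are flagged, not binned", {
  uni_a <- c("g1", "g2", "g3", "g4")
  uni_b <- c("g1", "g2", "g3")          # g4 never measured under treatment
  cmp <- compare_friend_sets(fs(c("g1", "g4"), "a", uni_a),
                             fs("g1", "b", uni_b))
  expect_identical(comparison_genes(cmp, "both"), "g1")
  expect_length(comparison_genes(cmp, "only_a"), 0L)
  expect_identical(comparison_genes(cmp, "unassessable"), "g4")
})

test_that("mismatched cutoffs trigger a warning", {
  expect_warning(compare_friend_sets(fs("a", alpha = 1e-8), fs("a", alpha = 1e-4)),
                 "different cutoffs")
})

test_that("seed self-connectivity comparison stays inside the seed set", {
  seed <- c("s1", "s2", "s3", "s4")
  cmp <- compare_seed_self_connectivity(c("s1", "s2", "s3"), c("s2", "s3"), seed)
  expect_identical(comparison_genes(cmp, "only_a"), "s1")
  expect_identical(comparison_genes(cmp, "both"), c("s2", "s3"))
  all_lost <- compare_seed_self_connectivity(seed, character(0), seed)
  expect_identical(comparison_genes(all_lost, "only_a"), seed)
  same <- compare_seed_self_connectivity(c("s1"), c("s1"), seed)
  expect_length(comparison_genes(same, "only_a"), 0L)
  expect_error(compare_seed_self_connectivity(c("s1", "zz"), "s1", seed),
               class = "seedcoex_domain_error")
})

test_that("comparisons round-trip through disk with a count summary", {
  cmp <- compare_seed_self_connectivity(c("s1", "s2", "s3", "s5"), c("s3", "s4"),
                                        sprintf("s%d", 1:9),
                                        label_a = "normal", label_b = "treated")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_comparison(cmp, path)
  first <- readLines(path, n = 1L)
  expect_match(first, "both=1 only_a=3 only_b=1")
  back <- read_comparison(path)
  expect_equal(back, cmp)

  empty <- compare_seed_self_connectivity(character(0), character(0), "s1")
  write_comparison(empty, path)
  expect_match(readLines(path, n = 1L), "both=0 only_a=0 only_b=0")
  expect_identical(nrow(tidy(read_comparison(path))), 0L)
})

test_that("p-value shift report pairs conditions and ranks lost significance", {
  sim <- generate_paired_dataset(
    simulation_config(n_genes = 150, seed_size = 12, n_true_friends = 10,
                      n_samples_normal = 50, n_samples_treated = 50,
                      disruption_fraction = 1, rng_seed = 21))
  ta <- test_all_genes(build_network(sim$normal), sim$truth$seed_genes)
  tb <- test_all_genes(build_network(sim$treated), sim$truth$seed_genes)
  sh <- compare_pvalues(ta, tb, "normal", "treated")
  expect_named(sh, c("gene", "p_normal", "p_treated", "log10_ratio"))
  expect_identical(nrow(sh), 150L)
  # fully disrupted module: top of the ranking is dominated by module genes
  top <- head(sh$gene, 10)
  module <- c(sim$truth$seed_genes, sim$truth$true_friends)
  expect_gte(mean(top %in% module), 0.8)
})
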