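test_that("spearman_rho reproduces hand-computed rank correlations", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_rho(x, x), 1)
  xi <- c(1, 2, 5, 7, 11)
  expect_equal(spearman_rho(xi, rev(xi)), -1)
  # ties: ranks of (1,2,2,4) are (1, 2.5, 2.5, 4)
  rx <- c(1, 2.5, 2.5, 4); ry <- 1:4
  expected <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(10, 20, 30, 40)), expected)
})

test_that("spearman_rho is symmetric, bounded and monotone-invariant", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(12); y <- rnorm(12)
    r <- spearman_rho(x, y)
    expect_equal(r, spearman_rho(y, x))
    expect_true(r >= -1 && r <= 1)
    expect_equal(spearman_rho(exp(2 * x), y), r)       # strictly increasing
    expect_equal(spearman_rho(x, -y^3 - 5 * y), -r)    # strictly decreasing
  }
})

test_that("tie-free spearman matches the closed form 1 - 6*sum(d^2)/(n(n^2-1))", {
  set.seed(8)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    x <- sample(seq_len(1000), n); y <- sample(seq_len(1000), n)
    d <- rank(x) - rank(y)
    expect_equal(spearman_rho(x, y), 1 - 6 * sum(d^2) / (n * (n^2 - 1)),
                 tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "constant")
  expect_error(spearman_rho(1:4, 1:3), "equal length")
})

test_that("duplicated profiles produce a single perfect edge", {
  x <- make_expr(list(a = c(1, 3, 2, 5, 4), b = c(1, 3, 2, 5, 4),
                      c = c(2, -1, 0, -3, 1)))
  net <- build_network(x, threshold = 0.9)
  expect_identical(nrow(net$edges), 1L)
  expect_identical(net$edges$gene_a, "a")
  expect_identical(net$edges$gene_b, "b")
  expect_equal(net$edges$rho, 1)
  expect_setequal(net$universe, c("a", "b", "c"))  # isolated node kept
})

test_that("signed rule drops strong negative pairs; absolute keeps them", {
  x <- make_expr(list(a = c(1, 2, 3, 4, 5), b = c(5, 4, 3, 2, 1)))
  signed <- build_network(x, threshold = 0.3, edge_rule = "signed")
  expect_identical(nrow(signed$edges), 0L)
  absolute <- build_network(x, threshold = 0.3, edge_rule = "absolute")
  expect_identical(nrow(absolute$edges), 1L)
  expect_equal(absolute$edges$rho, -1)
})

test_that("edges are exactly the pairs whose rho clears the threshold", {
  x <- make_expr(list(
    g1 = c(1, 2, 3, 4, 5, 6),
    g2 = c(2, 1, 4, 3, 6, 5),
    g3 = c(6, 5, 1, 3, 2, 4),
    g4 = c(1, 3, 2, 6, 4, 5)))
  m <- seedcoex:::expr_to_matrix(x)
  genes <- rownames(m)
  # enumerate all 6 pairs with an independent rank computation
  expected <- list()
  for (i in 1:3) for (j in (i + 1):4) {
    r <- cor(rank(m[i, ]), rank(m[j, ]))
    if (r >= 0.3) expected[[paste(genes[i], genes[j])]] <- r
  }
  net <- build_network(x, threshold = 0.3)
  got <- setNames(net$edges$rho, paste(net$edges$gene_a, net$edges$gene_b))
  expect_mapequal(as.list(got), expected)
  expect_lte(nrow(net$edges), 4 * 3 / 2)
})

test_that("raising the threshold never adds edges", {
  x <- random_expr(40, 12, seed = 77)
  pair_key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  lo <- build_network(x, threshold = 0.3)
  hi <- build_network(x, threshold = 0.5)
  expect_true(all(pair_key(hi) %in% pair_key(lo)))
  # and the network never has more than m(m-1)/2 edges
  expect_lte(nrow(lo$edges), 40 * 39 / 2)
})

test_that("network invariants are enforced by the constructor", {
  expect_error(coex_network(tibble::tibble(gene_a = "a", gene_b = "a", rho = 1),
                            universe = "a"), "self-loops")
  expect_error(coex_network(
    tibble::tibble(gene_a = c("a", "b"), gene_b = c("b", "a"), rho = c(0.5, 0.6)),
    universe = c("a", "b")), "duplicate edges")
  expect_error(coex_network(tibble::tibble(gene_a = "a", gene_b = "z", rho = 0.5),
                            universe = c("a", "b")), "outside the universe")
  expect_error(coex_network(tibble::tibble(gene_a = "a", gene_b = "b", rho = 0.1),
                            universe = c("a", "b")), "edge rule")
  expect_error(build_network(make_expr(list(a = 1:3, b = 3:1)), threshold = 0),
               class = "seedcoex_config_error")
})

test_that("edge lists round-trip with canonical pair ordering", {
  net <- coex_network(
    tibble::tibble(gene_a = c("B", "c", "a"), gene_b = c("A", "a", "d"),
                   rho = c(0.4, 0.55, 0.31)),
    universe = c("A", "B", "a", "c", "d", "lonely"),
    threshold = 0.3)
  ep <- withr::local_tempfile(fileext = ".tsv")
  np <- withr::local_tempfile(fileext = ".txt")
  write_edge_list(net, ep, np)
  lines <- readLines(ep)
  expect_match(lines[3], "^A\tB\t0\\.4$")  # (B, A) stored as A B
  back <- read_edge_list(ep, np)
  expect_equal(back, net)

  empty <- coex_network(tibble::tibble(gene_a = character(0),
                                       gene_b = character(0), rho = numeric(0)),
                        universe = letters[1:5])
  write_edge_list(empty, ep, np)
  expect_length(readLines(np), 5L)
  back2 <- read_edge_list(ep, np)
  expect_identical(nrow(back2$edges), 0L)
  expect_length(back2$universe, 5L)
})

test_that("degrees cover every gene including isolated ones", {
  net <- star_network(leaves = c("x", "y", "z"), extra_nodes = "iso")
  deg <- network_degrees(net)
  expect_identical(deg$degree[deg$gene == "hub"], 3L)
  expect_identical(deg$degree[deg$gene == "iso"], 0L)
})
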