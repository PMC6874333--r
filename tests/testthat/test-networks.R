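test_that("pearson_matrix is symmetric, clipped and NaN-free", {
  m <- matrix(c(1, 2, 3,
                3, 2, 1,
                2, 4, 6,
                5, 5, 5), ncol = 4,
              dimnames = list(c("s1", "s2", "s3"),
                              c("x", "xr", "x2", "const")))
  expect_warning(r <- pearson_matrix(OTUTable(m)), "constant")
  expect_equal(r["x", "xr"], -1)       # exact anti-correlation
  expect_equal(r["x", "x2"], 1)        # duplicated taxon (scaled)
  expect_equal(unname(r[, "const"]), c(0, 0, 0, 1))  # defined as 0, not NaN
  expect_true(all(r >= -1 & r <= 1))
  expect_identical(r, t(r))
  expect_error(pearson_matrix(OTUTable(m[1:2, ])), "3 samples")
})

test_that("proxi graph follows nearest-neighbour structure", {
  # x2 = 2 * x1 (distance 0), x3 independent; k = 1 links the twins
  withr::local_seed(1)
  x1 <- rpois(12, 30) + 1
  m <- cbind(x1 = x1, x2 = 2 * x1, x3 = rpois(12, 30) + 1,
             x4 = rpois(12, 30) + 1)
  rownames(m) <- sprintf("s%02d", 1:12)
  g <- build_proxi(OTUTable(m), k_neighbors = 1)
  expect_true(igraph::are_adjacent(g, "x1", "x2"))

  # k = n_taxa - 1 gives the complete graph
  gc <- build_proxi(OTUTable(m), k_neighbors = 3)
  expect_equal(igraph::ecount(gc), choose(4, 2))

  # union rule: every node has degree >= k
  tab <- make_benchmark(n_taxa = 30, n_planted = 0, n_per_group = 25,
                        seed = 3)$table
  gu <- build_proxi(tab, k_neighbors = 7)
  expect_true(all(igraph::degree(gu) >= 7))
  gm <- build_proxi(tab, k_neighbors = 7, rule = "mutual")
  expect_true(all(apply(igraph::as_edgelist(gm), 1, function(e)
    igraph::are_adjacent(gu, e[1], e[2]))))  # mutual edges subset of union
  expect_error(build_proxi(OTUTable(m), k_neighbors = 4), "n_taxa")
})

test_that("proxi is invariant to sign flips of a taxon (|r| unchanged)", {
  tab <- toy_table(n_per_group = 10, n_taxa = 9)
  g1 <- build_proxi(tab, k_neighbors = 3, log_transform = FALSE)
  flipped <- tab$values
  # linear reversal x -> max + min - x: negates r, preserves |r|, stays >= 0
  flipped[, 3] <- max(flipped[, 3]) + min(flipped[, 3]) - flipped[, 3]
  g2 <- build_proxi(OTUTable(flipped), k_neighbors = 3,
                    log_transform = FALSE)
  expect_setequal(apply(igraph::as_edgelist(g1), 1, paste, collapse = "|"),
                  apply(igraph::as_edgelist(g2), 1, paste, collapse = "|"))
})

test_that("sparcc is compositionally invariant and sparse under the null", {
  bench <- make_benchmark(n_taxa = 25, n_planted = 0, n_per_group = 60,
                          seed = 13, zero_inflation = 0)
  tab <- split_by_phenotype(bench$table)[[1]]
  g1 <- build_sparcc(tab)
  rho1 <- igraph::graph_attr(g1, "rho")

  scaled <- tab$values
  scaled[4, ] <- scaled[4, ] * 10  # rescale one sample's row
  g2 <- build_sparcc(OTUTable(scaled))
  rho2 <- igraph::graph_attr(g2, "rho")
  expect_lt(max(abs(rho1 - rho2)), 1e-9)
})

test_that("sparcc excludes a duplicated taxon pair in the first iteration", {
  withr::local_seed(8)
  m <- matrix(rpois(200, 50), 20, 10)
  m[, 10] <- m[, 9]  # perfect duplicate
  dimnames(m) <- list(sprintf("s%02d", 1:20), sprintf("t%02d", 1:10))
  g <- build_sparcc(OTUTable(m))
  excl <- igraph::graph_attr(g, "excluded")
  expect_gte(nrow(excl), 1)
  expect_equal(unname(excl[1, ]), c("t09", "t10"))
})

test_that("sparcc separates truth edges from non-edges on deep data", {
  bench <- make_benchmark(n_taxa = 25, n_planted = 0, n_per_group = 150,
                          seed = 17, zero_inflation = 0)
  tab <- split_by_phenotype(bench$table)[[1]]
  rho <- igraph::graph_attr(build_sparcc(tab), "rho")
  A <- adj_of(bench$truth_graph_a)[rownames(rho), colnames(rho)]
  diag(rho) <- NA
  expect_gt(mean(abs(rho)[A == 1], na.rm = TRUE),
            mean(abs(rho)[A == 0], na.rm = TRUE))
})

test_that("mb recovers a conditional-independence chain and obeys its rules", {
  # strong chain a - b - c: partial correlation of (a, c) given b is 0
  withr::local_seed(30)
  n <- 400
  a <- rnorm(n); b <- 0.9 * a + rnorm(n, sd = 0.4); c <- 0.9 * b + rnorm(n, sd = 0.4)
  noise <- matrix(rnorm(n * 9), n, 9)
  m <- exp(cbind(a = a, b = b, c = c, noise))
  colnames(m) <- c("a", "b", "c", sprintf("n%d", 1:9))
  rownames(m) <- sprintf("s%03d", seq_len(n))
  tab <- OTUTable(m)
  g <- build_mb(tab, density_target = 0.06)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "b", "c"))
  expect_false(igraph::are_adjacent(g, "a", "c"))

  # huge penalty -> empty graph; AND edges subset of OR edges
  g_inf <- build_mb(tab, lambda_grid = c(1e6))
  expect_equal(igraph::ecount(g_inf), 0)
  # rule containment must be compared at one shared penalty
  g_or <- build_mb(tab, lambda_grid = 0.05, merge_rule = "OR",
                   density_target = 1)
  g_and <- build_mb(tab, lambda_grid = 0.05, merge_rule = "AND",
                    density_target = 1)
  ek <- function(g) apply(igraph::as_edgelist(g), 1, function(e)
    paste(sort(e), collapse = "|"))
  expect_true(all(ek(g_and) %in% ek(g_or)))
  expect_error(build_mb(tab, lambda_grid = numeric(0)), "non-empty")
})

test_that("rmt fixed thresholds behave at the extremes and auto mode stays on grid", {
  bench <- make_benchmark(n_taxa = 40, n_planted = 0, n_per_group = 60,
                          seed = 19)
  tab <- split_by_phenotype(bench$table)[[1]]
  g_hi <- build_rmt(tab, threshold_mode = "fixed", fixed_threshold = 1.01)
  expect_equal(igraph::ecount(g_hi), 0)
  g_lo <- build_rmt(tab, threshold_mode = "fixed", fixed_threshold = 0)
  n <- igraph::vcount(g_lo)
  expect_equal(igraph::ecount(g_lo), choose(n, 2))

  g_auto <- suppressWarnings(build_rmt(tab))
  thr <- igraph::graph_attr(g_auto, "threshold")
  expect_gte(thr, 0.30)
  expect_lte(thr, 0.95)
  expect_gt(igraph::ecount(g_auto), 0)
})

test_that("all constructors emit simple undirected graphs over input taxa", {
  tab <- split_by_phenotype(make_benchmark(n_taxa = 30, n_planted = 3,
                                           n_per_group = 40,
                                           seed = 23)$table)[[1]]
  for (build in list(build_proxi, build_sparcc, build_mb,
                     function(t) suppressWarnings(build_rmt(t)))) {
    g <- build(tab)
    expect_true(igraph::is_simple(g))
    expect_false(igraph::is_directed(g))
    expect_true(all(igraph::V(g)$name %in% colnames(tab$values)))
  }
})
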