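test_that("degree-preserving rewiring keeps degrees and weights exactly", {
  g <- rand_graph(20, p = 0.3, seed = 2)
  cc <- function(x) igraph::transitivity(
    igraph::graph_from_adjacency_matrix(x$adjacency > 0, "undirected"))
  null_cc <- numeric(30)
  for (r in 1:30) {
    s <- maslov_sneppen_rewire(g, seed = r)
    expect_simple_graph(s)
    expect_identical(degree_seq(s), degree_seq(g))
    expect_equal(edge_multiset(s), edge_multiset(g))
    null_cc[r] <- cc(s)
  }
  # topology is actually randomized: clustering moves off the original value
  expect_gt(abs(mean(null_cc) - cc(g)), 1e-3)
})

test_that("graphs without a valid swap are returned unchanged", {
  expect_warning(s <- maslov_sneppen_rewire(fx$star4, seed = 1),
                 "no valid")
  expect_identical(s$adjacency, fx$star4$adjacency)
  expect_equal(attr(s, "n_accepted"), 0L)
  expect_warning(maslov_sneppen_rewire(fx$k4, seed = 1), "no valid")
})

test_that("geometry-preserving rewiring respects distance bins", {
  g <- synth_connectome(n_nodes = 40, target_density = 0.3, seed = 4)
  ed <- connectome_edges(g)
  emp_rho <- cor(ed$weight, ed$length, method = "spearman")
  n_bins <- 8
  br <- quantile(ed$length, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  orig_counts <- tabulate(findInterval(ed$length, br,
                                       rightmost.closed = TRUE),
                          nbins = n_bins)
  rho_null <- numeric(20)
  for (r in 1:20) {
    s <- geometry_preserving_rewire(g, n_bins = n_bins, seed = r)
    expect_simple_graph(s)
    expect_identical(degree_seq(s), degree_seq(g))
    expect_equal(edge_multiset(s), edge_multiset(g))
    eds <- connectome_edges(s)
    cnt <- tabulate(findInterval(eds$length, br, rightmost.closed = TRUE),
                    nbins = n_bins)
    expect_true(all(cnt >= pmin(floor(orig_counts * 0.8), orig_counts - 1)))
    expect_true(all(cnt <= pmax(ceiling(orig_counts * 1.2),
                                orig_counts + 1)))
    rho_null[r] <- cor(eds$weight, eds$length, method = "spearman")
  }
  # weight-length anticorrelation keeps its sign in the surrogates
  expect_true(mean(sign(rho_null) == sign(emp_rho)) > 0.9)
  expect_error(geometry_preserving_rewire(connectome(fx$k4$adjacency)),
               "coordinates")
})

test_that("null z-scores follow the definition", {
  suppressWarnings({   # 5-value null: small-sample warning is expected
    expect_equal(null_zscore(3, c(1, 2, 3, 4, 5))$z, 0)
    z1 <- null_zscore(3 + sqrt(2.5), c(1, 2, 3, 4, 5))
  })
  expect_equal(z1$z, 1)
  set.seed(11)
  nv <- rnorm(40, 5, 2)
  expect_equal(null_zscore(6, nv)$z, (6 - mean(nv)) / sd(nv))
  expect_error(null_zscore(1, rep(2, 30)), "zero standard deviation")
})

test_that("empirical energy beats degree-preserving nulls on a geometric graph", {
  g <- synth_connectome(n_nodes = 30, target_density = 0.3, seed = 6)
  maps <- synth_state_maps(g, k_maps = 8, seed = 6)
  rep1 <- empirical_vs_null_energy(g, maps, "degree_preserving",
                                   n_nulls = 20, n_steps = 100, seed = 1)
  expect_length(rep1$null_values, 20)
  expect_lt(rep1$z, 0)
  expect_lt(rep1$p, 0.5)
  # reproducible given (seed, parameters)
  rep2 <- empirical_vs_null_energy(g, maps, "degree_preserving",
                                   n_nulls = 20, n_steps = 100, seed = 1)
  expect_identical(rep1$null_values, rep2$null_values)
})

test_that("a degenerate null ensemble takes the z = 0 path", {
  maps <- matrix(rnorm(8), 4, 2)
  suppressWarnings(
    rep0 <- empirical_vs_null_energy(fx$star4, maps, "degree_preserving",
                                     n_nulls = 20, n_steps = 100, seed = 1))
  expect_true(rep0$degenerate)
  expect_equal(rep0$z, 0)
})

test_that("domain permutation test matches exact enumeration on a toy case", {
  scores <- c(a = 5, b = 4, c = 1, d = 2, e = 3)
  labs <- c("hi", "hi", "lo", "lo", "lo")
  res <- permutation_domain_test(scores, labs, n_perm = 4000, seed = 2)
  p_hi <- res$p[res$domain == "hi"]
  # exact: only 1 of the C(5,2) = 10 subsets has median >= 4.5
  expect_gt(p_hi, 0.06)
  expect_lt(p_hi, 0.15)

  flat <- rep(1, 6)
  res2 <- permutation_domain_test(flat, rep(c("x", "y"), 3), n_perm = 200,
                                  seed = 3)
  expect_true(all(res2$p > 0.95))

  res3 <- permutation_domain_test(scores, labs, n_perm = 500, seed = 9)
  res4 <- permutation_domain_test(scores, labs, n_perm = 500, seed = 9)
  expect_identical(res3, res4)
  expect_warning(
    permutation_domain_test(scores, c("hi", "lo", "lo", "lo", NA),
                            n_perm = 50, seed = 1), "< 2 terms")
})
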