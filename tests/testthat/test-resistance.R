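test_that("effective resistance matches closed forms", {
  w <- 2.5
  two <- connectome(rbind(c(0, w), c(w, 0)))
  expect_equal(unname(effective_resistance(two)$omega),
               rbind(c(0, 1 / w), c(1 / w, 0)))

  tri <- effective_resistance(fx$triangle)$omega
  expect_equal(unname(tri[upper.tri(tri)]), rep(2 / 3, 3))

  pa <- effective_resistance(fx$path4)$omega
  expect_equal(pa[1, 4], 3)
  expect_equal(pa[1, 2], 1)
})

test_that("Foster identity and metric property hold on random graphs", {
  for (seed in 1:6) {
    g <- rand_graph(sample(5:15, 1), seed = seed)
    om <- effective_resistance(g)$omega
    expect_equal(max(abs(om - t(om))), 0)
    expect_true(all(diag(om) == 0))
    ed <- connectome_edges(g)
    foster <- sum(ed$weight * om[cbind(ed$i, ed$j)])
    expect_equal(foster, g$n_nodes - 1, tolerance = 1e-8)
    n <- g$n_nodes
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(om[i, k], om[i, j] + om[j, k] + 1e-12)
  }
})

test_that("disconnected graphs are rejected with components named", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1
  expect_error(effective_resistance(a), "disconnected")
})

test_that("commute time equals vol * omega and random-walk round trips", {
  two <- connectome(rbind(c(0, 1), c(1, 0)))
  expect_equal(unname(commute_time(two)), rbind(c(0, 2), c(2, 0)))
  expect_equal(commute_time(fx$triangle)[1, 2], 4)

  # oracle: mean first-passage times of the explicit random-walk chain
  g <- rand_graph(6, seed = 3)
  a <- g$adjacency
  P <- a / rowSums(a)
  n <- nrow(a)
  mfpt <- matrix(0, n, n)
  for (j in 1:n) {
    idx <- setdiff(1:n, j)
    # m_ij = 1 + sum_k P_ik m_kj for i != j
    mfpt[idx, j] <- solve(diag(n - 1) - P[idx, idx], rep(1, n - 1))
  }
  expect_equal(unname(commute_time(g)), unname(mfpt + t(mfpt)),
               tolerance = 1e-8)
})

test_that("map_to_distribution rescales min to zero and sums to one", {
  expect_equal(map_to_distribution(c(1, 2, 3)), c(0, 1, 2) / 3)
  p <- c(0, 0.25, 0.75)
  expect_equal(map_to_distribution(p), p)
  expect_equal(map_to_distribution(c(-1, 0, 1)), c(0, 1, 2) / 3)
  expect_error(map_to_distribution(rep(2, 4)), "constant")
})

test_that("network variance equals the brute-force double sum", {
  two <- connectome(rbind(c(0, 1), c(1, 0)))
  r2 <- effective_resistance(two)
  expect_equal(network_variance(r2, c(1, 0)), 0)
  expect_equal(network_variance(r2, c(0.5, 0.5)), 0.25)

  for (seed in 1:5) {
    n <- sample(8:20, 1)
    g <- rand_graph(n, seed = 100 + seed)
    r <- effective_resistance(g)
    set.seed(seed)
    p <- map_to_distribution(runif(n))
    brute <- 0
    for (i in 1:n) for (j in 1:n) brute <- brute + p[i] * p[j] * r$omega[i, j]
    expect_equal(network_variance(r, p), brute / 2, tolerance = 1e-12)
    expect_lte(network_variance(r, p), 0.5 * max(r$omega))
    # invariance to simultaneous relabeling
    perm <- sample(n)
    expect_equal(network_variance(r$omega[perm, perm], p[perm]),
                 network_variance(r, p), tolerance = 1e-12)
  }
})
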