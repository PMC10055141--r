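test_that("solver agrees with the direct-transcription oracle", {
  # 3-node system, 2000-step transcription grid
  set.seed(21)
  g <- rand_graph(3, p = 1, seed = 21)
  s <- normalize_adjacency(g)
  x0 <- rnorm(3) / sqrt(3); xT <- rnorm(3) / sqrt(3)
  tr <- solve_optimal_control(control_problem(s, x0, xT), n_steps = 1000)
  ref <- oracle_control_energy(s$a_norm, rep(1, 3), x0, xT, K = 2000)
  expect_lt(abs(tr$total_energy - ref) / ref, 0.005)
})

test_that("trajectory hits the boundary conditions", {
  set.seed(8)
  g <- rand_graph(6, seed = 8)
  s <- normalize_adjacency(g)
  x0 <- rnorm(6); xT <- rnorm(6)
  tr <- solve_optimal_control(control_problem(s, x0, xT), n_steps = 300)
  expect_identical(tr$states[1, ], x0)
  expect_lt(sqrt(sum((tr$states[nrow(tr$states), ] - xT)^2)) /
              sqrt(sum(xT^2)), 1e-6)
  expect_equal(tr$total_energy, sum(tr$energy_per_node))
  expect_true(all(tr$energy_per_node >= 0))
  # u = -B' lambda / (2 rho) along the whole trajectory
  expect_equal(tr$inputs, -tr$costates / 2, tolerance = 1e-12)
})

test_that("energy is degree-2 homogeneous in the state pair", {
  set.seed(9)
  g <- rand_graph(5, seed = 9)
  s <- normalize_adjacency(g)
  x0 <- rnorm(5); xT <- rnorm(5)
  e1 <- solve_optimal_control(control_problem(s, x0, xT), 300)$total_energy
  for (alpha in c(0.5, 2, 10)) {
    ea <- solve_optimal_control(control_problem(s, alpha * x0, alpha * xT),
                                300)$total_energy
    expect_equal(ea / e1, alpha^2, tolerance = 1e-6)
  }
})

test_that("an equilibrium state costs nothing to hold", {
  g <- rand_graph(6, seed = 12)
  s <- normalize_adjacency(g, c = 0)
  v <- eigen(s$a_norm, symmetric = TRUE)$vectors[, 1]  # a_norm v = 0
  tr <- solve_optimal_control(control_problem(s, v, v), 300)
  expect_lt(tr$total_energy, 1e-10)
  expect_lt(max(abs(tr$inputs)), 1e-6)
})

test_that("transition energy matrix is consistent with per-pair solves", {
  set.seed(30)
  g <- rand_graph(5, seed = 30)
  states <- matrix(rnorm(20), 5, 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  tem <- transition_energy_matrix(g, states, n_steps = 200)
  expect_true(all(tem$energies >= 0) && all(is.finite(tem$energies)))
  s <- normalize_adjacency(g)
  for (i in 1:4) for (j in 1:4) {
    e <- solve_optimal_control(
      control_problem(s, states[, i], states[, j]), 200)$total_energy
    expect_equal(unname(tem$energies[i, j]), e, tolerance = 1e-8)
  }
})

test_that("degenerate state sets give the forced matrix shapes", {
  g <- rand_graph(6, seed = 13)
  s <- normalize_adjacency(g)
  set.seed(13)
  v <- rnorm(6)
  same <- cbind(v, v, v)
  tem <- transition_energy_matrix(s, same, n_steps = 150)
  expect_equal(max(tem$energies) - min(tem$energies), 0, tolerance = 1e-10)

  v0 <- eigen(s$a_norm, symmetric = TRUE)$vectors[, 1]
  tem2 <- transition_energy_matrix(s, cbind(v0, -v0), n_steps = 150)$energies
  expect_lt(max(abs(diag(tem2))), 1e-10)
  expect_equal(tem2[1, 2], tem2[2, 1], tolerance = 1e-8)
})

test_that("state normalization option rescales to unit norm", {
  g <- rand_graph(5, seed = 14)
  set.seed(14)
  states <- matrix(rnorm(10), 5, 2)
  t1 <- transition_energy_matrix(g, states, n_steps = 150,
                                 normalize_states = TRUE)
  unit <- sweep(states, 2, sqrt(colSums(states^2)), `/`)
  t2 <- transition_energy_matrix(g, unit, n_steps = 150)
  expect_equal(t1$energies, t2$energies, tolerance = 1e-12)
})

test_that("input-cost trade-off is monotone in rho", {
  set.seed(15)
  g <- rand_graph(6, seed = 15)
  s <- normalize_adjacency(g)
  x0 <- rnorm(6); xT <- rnorm(6)
  rhos <- c(0.25, 0.5, 1, 2, 4)
  U <- vapply(rhos, function(r)
    solve_optimal_control(control_problem(s, x0, xT, rho = r),
                          200)$total_energy, numeric(1))
  expect_true(all(diff(U) <= 1e-10))            # less input used as it gets dearer
  expect_true(all(diff(rhos * U) >= -1e-10))    # weighted cost component grows
})

test_that("uniformly larger input gains never cost more energy", {
  set.seed(16)
  g <- rand_graph(6, seed = 16)
  s <- normalize_adjacency(g)
  x0 <- rnorm(6); xT <- rnorm(6)
  E <- vapply(c(0.5, 1, 2, 4), function(gain)
    solve_optimal_control(control_problem(s, x0, xT, b_diag = rep(gain, 6)),
                          200)$total_energy, numeric(1))
  expect_true(all(diff(E) < 0))
})

test_that("invalid problems are rejected", {
  g <- rand_graph(4, seed = 17)
  s <- normalize_adjacency(g)
  expect_error(control_problem(s, 1:3, 1:4), "dimension")
  expect_error(control_problem(s, 1:4, 1:4, T = 0), "T must be positive")
  expect_error(control_problem(s, 1:4, 1:4, rho = -1), "rho")
  expect_error(control_problem(s, 1:4, 1:4, b_diag = rep(0, 4)), "positive")
  expect_error(control_operators(s, n_steps = 50), "at least 100")
})
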