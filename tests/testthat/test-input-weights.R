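test_that("input-weighting constructors follow their scaling contracts", {
  u <- uniform_inputs(3)
  expect_equal(u$b_diag, c(1, 1, 1))
  expect_equal(u$scheme, "uniform")

  d <- disease_inputs(c(0.87, -0.59, 0))
  expect_equal(d$b_diag, c(1.87, 0.41, 1))
  expect_error(disease_inputs(c(0.2, -1)), "non-positive")
  expect_equal(disease_inputs(rep(0, 5))$b_diag, rep(1, 5))
  set.seed(1)
  dd <- runif(30, -0.6, 0.9)
  expect_true(all(disease_inputs(dd)$b_diag > 0.4 &
                    disease_inputs(dd)$b_diag < 1.9))

  r <- receptor_inputs(c(0, 5, 10))
  expect_equal(r$b_diag, c(1, 1.5, 2))
  expect_equal(receptor_inputs(3 * c(0, 5, 10) + 7)$b_diag, r$b_diag)
  expect_error(receptor_inputs(rep(1, 4)), "constant")

  # order preservation
  v <- rnorm(10)
  expect_equal(order(receptor_inputs(v)$b_diag), order(v))
  expect_equal(order(disease_inputs(v / 3)$b_diag), order(v))
})

test_that("uniform weighting reproduces the plain solver", {
  g <- rand_graph(5, seed = 22)
  set.seed(22)
  states <- matrix(rnorm(15), 5, 3)
  t1 <- transition_energy_matrix(g, states, n_steps = 150)
  t2 <- transition_energy_matrix(g, states, n_steps = 150,
                                 b_diag = uniform_inputs(5)$b_diag)
  expect_equal(t1$energies, t2$energies)
})

test_that("an identity-rotation surrogate ensemble shows zero facilitation", {
  g <- synth_connectome(n_nodes = 16, target_density = 0.4, seed = 23)
  states <- synth_state_maps(g, k_maps = 3, seed = 23)
  rec <- synth_annotation_maps(g, "receptor", n_maps = 1, seed = 23)
  fac <- receptor_facilitation(g, states, rec, n_steps = 100,
                               rotations = list(diag(3)))
  expect_true(all(fac$percent == 0))   # empirical < empirical is never true
  expect_true(all(fac$per_transition[[1]] == 0))
})

test_that("facilitation percentages match a hand count on a toy case", {
  g <- synth_connectome(n_nodes = 12, target_density = 0.5, seed = 24)
  states <- synth_state_maps(g, k_maps = 2, seed = 24)
  rec <- synth_annotation_maps(g, "receptor", n_maps = 1, seed = 24)
  set.seed(99)
  rots <- replicate(3, nctr:::.random_rotation(), simplify = FALSE)
  fac <- receptor_facilitation(g, states, rec, n_steps = 100,
                               rotations = rots)
  # independent count: energy tables per weighting via the public API
  ens <- spin_surrogates(rec[, 1], g, rotations = rots)
  tem_for <- function(m) transition_energy_matrix(
    g, states, n_steps = 100, b_diag = receptor_inputs(m)$b_diag)$energies
  emp <- tem_for(rec[, 1])
  wins <- matrix(0, 2, 2)
  for (r in 1:3) wins <- wins + (emp < tem_for(ens$members[, r]))
  for (j in 1:2)
    expect_equal(unname(fac$percent[1, j]),
                 100 * sum(wins[-j, j]) / (1 * 3))
  expect_equal(unname(fac$per_transition[[1]]), unname(100 * wins / 3))
})

test_that("disease z-scores flag degenerate maps and detect real ones", {
  g <- synth_connectome(n_nodes = 16, target_density = 0.4, seed = 25)
  states <- synth_state_maps(g, k_maps = 3, seed = 25)
  zero_map <- matrix(0, 16, 1)
  expect_warning(
    z0 <- disease_target_zscores(g, states, zero_map, n_rot = 25,
                                 n_steps = 100, seed = 2),
    "degenerate")
  expect_true(all(is.na(z0$z)))

  dis <- synth_annotation_maps(g, "disease", n_maps = 1, seed = 25)
  z1 <- disease_target_zscores(g, states, dis, n_rot = 25, n_steps = 100,
                               seed = 2)
  expect_true(all(is.finite(z1$z)))
  expect_equal(dim(z1$z), c(1, 3))
})

test_that("hub-concentrated and diffuse maps produce different z patterns", {
  g <- synth_connectome(n_nodes = 20, target_density = 0.35, seed = 26)
  states <- synth_state_maps(g, k_maps = 3, seed = 26)
  hub <- synth_annotation_maps(g, "disease", n_maps = 1, seed = 26,
                               hub_concentrated = TRUE)
  diffuse <- synth_annotation_maps(g, "disease", n_maps = 1, seed = 27,
                                   smoothness = 0)
  zh <- disease_target_zscores(g, states, hub, n_rot = 25, n_steps = 100,
                               seed = 3)
  zd <- disease_target_zscores(g, states, diffuse, n_rot = 25,
                               n_steps = 100, seed = 3)
  expect_true(all(is.finite(zh$z)) && all(is.finite(zd$z)))
  expect_gt(max(abs(zh$z - zd$z)), 0.1)   # spatial layout matters
})
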