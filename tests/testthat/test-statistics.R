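test_that("partial Spearman reduces to plain Spearman without covariates", {
  set.seed(31)
  x <- rnorm(25); y <- x + rnorm(25)
  r <- partial_spearman(x, y)
  expect_equal(r$rho, cor(x, y, method = "spearman"))
  expect_equal(r$p, cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-10)
})

test_that("partialling y out of itself leaves nothing", {
  set.seed(32)
  x <- rnorm(30); y <- rnorm(30)
  expect_lt(abs(partial_spearman(x, y, covariates = y)$rho), 1e-10)
})

test_that("partial Spearman matches the two-step regression oracle", {
  set.seed(33)
  z <- rnorm(40)
  x <- z + rnorm(40); y <- -z + rnorm(40)
  r <- partial_spearman(x, y, covariates = z)
  rx <- residuals(lm(rank(x) ~ rank(z)))
  ry <- residuals(lm(rank(y) ~ rank(z)))
  expect_equal(r$rho, cor(rx, ry), tolerance = 1e-12)
  # symmetry and monotone-transform invariance
  expect_equal(partial_spearman(y, x, covariates = z)$rho, r$rho)
  expect_equal(partial_spearman(exp(x), y^3 + y, covariates = z)$rho, r$rho)
  expect_error(partial_spearman(rep(1, 20), rnorm(20)), "constant")
  expect_error(partial_spearman(x, y, covariates = cbind(z, z)),
               "rank deficient")
})

test_that("dominance analysis matches closed forms", {
  set.seed(34)
  x <- rnorm(50); y <- 2 * x + rnorm(50)
  d1 <- dominance_analysis(cbind(x = x), y)
  expect_equal(unname(d1$dominance["x"]), cor(x, y)^2, tolerance = 1e-12)

  # exactly orthogonal (and centered) standardized predictors
  x1 <- as.numeric(scale(rnorm(50)))
  x2 <- as.numeric(scale(residuals(lm(rnorm(50) ~ x1))))
  X <- cbind(x1, x2)
  y2 <- X %*% c(1, 0.5) + rnorm(50)
  d2 <- dominance_analysis(X, y2)
  r2 <- c(cor(X[, 1], y2)^2, cor(X[, 2], y2)^2)
  expect_equal(unname(d2$dominance), r2, tolerance = 1e-10)
  expect_equal(sum(d2$dominance), d2$r2_full, tolerance = 1e-10)
})

test_that("dominance matches the brute-force subset oracle for p = 3", {
  set.seed(35)
  n <- 40
  X <- matrix(rnorm(3 * n), n, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  X[, 2] <- X[, 1] + 0.6 * X[, 2]   # induce correlation
  y <- X %*% c(1, -0.5, 0.25) + rnorm(n)
  d <- dominance_analysis(X, y)
  # independent evaluation through lm() and explicit size-stratified loops
  r2 <- function(cols) if (length(cols) == 0) 0 else
    summary(lm(y ~ X[, cols, drop = FALSE]))$r.squared
  for (k in 1:3) {
    others <- setdiff(1:3, k)
    per_size <- sapply(0:2, function(s) {
      subs <- if (s == 0) list(integer(0)) else
        combn(others, s, simplify = FALSE)
      mean(sapply(subs, function(S) r2(c(S, k)) - r2(S)))
    })
    expect_equal(unname(d$dominance[k]), mean(per_size), tolerance = 1e-10)
  }
  expect_equal(sum(d$dominance), summary(lm(y ~ X))$r.squared,
               tolerance = 1e-10)
})

test_that("dominance sum identity holds across random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(30 * p), 30, p)
    y <- rnorm(30)
    d <- dominance_analysis(X, y)
    expect_equal(sum(d$dominance), d$r2_full, tolerance = 1e-10)
  }
  X <- matrix(rnorm(60), 30, 2)
  expect_error(dominance_analysis(cbind(X, X[, 1]), rnorm(30)), "collinear")
})

test_that("the predictor table wires graph, maps and energies together", {
  g <- synth_connectome(n_nodes = 20, target_density = 0.35, seed = 36)
  states <- synth_state_maps(g, k_maps = 6, seed = 36)
  np <- node_predictors(g, rep(1:2, 10))
  states[, 1] <- np$degree   # state = the degree vector itself
  tem <- transition_energy_matrix(g, states, n_steps = 100)
  tab <- build_predictor_table(states, g, tem, rep(1:2, 10))
  expect_equal(nrow(tab), 6)
  expect_equal(tab$cor_degree[1], 1, tolerance = 1e-6)
  expect_false(any(is.na(tab)))
  # network-variance column equals an independent recomputation
  res <- effective_resistance(g)
  for (j in 1:6)
    expect_equal(tab$network_variance[j],
                 network_variance(res, map_to_distribution(states[, j])))
  # response = mean energy to reach each target
  e <- tem$energies
  expect_equal(tab$mean_energy_to_reach,
               unname((colSums(e) - diag(e)) / 5))

  # degenerate (constant) response is flagged
  const_tem <- matrix(1, 6, 6)
  expect_warning(
    tab2 <- build_predictor_table(states, g, const_tem, rep(1:2, 10)),
    "constant response")
  expect_true(attr(tab2, "degenerate_response"))
})
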