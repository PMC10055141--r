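#' Define a finite-horizon optimal control problem
#'
#' Bundles the normalized dynamics with a source state `x0`, target state
#' `xT`, horizon `T`, input-energy weight `rho`, and diagonal control-input
#' gains `b_diag` (the diagonal of the input matrix B; all ones =
#' whole-brain uniform control).
#'
#' The optimal input minimizes
#' `J = integral_0^T [ (xT - x(t))'(xT - x(t)) + rho u(t)'u(t) ] dt`
#' subject to `dx/dt = A x + B u`, `x(0) = x0`, `x(T) = xT`.
#'
#' @param system A `"normalized_system"` from [normalize_adjacency].
#' @param x0,xT Numeric N-vectors: source and target activation states.
#' @param T Control horizon (> 0, default 1).
#' @param rho Input-energy weight (> 0, default 1, equal weighting of
#'   trajectory distance and input cost).
#' @param b_diag Nonnegative N-vector of input gains with at least one
#'   positive entry; scalar 1 expands to uniform gains.
#' @return Object of class `"control_problem"`.
#' @export
control_problem <- function(system, x0, xT, T = 1, rho = 1, b_diag = 1) {
  stopifnot(inherits(system, "normalized_system"))
  n <- nrow(system$a_norm)
  x0 <- as.numeric(x0); xT <- as.numeric(xT)
  if (length(x0) != n || length(xT) != n)
    stop("x0 and xT must match the system dimension")
  if (length(b_diag) == 1) b_diag <- rep(b_diag, n)
  if (length(b_diag) != n) stop("b_diag must have one gain per node")
  if (any(b_diag < 0) || all(b_diag == 0))
    stop("b_diag must be nonnegative with at least one positive entry")
  if (T <= 0) stop("T must be positive")
  if (rho <= 0) stop("rho must be positive")
  structure(list(system = system, x0 = x0, xT = xT, T = T, rho = rho,
                 b_diag = b_diag),
            class = "control_problem")
}

# State-costate generator of the Hamiltonian system, augmented with the
# (constant) target state so one matrix exponential serves every state pair:
#   d/dt [x; lambda; xT] = M [x; lambda; xT],
#   M = [[A, -BB'/(2 rho), 0], [-2I, -A', 2I], [0, 0, 0]].
# Stationarity of the Hamiltonian gives u*(t) = -B' lambda(t) / (2 rho).
.stm_generator <- function(a_norm, b_diag, rho) {
  n <- nrow(a_norm)
  Z <- matrix(0, n, n)
  I <- diag(n)
  rbind(
    cbind(a_norm, -diag(b_diag^2, n) / (2 * rho), Z),
    cbind(-2 * I, -t(a_norm), 2 * I),
    cbind(Z, Z, Z))
}

#' Precompute transition-energy operators for a system
#'
#' For a fixed (system, T, rho, b_diag) configuration, the optimal control
#' energy between any state pair is a quadratic form
#' `E(x0 -> xT) = [x0; xT]' W [x0; xT]`, where W is accumulated once by
#' trapezoidal quadrature of the state-costate block exponential over the
#' time grid. This is algebraically identical to integrating `u(t)'u(t)`
#' along each pair's optimal trajectory on the same grid, but costs O(N^2)
#' per pair instead of O(N^2 n_steps).
#'
#' @param system A `"normalized_system"`.
#' @param T,rho,b_diag As in [control_problem].
#' @param n_steps Number of quadrature intervals on `[0, T]` (>= 100).
#' @return Object of class `"control_operators"`: list with `W_pair`
#'   (2N x 2N positive semidefinite), boundary-solve maps `R1`, `R2`
#'   (`lambda(0) = R1 x0 + R2 xT`), the horizon-T block exponential `Phi`,
#'   the per-step exponential `E_step`, the boundary condition number
#'   `kappa_boundary`, and the configuration.
#' @export
control_operators <- function(system, T = 1, rho = 1, b_diag = 1,
                              n_steps = 1000) {
  stopifnot(inherits(system, "normalized_system"))
  n <- nrow(system$a_norm)
  if (length(b_diag) == 1) b_diag <- rep(b_diag, n)
  if (n_steps < 100) stop("n_steps must be at least 100")
  M <- .stm_generator(system$a_norm, b_diag, rho)
  dt <- T / n_steps
  E_step <- as.matrix(Matrix::expm(Matrix::Matrix(M * dt)))

  ix <- seq_len(n); il <- n + ix; it <- 2 * n + ix
  gain <- b_diag / (2 * rho)          # u = -(1/2rho) B lambda
  # accumulate W = sum_k w_k * (gain * E_k[lambda rows, ])' (...) over grid
  W <- matrix(0, 3 * n, 3 * n)
  E <- diag(3 * n)
  U0 <- gain * E[il, , drop = FALSE]
  W <- W + (dt / 2) * crossprod(U0)
  for (k in seq_len(n_steps)) {
    E <- E_step %*% E
    Uk <- gain * E[il, , drop = FALSE]
    w <- if (k == n_steps) dt / 2 else dt
    W <- W + w * crossprod(Uk)
  }
  Phi <- E
  # boundary solve: x(T) = Phi11 x0 + Phi12 lambda0 + Phi13 xT = xT
  Phi12 <- Phi[ix, il, drop = FALSE]
  kap <- kappa(Phi12)
  if (!is.finite(kap) || kap > 1e14)
    stop(sprintf("boundary-condition solve is singular (condition number %.3g): configuration is effectively uncontrollable", kap))
  if (kap > 1e10)
    warning(sprintf("boundary solve badly conditioned (kappa = %.3g)", kap))
  R1 <- -solve(Phi12, Phi[ix, ix, drop = FALSE])
  R2 <- solve(Phi12, diag(n) - Phi[ix, it, drop = FALSE])
  # energy quadratic form on [x0; xT]: z = L [x0; xT]
  L <- rbind(cbind(diag(n), matrix(0, n, n)),
             cbind(R1, R2),
             cbind(matrix(0, n, n), diag(n)))
  W_pair <- crossprod(L, W %*% L)
  W_pair <- (W_pair + t(W_pair)) / 2
  structure(list(W_pair = W_pair, R1 = R1, R2 = R2, Phi = Phi,
                 E_step = E_step, kappa_boundary = kap, n_nodes = n,
                 T = T, rho = rho, b_diag = b_diag, n_steps = n_steps,
                 system = system),
            class = "control_operators")
}

#' Solve the optimal control problem for one state pair
#'
#' Solves the two-point boundary-value problem of the Hamiltonian system:
#' stationarity gives `u*(t) = -B' lambda(t) / (2 rho)`; the joint
#' state-costate dynamics are linear and are evolved with the exact block
#' matrix exponential at the grid times (no ODE-stepper truncation error),
#' with `lambda(0)` obtained from the linear system enforcing `x(T) = xT`.
#'
#' @param problem A [control_problem].
#' @param n_steps Grid intervals on `[0, T]` (default 1000, >= 100) used
#'   for the trajectory and the trapezoidal energy quadrature.
#' @param reach_tol Relative terminal-accuracy tolerance (default 1e-6).
#' @param operators Optionally, precomputed [control_operators] matching
#'   the problem's configuration (avoids recomputing the exponential).
#' @return Object of class `"control_trajectory"`: `times`, `states`
#'   ((n_steps+1) x N), `inputs`, `costates`, `energy_per_node`
#'   (`integral u_k(t)^2 dt` by trapezoid), and `total_energy`.
#' @examples
#' g <- connectome(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
#' s <- normalize_adjacency(g)
#' p <- control_problem(s, x0 = c(1, 0, 0), xT = c(0, 0, 1))
#' tr <- solve_optimal_control(p, n_steps = 200)
#' tr$total_energy
#' @export
solve_optimal_control <- function(problem, n_steps = 1000, reach_tol = 1e-6,
                                  operators = NULL) {
  stopifnot(inherits(problem, "control_problem"))
  n <- length(problem$x0)
  if (is.null(operators)) {
    operators <- control_operators(problem$system, T = problem$T,
                                   rho = problem$rho,
                                   b_diag = problem$b_diag,
                                   n_steps = n_steps)
  } else {
    stopifnot(inherits(operators, "control_operators"))
    if (operators$n_steps != n_steps ||
        operators$T != problem$T || operators$rho != problem$rho ||
        !isTRUE(all.equal(operators$b_diag, problem$b_diag)))
      stop("operators were built for a different configuration")
  }
  lambda0 <- as.numeric(operators$R1 %*% problem$x0 +
                        operators$R2 %*% problem$xT)
  z <- c(problem$x0, lambda0, problem$xT)
  dt <- problem$T / n_steps
  ix <- seq_len(n); il <- n + ix
  states <- matrix(NA_real_, n_steps + 1, n)
  costates <- matrix(NA_real_, n_steps + 1, n)
  states[1, ] <- problem$x0
  costates[1, ] <- lambda0
  for (k in seq_len(n_steps)) {
    z <- as.numeric(operators$E_step %*% z)
    states[k + 1, ] <- z[ix]
    costates[k + 1, ] <- z[il]
  }
  gain <- problem$b_diag / (2 * problem$rho)
  inputs <- -sweep(costates, 2, gain, `*`)
  # terminal accuracy, relative to the target scale
  scale <- max(sqrt(sum(problem$xT^2)), sqrt(sum(problem$x0^2)), 1e-12)
  miss <- sqrt(sum((states[n_steps + 1, ] - problem$xT)^2)) / scale
  if (miss > reach_tol)
    stop(sprintf(
      "terminal state missed target (relative error %.3g > %.3g); boundary condition number %.3g - increase n_steps or inspect conditioning",
      miss, reach_tol, operators$kappa_boundary))
  trapw <- c(dt / 2, rep(dt, n_steps - 1), dt / 2)
  energy_per_node <- colSums(trapw * inputs^2)
  names(energy_per_node) <- problem$system$node_labels
  structure(list(times = seq(0, problem$T, length.out = n_steps + 1),
                 states = states, inputs = inputs, costates = costates,
                 energy_per_node = energy_per_node,
                 total_energy = sum(energy_per_node),
                 terminal_error = miss,
                 kappa_boundary = operators$kappa_boundary),
            class = "control_trajectory")
}

#' @export
print.control_trajectory <- function(x, ...) {
  cat(sprintf("<control_trajectory> %d grid points, total energy %.6g, terminal error %.2g\n",
              length(x$times), x$total_energy, x$terminal_error))
  invisible(x)
}

#' All-pairs transition energy matrix
#'
#' Optimal control energy for every ordered pair of states (rows = source,
#' columns = target; the diagonal of self-transitions is computed, not
#' skipped). Defaults reproduce the main-analysis configuration: `T = 1`,
#' `rho = 1`, `c = 0`, uniform whole-brain inputs; `T = 3` and
#' `c = "0.01lmax"` are supported replication settings.
#'
#' @param x A [connectome], a `"normalized_system"`, or precomputed
#'   [control_operators].
#' @param states Regions x terms numeric matrix (columns are states) whose
#'   rows follow the connectome's node order.
#' @param T,rho,b_diag,n_steps Passed to [control_operators] when `x` is
#'   not already one.
#' @param c Stabilization scalar for [normalize_adjacency] when `x` is a
#'   connectome.
#' @param normalize_states If `TRUE`, each state is first scaled to unit
#'   Euclidean norm (supplementary variant); default uses maps as-is.
#' @return Object of class `"transition_energy_matrix"`: list with
#'   `energies` (K x K, nonnegative), `term_labels`, and the parameter set.
#' @export
transition_energy_matrix <- function(x, states, T = 1, rho = 1, c = 0,
                                     b_diag = 1, n_steps = 1000,
                                     normalize_states = FALSE) {
  states <- as.matrix(states)
  if (inherits(x, "control_operators")) {
    ops <- x
  } else {
    system <- if (inherits(x, "connectome")) normalize_adjacency(x, c = c)
              else x
    stopifnot(inherits(system, "normalized_system"))
    ops <- control_operators(system, T = T, rho = rho, b_diag = b_diag,
                             n_steps = n_steps)
  }
  n <- ops$n_nodes
  if (nrow(states) != n)
    stop("states must have one row per connectome node")
  if (normalize_states) {
    nrm <- sqrt(colSums(states^2))
    if (any(nrm == 0)) stop("cannot normalize an all-zero state")
    states <- sweep(states, 2, nrm, `/`)
  }
  labels <- colnames(states)
  if (is.null(labels)) labels <- paste0("state", seq_len(ncol(states)))
  ix <- seq_len(n); jx <- n + ix
  W11 <- ops$W_pair[ix, ix]; W22 <- ops$W_pair[jx, jx]
  Wc <- ops$W_pair[ix, jx] + t(ops$W_pair[jx, ix])
  q_src <- colSums(states * (W11 %*% states))
  q_tgt <- colSums(states * (W22 %*% states))
  cross <- crossprod(states, Wc %*% states)
  energies <- outer(q_src, q_tgt, `+`) + cross
  energies[energies < 0] <- 0   # round-off guard; W_pair is PSD
  if (any(!is.finite(energies))) {
    bad <- which(!is.finite(energies), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite transition energy for pair (%s -> %s)",
                 labels[bad[1]], labels[bad[2]]))
  }
  dimnames(energies) <- list(source = labels, target = labels)
  structure(list(energies = energies, term_labels = labels,
                 T = ops$T, rho = ops$rho, c = ops$system$c,
                 b_diag = ops$b_diag, n_steps = ops$n_steps,
                 normalize_states = normalize_states),
            class = "transition_energy_matrix")
}

#' @export
print.transition_energy_matrix <- function(x, ...) {
  cat(sprintf("<transition_energy_matrix> %d states, energies in [%.4g, %.4g] (T=%g, rho=%g, c=%.4g)\n",
              length(x$term_labels), min(x$energies), max(x$energies),
              x$T, x$rho, x$c))
  invisible(x)
}
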