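# independent direct-transcription oracle for the optimal control energy:
# forward-Euler dynamics, rectangle-rule cost, terminal equality constraint,
# solved exactly as a sparse KKT system. Shares no code with the package's
# block-exponential TPBVP solver.
oracle_control_energy <- function(a_norm, b_diag, x0, xT, T = 1, rho = 1,
                                  K = 2000) {
  n <- nrow(a_norm)
  dt <- T / K
  nx <- n * (K + 1)
  nu <- n * K
  Hd <- c(rep(2 * dt, nx), rep(2 * dt * rho, nu))
  f <- c(rep(-2 * dt * xT, K + 1), rep(0, nu))
  Ad <- diag(n) + dt * a_norm
  ii <- jj <- vv <- vector("list", K + 2)
  dense_idx <- which(Ad != 0, arr.ind = TRUE)
  for (k in 0:(K - 1)) {
    r0 <- k * n
    ii[[k + 1]] <- c(r0 + 1:n, r0 + dense_idx[, 1], r0 + 1:n)
    jj[[k + 1]] <- c((k + 1) * n + 1:n, k * n + dense_idx[, 2],
                     nx + k * n + 1:n)
    vv[[k + 1]] <- c(rep(1, n), -Ad[dense_idx], -dt * b_diag)
  }
  nr <- n * K
  ii[[K + 1]] <- nr + 1:n; jj[[K + 1]] <- 1:n; vv[[K + 1]] <- rep(1, n)
  ii[[K + 2]] <- nr + n + 1:n; jj[[K + 2]] <- K * n + 1:n
  vv[[K + 2]] <- rep(1, n)
  Aeq <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                              dims = c(nr + 2 * n, nx + nu))
  beq <- c(rep(0, nr), x0, xT)
  KKT <- rbind(cbind(Matrix::Diagonal(x = Hd), Matrix::t(Aeq)),
               cbind(Aeq, Matrix::Matrix(0, nrow(Aeq), nrow(Aeq))))
  sol <- Matrix::solve(KKT, c(-f, beq))
  u <- matrix(sol[nx + 1:nu], nrow = K, byrow = TRUE)
  dt * sum(u^2)
}
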