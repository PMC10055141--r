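#' Normalize a connectome into stable linear dynamics
#'
#' Rescales and shifts the adjacency matrix so the linear system
#' `dx/dt = A_norm x + B u` does not blow up over the control horizon:
#' `A_norm = A / (lambda_max + c) - I`, where `lambda_max` is the largest
#' eigenvalue of `A`. With `c = 0` (the default) the largest mode of
#' `A_norm` is exactly 0, so the system drifts toward its dominant
#' eigenvector; with `c > 0` all modes decay.
#'
#' @param x A [connectome] or a symmetric nonnegative adjacency matrix.
#' @param c Nonnegative stabilization scalar. `c = 0` is the main-analysis
#'   setting; `c = 0.01 * lambda_max` is a supported replication setting
#'   (pass e.g. `c = "0.01lmax"` or a number).
#'
#' @return An object of class `"normalized_system"`: list with `a_norm`
#'   (N x N), `c`, `lambda_max`, and `node_labels`.
#' @examples
#' g <- connectome(rbind(c(0, 2), c(2, 0)))
#' s <- normalize_adjacency(g)      # a_norm = [[-1, 1], [1, -1]]
#' s$lambda_max
#' @export
normalize_adjacency <- function(x, c = 0) {
  a <- if (inherits(x, "connectome")) x$adjacency else as.matrix(x)
  labels <- if (inherits(x, "connectome")) x$node_labels else rownames(a)
  if (max(abs(a - t(a))) > 1e-12) stop("adjacency must be symmetric")
  lambda_max <- max(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  if (is.character(c)) {
    if (!identical(c, "0.01lmax")) stop('character c must be "0.01lmax"')
    c <- 0.01 * lambda_max
  }
  if (c < 0) stop("c must be nonnegative")
  if (lambda_max + c <= 0)
    stop("lambda_max + c must be positive: a zero adjacency with c = 0 cannot be normalized")
  a_norm <- a / (lambda_max + c) - diag(nrow(a))
  dimnames(a_norm) <- list(labels, labels)
  structure(list(a_norm = a_norm, c = c, lambda_max = lambda_max,
                 node_labels = labels),
            class = "normalized_system")
}

#' @export
print.normalized_system <- function(x, ...) {
  cat(sprintf("<normalized_system> %d nodes, lambda_max = %.4g, c = %.4g\n",
              nrow(x$a_norm), x$lambda_max, x$c))
  invisible(x)
}
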