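#' Effective resistance between all node pairs
#'
#' Treats the weighted graph as an electrical network (edge weight =
#' conductance) and returns the resistance distance
#' `omega[i, j] = (e_i - e_j)' Q (e_i - e_j)`, where `Q` is the
#' Moore-Penrose pseudoinverse of the graph Laplacian
#' `L = diag(strength) - A`. Effective resistance is small when many short
#' paths join two nodes and is proportional to random-walk commute time.
#'
#' @param x A [connectome] or symmetric adjacency matrix (connected).
#' @return Object of class `"resistance_matrix"`: list with `omega` (N x N,
#'   symmetric, zero diagonal) and `laplacian_pinv`.
#' @details The pseudoinverse is computed by eigendecomposition of `L`;
#'   eigenvalues below `1e-10 * max(eigenvalue)` are treated as the null
#'   space, which keeps the computation robust for nearly disconnected
#'   graphs. A connected graph has exactly one such eigenvalue.
#' @examples
#' tri <- connectome(matrix(1, 3, 3) - diag(3))
#' effective_resistance(tri)$omega   # 2/3 off-diagonal
#' @export
effective_resistance <- function(x) {
  a <- if (inherits(x, "connectome")) x$adjacency else as.matrix(x)
  comp <- .components(a)
  if (max(comp) > 1L)
    stop(sprintf("graph is disconnected (%d components: %s)", max(comp),
                 paste(tapply(seq_along(comp), comp, function(i)
                   paste0("{", paste(i, collapse = ","), "}")), collapse = " ")))
  L <- diag(rowSums(a)) - a
  ev <- eigen(L, symmetric = TRUE)
  vals <- ev$values
  keep <- vals > 1e-10 * max(vals)
  Q <- ev$vectors[, keep, drop = FALSE] %*%
    (t(ev$vectors[, keep, drop = FALSE]) / vals[keep])
  dq <- diag(Q)
  omega <- outer(dq, dq, "+") - 2 * Q
  omega <- (omega + t(omega)) / 2
  diag(omega) <- 0
  dimnames(omega) <- dimnames(Q) <- dimnames(a)
  structure(list(omega = omega, laplacian_pinv = Q),
            class = "resistance_matrix")
}

#' @export
print.resistance_matrix <- function(x, ...) {
  cat(sprintf("<resistance_matrix> %d nodes, max omega = %.4g\n",
              nrow(x$omega), max(x$omega)))
  invisible(x)
}

#' Random-walk commute times
#'
#' Mean round-trip time of an unbiased random walker between node pairs:
#' `commute[i, j] = vol(G) * omega[i, j]`, with `vol(G)` the total node
#' strength. Provided as a cross-check on the resistance computation.
#'
#' @inheritParams effective_resistance
#' @return N x N matrix of commute times.
#' @export
commute_time <- function(x) {
  a <- if (inherits(x, "connectome")) x$adjacency else as.matrix(x)
  sum(rowSums(a)) * effective_resistance(x)$omega
}

#' Rescale an activation map into a node distribution
#'
#' Shifts a regional map so its minimum is 0, then divides by the sum, so
#' it can serve as a probability mass function over nodes (the input to
#' [network_variance]).
#'
#' @param map Numeric vector of regional values (not constant).
#' @return Nonnegative vector summing to 1.
#' @export
map_to_distribution <- function(map) {
  v <- as.numeric(map) - min(map)
  s <- sum(v)
  if (s <= 0) stop("map is constant: cannot be rescaled to a distribution")
  p <- v / s
  names(p) <- names(map)
  p
}

#' Network variance of a distribution on a graph
#'
#' Generalizes variance to a distribution over graph nodes:
#' `var(p) = 1/2 * sum_ij p(i) p(j) * omega[i, j]`, with effective
#' resistance `omega` playing the role of squared distance. High network
#' variance means the mass sits on nodes that are hard to reach from one
#' another by diffusion.
#'
#' @param resistance A `"resistance_matrix"` (or plain omega matrix).
#' @param p A node distribution (nonnegative, sums to 1), e.g. from
#'   [map_to_distribution].
#' @return Scalar network variance.
#' @details Using `omega` itself as the squared distance (rather than
#'   `omega^2`) follows the recommendation of the measure's originators,
#'   for whom resistance distance is the natural metric; this convention is
#'   fixed here and documented rather than configurable.
#' @export
network_variance <- function(resistance, p) {
  omega <- if (inherits(resistance, "resistance_matrix")) resistance$omega
           else as.matrix(resistance)
  p <- as.numeric(p)
  if (length(p) != nrow(omega)) stop("p and omega dimensions disagree")
  if (any(p < -1e-12) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a distribution (nonnegative, summing to 1)")
  0.5 * as.numeric(p %*% omega %*% p)
}
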