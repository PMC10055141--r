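#' Synthetic geometric connectome
#'
#' Generates a connectome with the geometric signature the analysis
#' assumes: nodes on two lateralized spherical caps (providing Euclidean
#' coordinates in mm, unit-sphere coordinates, and hemisphere labels),
#' edges drawn preferentially between nearby nodes, weights decaying
#' exponentially with distance (so weight and length are anticorrelated),
#' and connectivity guaranteed by always including a minimum spanning tree
#' of the distance graph.
#'
#' @param n_nodes Number of regions (default 68, a whole-cortex
#'   parcellation scale).
#' @param target_density Edge density (default 0.27, the consensus
#'   connectome scale); realized density matches to rounding.
#' @param decay_length Distance decay constant in mm for both connection
#'   probability and weight (default 35).
#' @param radius Cortical sphere radius in mm (default 70).
#' @param seed Integer seed.
#' @return A [connectome] with all geometry fields populated.
#' @export
synth_connectome <- function(n_nodes = 68, target_density = 0.27,
                             decay_length = 35, radius = 70, seed = 1) {
  if (n_nodes < 4) stop("need at least 4 nodes")
  if (target_density <= 0 || target_density > 1)
    stop("target_density must be in (0, 1]")
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  m <- round(target_density * n_pairs)
  if (m < n_nodes - 1)
    stop(sprintf("density %.3f infeasible at %d nodes: %d edges cannot keep the graph connected",
                 target_density, n_nodes, m))
  set.seed(seed)
  n_left <- ceiling(n_nodes / 2)
  hemi <- rep(c("left", "right"), c(n_left, n_nodes - n_left))
  # uniform samples on a cap of half-angle 80 deg around -x (left) / +x (right)
  cap <- function(k, axis_sign) {
    cth <- stats::runif(k, cos(80 * pi / 180), 1)
    sth <- sqrt(1 - cth^2)
    phi <- stats::runif(k, 0, 2 * pi)
    cbind(axis_sign * cth, sth * cos(phi), sth * sin(phi))
  }
  sph <- rbind(cap(n_left, -1), cap(n_nodes - n_left, +1))
  eu <- radius * sph
  labels <- paste0(ifelse(hemi == "left", "L", "R"),
                   sprintf("%02d", stats::ave(seq_len(n_nodes), hemi,
                                              FUN = seq_along)))
  D <- as.matrix(stats::dist(eu))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  d_pair <- D[pairs]
  # spanning tree of the distance graph keeps the result connected
  gfull <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                               weighted = TRUE)
  mst <- igraph::as_edgelist(igraph::mst(gfull), names = FALSE)
  mst_id <- (pmin(mst[, 1], mst[, 2]) - 1) * n_nodes +
    pmax(mst[, 1], mst[, 2])
  pair_id <- (pairs[, 1] - 1) * n_nodes + pairs[, 2]
  in_mst <- pair_id %in% mst_id
  remaining <- which(!in_mst)
  extra <- sample(remaining, m - sum(in_mst),
                  prob = exp(-d_pair[remaining] / decay_length))
  chosen <- c(which(in_mst), extra)
  w <- exp(-d_pair[chosen] / decay_length) *
    stats::rlnorm(length(chosen), 0, 0.3)
  a <- matrix(0, n_nodes, n_nodes)
  a[pairs[chosen, , drop = FALSE]] <- w
  a <- a + t(a)
  connectome(a, labels, coords_euclidean = eu, coords_spherical = sph,
             hemisphere = hemi)
}

# graph heat-kernel smoothing: exp(-s * L / mean strength) applied to v
.graph_smooth <- function(x, v, smoothness) {
  if (smoothness == 0) return(v)
  a <- x$adjacency
  L <- diag(rowSums(a)) - a
  L <- L / mean(rowSums(a))
  ev <- eigen(L, symmetric = TRUE)
  ev$vectors %*% (exp(-smoothness * ev$values) * crossprod(ev$vectors, v))
}

#' Synthetic activation-state maps
#'
#' White noise per node, diffused over the connectome with a graph heat
#' kernel (smoothing parameter = spatial autocorrelation length; 0 gives
#' i.i.d. maps), then affinely rescaled to a per-map (mean, SD) drawn from
#' the given ranges. Heterogeneous means/SDs across maps emulate the
#' spread of meta-analytic activation maps.
#'
#' @param x A [connectome].
#' @param k_maps Number of maps.
#' @param smoothness Heat-kernel diffusion time (>= 0, default 2).
#' @param mean_range,sd_range Ranges the per-map mean and SD are drawn
#'   from (defaults `c(0, 2)` and `c(0.5, 1.5)`).
#' @param seed Integer seed.
#' @return Regions x k_maps matrix with term labels `"term01"...`.
#' @export
synth_state_maps <- function(x, k_maps = 20, smoothness = 2,
                             mean_range = c(0, 2), sd_range = c(0.5, 1.5),
                             seed = 1) {
  stopifnot(inherits(x, "connectome"), smoothness >= 0)
  set.seed(seed)
  n <- x$n_nodes
  raw <- .graph_smooth(x, matrix(stats::rnorm(n * k_maps), n, k_maps),
                       smoothness)
  mu <- stats::runif(k_maps, mean_range[1], mean_range[2])
  sg <- stats::runif(k_maps, sd_range[1], sd_range[2])
  out <- vapply(seq_len(k_maps), function(j) {
    v <- raw[, j]
    mu[j] + sg[j] * (v - mean(v)) / stats::sd(v)
  }, numeric(n))
  dimnames(out) <- list(x$node_labels,
                        sprintf("term%02d", seq_len(k_maps)))
  out
}

#' Synthetic annotation maps (receptor- or disease-like)
#'
#' Smooth maps shaped like the two annotation families the input-weighting
#' analysis consumes: `"receptor"` maps are nonnegative (tracer-density
#' like); `"disease"` maps are Cohen's d cortical-abnormality like, mildly
#' atrophy-dominant and clipped to (-0.6, 0.9) so the `1 + d` gains stay
#' positive.
#'
#' @param x A [connectome].
#' @param kind `"receptor"` or `"disease"`.
#' @param n_maps Number of maps (default 3).
#' @param smoothness Heat-kernel diffusion time (default 2).
#' @param hub_concentrated If `TRUE`, the first map tracks node strength
#'   (its top decile sits on the top-strength decile), for spatial
#'   specificity checks.
#' @param seed Integer seed.
#' @return Regions x n_maps matrix.
#' @export
synth_annotation_maps <- function(x, kind = c("receptor", "disease"),
                                  n_maps = 3, smoothness = 2,
                                  hub_concentrated = FALSE, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(inherits(x, "connectome"))
  set.seed(seed)
  n <- x$n_nodes
  raw <- .graph_smooth(x, matrix(stats::rnorm(n * n_maps), n, n_maps),
                       smoothness)
  raw <- apply(raw, 2, function(v) (v - mean(v)) / stats::sd(v))
  if (hub_concentrated) {
    s <- rowSums(x$adjacency)
    raw[, 1] <- (s - mean(s)) / stats::sd(s) + stats::rnorm(n, 0, 0.01)
  }
  out <- if (kind == "receptor") {
    apply(raw, 2, function(v) (v - min(v)) * stats::runif(1, 1, 10))
  } else {
    pmin(pmax(raw * 0.25 - 0.05, -0.6), 0.9)
  }
  dimnames(out) <- list(x$node_labels,
                        sprintf("%s%02d", substr(kind, 1, 3),
                                seq_len(ncol(out))))
  out
}

#' Small closed-form fixture graphs
#'
#' Unit-weight graphs with known effective resistances, used throughout
#' the test suite: the triangle, the 4-node path, ring, and star, and the
#' complete graph K4. All carry planar coordinates.
#'
#' @return Named list of [connectome] objects: `triangle`, `path4`,
#'   `ring4`, `star4`, `k4`.
#' @export
fixture_graphs <- function() {
  ring_coords <- function(n, r = 10)
    cbind(r * cos(2 * pi * seq_len(n) / n), r * sin(2 * pi * seq_len(n) / n), 0)
  from_edges <- function(n, edges, coords) {
    a <- matrix(0, n, n)
    for (e in edges) a[e[1], e[2]] <- a[e[2], e[1]] <- 1
    connectome(a, coords_euclidean = coords)
  }
  list(
    triangle = from_edges(3, list(c(1, 2), c(2, 3), c(1, 3)), ring_coords(3)),
    path4 = from_edges(4, list(c(1, 2), c(2, 3), c(3, 4)),
                       cbind(10 * (1:4), 0, 0)),
    ring4 = from_edges(4, list(c(1, 2), c(2, 3), c(3, 4), c(1, 4)),
                       ring_coords(4)),
    star4 = from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)),
                       rbind(c(0, 0, 0), ring_coords(3))),
    k4 = from_edges(4, list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                            c(3, 4)), ring_coords(4)))
}
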