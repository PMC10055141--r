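#' Weighted structural connectome
#'
#' Container for a weighted, undirected, connected brain network: the
#' adjacency matrix that plays the role of the state-interaction matrix of
#' the linear dynamics, plus optional node geometry used by the spatial
#' null models.
#'
#' @param adjacency Symmetric N x N numeric matrix of nonnegative weights
#'   (e.g. streamline densities) with zero diagonal.
#' @param node_labels Character vector of N region names. Defaults to the
#'   dimnames of `adjacency`, or `"n1".."nN"`.
#' @param coords_euclidean Optional N x 3 matrix of region centroids (mm).
#' @param coords_spherical Optional N x 3 matrix of unit vectors placing each
#'   region on the sphere (used by spin surrogates).
#' @param hemisphere Optional character vector of N labels in
#'   `c("left", "right")`.
#'
#' @return An object of class `"connectome"`: a list with fields
#'   `adjacency`, `node_labels`, `coords_euclidean`, `coords_spherical`,
#'   `hemisphere`, and `n_nodes`.
#'
#' @details Construction validates symmetry (within 1e-12), nonnegativity,
#'   zero diagonal, and connectedness (binary reachability over nonzero
#'   weights); resistance-based quantities require a connected graph, so a
#'   disconnected input is rejected with the component memberships named.
#'
#' @examples
#' g <- connectome(rbind(c(0, 1, 1), c(1, 0, 1), c(1, 1, 0)))
#' g$n_nodes
#' @export
connectome <- function(adjacency, node_labels = NULL, coords_euclidean = NULL,
                       coords_spherical = NULL, hemisphere = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stop("adjacency must be square")
  if (n < 2) stop("connectome needs at least 2 nodes")
  if (any(!is.finite(adjacency))) stop("adjacency contains non-finite values")
  if (max(abs(adjacency - t(adjacency))) > 1e-12)
    stop("adjacency is not symmetric (tolerance 1e-12)")
  adjacency <- (adjacency + t(adjacency)) / 2
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal")
  if (any(adjacency < 0)) stop("adjacency weights must be nonnegative")

  if (is.null(node_labels)) {
    node_labels <- rownames(adjacency)
    if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  }
  if (length(node_labels) != n) stop("node_labels length must match adjacency")
  dimnames(adjacency) <- list(node_labels, node_labels)

  comp <- .components(adjacency)
  if (max(comp) > 1L) {
    sizes <- table(comp)
    stop(sprintf(
      "graph is disconnected: %d components (sizes %s); component of node 1 contains {%s}",
      max(comp), paste(sizes, collapse = ", "),
      paste(node_labels[comp == comp[1]], collapse = ", ")))
  }

  if (!is.null(coords_euclidean)) {
    coords_euclidean <- as.matrix(coords_euclidean)
    stopifnot(nrow(coords_euclidean) == n, ncol(coords_euclidean) == 3)
    dimnames(coords_euclidean) <- list(node_labels, c("x", "y", "z"))
  }
  if (!is.null(coords_spherical)) {
    coords_spherical <- as.matrix(coords_spherical)
    stopifnot(nrow(coords_spherical) == n, ncol(coords_spherical) == 3)
    nrm <- sqrt(rowSums(coords_spherical^2))
    if (any(abs(nrm - 1) > 1e-6))
      stop("coords_spherical rows must be unit vectors")
    dimnames(coords_spherical) <- list(node_labels, c("sx", "sy", "sz"))
  }
  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    stopifnot(length(hemisphere) == n)
    if (!all(hemisphere %in% c("left", "right")))
      stop('hemisphere labels must be "left" or "right"')
  }

  structure(
    list(adjacency = adjacency, node_labels = node_labels,
         coords_euclidean = coords_euclidean,
         coords_spherical = coords_spherical,
         hemisphere = hemisphere, n_nodes = n),
    class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  m <- sum(x$adjacency > 0) / 2
  dens <- m / (x$n_nodes * (x$n_nodes - 1) / 2)
  cat(sprintf("<connectome> %d nodes, %d edges (density %.3f)%s%s\n",
              x$n_nodes, m, dens,
              if (!is.null(x$coords_euclidean)) ", coords" else "",
              if (!is.null(x$coords_spherical)) ", sphere+hemi" else ""))
  invisible(x)
}

# connected-component labels via binary reachability on nonzero weights
.components <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency > 0, mode = "undirected")
  igraph::components(g)$membership
}

#' Edge list of a connectome
#'
#' @param x A `connectome`.
#' @return Data frame with columns `i`, `j` (i < j, integer node indices),
#'   `weight`, and, when Euclidean coordinates are present, `length` (mm).
#' @export
connectome_edges <- function(x) {
  stopifnot(inherits(x, "connectome"))
  idx <- which(upper.tri(x$adjacency) & x$adjacency > 0, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    weight = x$adjacency[idx])
  if (!is.null(x$coords_euclidean)) {
    d <- x$coords_euclidean[out$i, , drop = FALSE] -
      x$coords_euclidean[out$j, , drop = FALSE]
    out$length <- sqrt(rowSums(d^2))
  }
  out
}

#' Read a connectome from a labeled square-matrix CSV/TSV
#'
#' Expects a header row and first column holding node labels; the matrix is
#' checked for symmetry on read. An optional coordinates table supplies node
#' geometry: columns `label`, `x`, `y`, `z` and optionally `sx`, `sy`, `sz`,
#' `hemisphere`.
#'
#' @param file Path to the adjacency table (`.csv` or `.tsv` by extension).
#' @param coords_file Optional path to the coordinates table.
#' @return A [connectome].
#' @export
read_connectome <- function(file, coords_file = NULL) {
  a <- .read_labeled_matrix(file)
  ce <- cs <- hemi <- NULL
  if (!is.null(coords_file)) {
    co <- utils::read.csv(coords_file, stringsAsFactors = FALSE,
                          sep = .sep_for(coords_file))
    if (!all(c("label", "x", "y", "z") %in% names(co)))
      stop("coords file needs columns label, x, y, z")
    co <- co[match(rownames(a), co$label), ]
    if (any(is.na(co$label)))
      stop("coords file is missing labels present in the adjacency table")
    ce <- as.matrix(co[, c("x", "y", "z")])
    if (all(c("sx", "sy", "sz") %in% names(co)))
      cs <- as.matrix(co[, c("sx", "sy", "sz")])
    if ("hemisphere" %in% names(co)) hemi <- co$hemisphere
  }
  connectome(a, rownames(a), coords_euclidean = ce,
             coords_spherical = cs, hemisphere = hemi)
}

#' Write a connectome (and its coordinates) to CSV
#'
#' @param x A `connectome`.
#' @param file Output path for the labeled adjacency matrix.
#' @param coords_file Optional output path for the coordinates table.
#' @return `x`, invisibly.
#' @export
write_connectome <- function(x, file, coords_file = NULL) {
  stopifnot(inherits(x, "connectome"))
  .write_labeled_matrix(x$adjacency, file)
  if (!is.null(coords_file)) {
    if (is.null(x$coords_euclidean))
      stop("connectome carries no Euclidean coordinates")
    co <- data.frame(label = x$node_labels, x$coords_euclidean)
    names(co) <- c("label", "x", "y", "z")
    if (!is.null(x$coords_spherical)) {
      co$sx <- x$coords_spherical[, 1]
      co$sy <- x$coords_spherical[, 2]
      co$sz <- x$coords_spherical[, 3]
    }
    if (!is.null(x$hemisphere)) co$hemisphere <- x$hemisphere
    utils::write.csv(co, coords_file, row.names = FALSE)
  }
  invisible(x)
}

.sep_for <- function(file) if (grepl("\\.tsv$", file)) "\t" else ","

.read_labeled_matrix <- function(file) {
  d <- utils::read.csv(file, row.names = 1, check.names = FALSE,
                       sep = .sep_for(file))
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("matrix table is not square")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels disagree")
  m
}

.write_labeled_matrix <- function(m, file) {
  d <- data.frame(m, check.names = FALSE)
  utils::write.csv(cbind(label = rownames(m), d), file, row.names = FALSE)
  invisible(file)
}

#' Read / write a state set (regions x terms table)
#'
#' State sets are stored with node labels as the first column and term names
#' as the header, matching the annotation-map layout.
#'
#' @param file Path to a CSV/TSV table.
#' @param node_labels Optional labels to reorder/validate rows against.
#' @return Numeric matrix, regions x terms, with dimnames.
#' @export
read_state_set <- function(file, node_labels = NULL) {
  d <- utils::read.csv(file, row.names = 1, check.names = FALSE,
                       sep = .sep_for(file))
  m <- as.matrix(d)
  if (!is.null(node_labels)) {
    if (!all(node_labels %in% rownames(m)))
      stop("state set is missing some connectome node labels")
    m <- m[node_labels, , drop = FALSE]
  }
  m
}

#' @rdname read_state_set
#' @param states Regions x terms numeric matrix.
#' @export
write_state_set <- function(states, file) {
  d <- data.frame(states, check.names = FALSE)
  utils::write.csv(cbind(label = rownames(states), d), file, row.names = FALSE)
  invisible(file)
}
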