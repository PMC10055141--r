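#' Nodal graph-theoretic predictors
#'
#' Per-region quantities used to characterise activation maps against the
#' connectome: binary degree, strength (weighted degree), and the weighted
#' participation coefficient `P_i = 1 - sum_m (kappa_im / kappa_i)^2`,
#' where `kappa_im` is node i's strength into module m. Optional per-node
#' annotation vectors (e.g. a cortical-hierarchy gradient) are passed
#' through unchanged.
#'
#' @param x A [connectome].
#' @param module_assignment Vector (length N) assigning every node to a
#'   module; any type coercible to factor.
#' @param annotations Optional named list / data frame of extra per-node
#'   numeric vectors.
#' @return Data frame with one row per node: `label`, `degree`, `strength`,
#'   `participation`, plus one column per annotation. Isolated nodes
#'   (strength 0) get participation 0 and are flagged in the
#'   `isolated` column.
#' @examples
#' k4 <- connectome(matrix(1, 4, 4) - diag(4))
#' node_predictors(k4, c(1, 1, 2, 2))$participation   # all 4/9
#' @export
node_predictors <- function(x, module_assignment, annotations = NULL) {
  stopifnot(inherits(x, "connectome"))
  a <- x$adjacency
  n <- x$n_nodes
  if (length(module_assignment) != n)
    stop("module_assignment must cover every node")
  mods <- as.factor(module_assignment)
  strength <- rowSums(a)
  degree <- rowSums(a > 0)
  # strength into each module, rows = nodes
  kim <- sapply(levels(mods), function(m)
    rowSums(a[, mods == m, drop = FALSE]))
  kim <- matrix(kim, nrow = n)
  part <- ifelse(strength > 0,
                 1 - rowSums((kim / pmax(strength, .Machine$double.eps))^2),
                 0)
  out <- data.frame(label = x$node_labels, degree = degree,
                    strength = strength, participation = part,
                    isolated = strength == 0,
                    row.names = NULL)
  if (any(out$isolated))
    warning(sprintf("%d isolated node(s): participation set to 0",
                    sum(out$isolated)))
  if (!is.null(annotations)) {
    annotations <- as.data.frame(annotations)
    if (nrow(annotations) != n) stop("annotations must have one row per node")
    out <- cbind(out, annotations)
  }
  out
}
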