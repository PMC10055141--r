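#' Transition asymmetry and per-target net scores
#'
#' `asym[i, j] = E(i -> j) - E(j -> i)` (antisymmetric); the net score of a
#' target `j` averages `asym[i, j]` over sources `i != j`. Positive net =
#' the state is harder to reach than to leave; negative = easier to reach
#' than to leave.
#'
#' @param tem A `"transition_energy_matrix"` or plain square matrix.
#' @return List with `asymmetry` (K x K antisymmetric matrix) and `net`
#'   (named K-vector of per-target net scores).
#' @export
transition_asymmetry <- function(tem) {
  e <- .tem_matrix(tem)
  asym <- e - t(e)
  k <- nrow(e)
  net <- (colSums(asym)) / (k - 1)   # diagonal of asym is 0
  names(net) <- colnames(e)
  list(asymmetry = asym, net = net)
}

#' Source versus target variability of transition energies
#'
#' Compares how much transition energy varies when the target changes
#' (row-wise SDs: for each source, SD across its K-1 off-diagonal target
#' entries) against how much it varies when the source changes
#' (column-wise SDs: for each target, SD across sources). A positive t
#' statistic means the identity of the target state drives transition-cost
#' variability more than the identity of the source.
#'
#' @param tem A `"transition_energy_matrix"` or square matrix with K >= 3.
#' @return List with `sd_across_targets` (one per source state),
#'   `sd_across_sources` (one per target state), the pooled two-sample
#'   `t` statistic with `df = 2K - 2`, its p-value, `cohens_d`, and a
#'   `degenerate` flag (TRUE when both SD samples are all zero, leaving t
#'   undefined).
#' @export
source_target_variability <- function(tem) {
  e <- .tem_matrix(tem)
  k <- nrow(e)
  if (k < 3) stop("need at least 3 states")
  off <- function(v, idx) v[-idx]
  sd_across_targets <- vapply(seq_len(k), function(i) stats::sd(off(e[i, ], i)),
                              numeric(1))
  sd_across_sources <- vapply(seq_len(k), function(j) stats::sd(off(e[, j], j)),
                              numeric(1))
  names(sd_across_targets) <- rownames(e)
  names(sd_across_sources) <- colnames(e)
  s1 <- sd_across_targets; s2 <- sd_across_sources
  pooled <- sqrt(((k - 1) * stats::var(s1) + (k - 1) * stats::var(s2)) /
                   (2 * k - 2))
  if (pooled == 0) {
    return(list(sd_across_targets = s1, sd_across_sources = s2,
                t = NA_real_, df = 2 * k - 2, p = NA_real_,
                cohens_d = NA_real_, degenerate = TRUE))
  }
  t_stat <- (mean(s1) - mean(s2)) / (pooled * sqrt(2 / k))
  list(sd_across_targets = s1, sd_across_sources = s2,
       t = t_stat, df = 2 * k - 2,
       p = 2 * stats::pt(-abs(t_stat), df = 2 * k - 2),
       cohens_d = (mean(s1) - mean(s2)) / pooled,
       degenerate = FALSE)
}

#' Fraction of transitions with a cheaper two-step route
#'
#' For each ordered pair `(i, j)`, checks whether routing through some
#' intermediate state `k` is cheaper than the direct transition:
#' `min_k [E(i -> k) + E(k -> j)] < E(i -> j)`.
#'
#' @param tem A `"transition_energy_matrix"` or nonnegative square matrix.
#' @return List with `fraction` (share of ordered pairs with a cheaper
#'   indirect route) and `pairs`: a data frame of all ordered pairs with
#'   the direct cost, the best two-step cost, the best intermediate, and an
#'   `indirect_cheaper` flag.
#' @export
indirect_transition_fraction <- function(tem) {
  e <- .tem_matrix(tem)
  k <- nrow(e)
  labels <- rownames(e)
  rows <- vector("list", k * (k - 1))
  r <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    mids <- setdiff(seq_len(k), c(i, j))
    two_step <- e[i, mids] + e[mids, j]
    best <- which.min(two_step)
    r <- r + 1L
    rows[[r]] <- data.frame(
      source = labels[i], target = labels[j],
      direct = e[i, j], best_two_step = two_step[best],
      via = labels[mids[best]],
      indirect_cheaper = two_step[best] < e[i, j])
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(fraction = mean(pairs$indirect_cheaper), pairs = pairs)
}

#' Euclidean distances between state vectors
#'
#' @param states Regions x terms matrix (columns are states).
#' @return Symmetric K x K matrix of L2 distances, zero diagonal; a
#'   standard predictor of transition energy.
#' @export
euclidean_state_distance <- function(states) {
  states <- as.matrix(states)
  d <- as.matrix(stats::dist(t(states)))
  dimnames(d) <- list(colnames(states), colnames(states))
  d
}

.tem_matrix <- function(tem) {
  e <- if (inherits(tem, "transition_energy_matrix")) tem$energies
       else as.matrix(tem)
  if (nrow(e) != ncol(e)) stop("transition energy matrix must be square")
  if (is.null(rownames(e)))
    dimnames(e) <- list(paste0("state", seq_len(nrow(e))),
                        paste0("state", seq_len(nrow(e))))
  e
}
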