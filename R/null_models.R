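#' Degree-preserving (Maslov-Sneppen) rewired surrogate
#'
#' Randomizes topology by repeated double-edge swaps: edges (a,b) and (c,d)
#' become (a,d) and (c,b) when no self-loop or multi-edge would result.
#' Each node's binary degree is preserved exactly, and weights travel with
#' their edges, so the weight multiset is preserved exactly as well.
#'
#' @param x A [connectome].
#' @param n_swap_per_edge Target number of accepted swaps per edge
#'   (default 10).
#' @param seed Integer seed for reproducibility.
#' @return A rewired [connectome] (geometry fields carried over unchanged);
#'   the number of accepted swaps is attached as attribute `"n_accepted"`.
#'   Graphs admitting no valid swap (stars, complete graphs) are returned
#'   unchanged with a warning.
#' @export
maslov_sneppen_rewire <- function(x, n_swap_per_edge = 10, seed = NULL) {
  stopifnot(inherits(x, "connectome"))
  if (!is.null(seed)) set.seed(seed)
  a <- x$adjacency
  ed <- connectome_edges(x)
  m <- nrow(ed)
  if (m < 2) {
    warning("fewer than 2 edges: nothing to rewire")
    return(x)
  }
  target <- n_swap_per_edge * m
  max_attempts <- 100 * target
  accepted <- 0L
  attempts <- 0L
  ei <- ed$i; ej <- ed$j; ew <- ed$weight
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    pick <- sample.int(m, 2)
    a1 <- ei[pick[1]]; b1 <- ej[pick[1]]
    c1 <- ei[pick[2]]; d1 <- ej[pick[2]]
    if (stats::runif(1) < 0.5) { tmp <- c1; c1 <- d1; d1 <- tmp }
    # propose (a1,d1) and (c1,b1)
    if (a1 == d1 || c1 == b1) next
    if (a[a1, d1] > 0 || a[c1, b1] > 0) next
    if (length(unique(c(a1, b1, c1, d1))) < 4) next
    a[a1, b1] <- a[b1, a1] <- 0
    a[c1, d1] <- a[d1, c1] <- 0
    a[a1, d1] <- a[d1, a1] <- ew[pick[1]]
    a[c1, b1] <- a[b1, c1] <- ew[pick[2]]
    ei[pick[1]] <- min(a1, d1); ej[pick[1]] <- max(a1, d1)
    ei[pick[2]] <- min(c1, b1); ej[pick[2]] <- max(c1, b1)
    accepted <- accepted + 1L
  }
  if (accepted == 0L)
    warning("no valid degree-preserving swap exists: returning the input graph")
  out <- .rewired_connectome(x, a)
  attr(out, "n_accepted") <- accepted
  out
}

#' Geometry-preserving rewired surrogate
#'
#' Like [maslov_sneppen_rewire], but swaps are only accepted when the
#' binned edge-length histogram stays within a tolerance of the original,
#' so the surrogate approximately preserves wiring cost. After the
#' topology phase, weights are reassigned by length rank and then shuffled
#' within distance bins, which approximately preserves the original
#' weight-length relationship while keeping the global weight multiset
#' exact.
#'
#' @param x A [connectome] with Euclidean coordinates.
#' @param n_bins Number of (quantile) distance bins (default 10); bins are
#'   merged with a warning when the graph has too few edges per bin.
#' @param bin_tolerance Allowed relative deviation of each bin count from
#'   the original histogram (default 0.2, i.e. every bin within +/- 20%).
#' @param n_swap_per_edge,seed As in [maslov_sneppen_rewire].
#' @return A rewired [connectome]; attributes `"n_accepted"` and
#'   `"bin_breaks"` record the run.
#' @export
geometry_preserving_rewire <- function(x, n_bins = 10, bin_tolerance = 0.2,
                                       n_swap_per_edge = 10, seed = NULL) {
  stopifnot(inherits(x, "connectome"))
  if (is.null(x$coords_euclidean))
    stop("geometry-preserving rewiring needs Euclidean coordinates")
  if (!is.null(seed)) set.seed(seed)
  a <- x$adjacency
  D <- as.matrix(stats::dist(x$coords_euclidean))
  ed <- connectome_edges(x)
  m <- nrow(ed)
  if (m / n_bins < 5) {
    n_bins_new <- max(1L, floor(m / 5))
    warning(sprintf("too few edges per bin: merging %d bins into %d",
                    n_bins, n_bins_new))
    n_bins <- n_bins_new
  }
  br <- stats::quantile(ed$length, probs = seq(0, 1, length.out = n_bins + 1))
  br[1] <- -Inf; br[length(br)] <- Inf
  br <- unique(br)
  bin_of <- function(len) findInterval(len, br, rightmost.closed = TRUE)
  orig_counts <- tabulate(bin_of(ed$length), nbins = length(br) - 1)
  lo <- pmax(0, floor(orig_counts * (1 - bin_tolerance)) - 0)
  hi <- ceiling(orig_counts * (1 + bin_tolerance))
  lo <- pmin(lo, pmax(orig_counts - 1, 0))   # >= 1 swap slack for tiny bins
  hi <- pmax(hi, orig_counts + 1)
  counts <- orig_counts
  ei <- ed$i; ej <- ed$j
  target <- n_swap_per_edge * m
  max_attempts <- 200 * target
  accepted <- 0L; attempts <- 0L
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    pick <- sample.int(m, 2)
    a1 <- ei[pick[1]]; b1 <- ej[pick[1]]
    c1 <- ei[pick[2]]; d1 <- ej[pick[2]]
    if (stats::runif(1) < 0.5) { tmp <- c1; c1 <- d1; d1 <- tmp }
    if (a1 == d1 || c1 == b1) next
    if (a[a1, d1] > 0 || a[c1, b1] > 0) next
    if (length(unique(c(a1, b1, c1, d1))) < 4) next
    rm1 <- bin_of(D[a1, b1]); rm2 <- bin_of(D[c1, d1])
    ad1 <- bin_of(D[a1, d1]); ad2 <- bin_of(D[c1, b1])
    newc <- counts
    newc[rm1] <- newc[rm1] - 1L; newc[rm2] <- newc[rm2] - 1L
    newc[ad1] <- newc[ad1] + 1L; newc[ad2] <- newc[ad2] + 1L
    if (any(newc < lo) || any(newc > hi)) next
    counts <- newc
    a[a1, b1] <- a[b1, a1] <- 0
    a[c1, d1] <- a[d1, c1] <- 0
    a[a1, d1] <- a[d1, a1] <- 1   # placeholder; weights reassigned below
    a[c1, b1] <- a[b1, c1] <- 1
    ei[pick[1]] <- min(a1, d1); ej[pick[1]] <- max(a1, d1)
    ei[pick[2]] <- min(c1, b1); ej[pick[2]] <- max(c1, b1)
    accepted <- accepted + 1L
  }
  if (accepted == 0L)
    warning("no valid geometry-preserving swap found: topology unchanged")
  # weight reassignment: length-rank matching, then within-bin shuffle
  new_len <- D[cbind(ei, ej)]
  w_sorted <- ed$weight[order(ed$length)]
  ord <- order(new_len)
  w_new <- numeric(m)
  w_new[ord] <- w_sorted
  for (b in seq_len(length(br) - 1)) {
    in_bin <- which(bin_of(new_len) == b)
    if (length(in_bin) > 1)
      w_new[in_bin] <- w_new[sample(in_bin)]
  }
  a[a > 0] <- 0
  a[cbind(ei, ej)] <- w_new
  a[cbind(ej, ei)] <- w_new
  out <- .rewired_connectome(x, a)
  attr(out, "n_accepted") <- accepted
  attr(out, "bin_breaks") <- br
  out
}

.rewired_connectome <- function(x, a) {
  connectome(a, x$node_labels, coords_euclidean = x$coords_euclidean,
             coords_spherical = x$coords_spherical,
             hemisphere = x$hemisphere)
}

#' z-score of an empirical value against a null distribution
#'
#' @param empirical Scalar empirical statistic.
#' @param null_values Numeric vector of null statistics (>= 20 recommended;
#'   fewer triggers a warning).
#' @return List with `z = (empirical - mean(null)) / sd(null)` and the
#'   empirical `percentile` within the null distribution.
#' @export
null_zscore <- function(empirical, null_values) {
  null_values <- as.numeric(null_values)
  if (length(null_values) < 2) stop("need at least 2 null values")
  if (length(null_values) < 20)
    warning("fewer than 20 null values: z-score will be noisy")
  s <- stats::sd(null_values)
  if (s == 0) stop("null distribution has zero standard deviation")
  list(z = (empirical - mean(null_values)) / s,
       percentile = mean(null_values < empirical) +
         0.5 * mean(null_values == empirical))
}

#' Compare empirical transition energy against rewired-null ensembles
#'
#' Computes the mean all-to-all transition energy on the empirical
#' connectome and on each of `n_nulls` rewired surrogates, and summarises
#' the comparison with a z-score and a one-sided empirical p-value for the
#' hypothesis that the empirical network supports cheaper transitions
#' (`p = (#{null <= empirical} + 1) / (n_nulls + 1)`).
#'
#' @param x A [connectome].
#' @param states Regions x terms state matrix.
#' @param null_kind `"degree_preserving"` or `"geometry_preserving"`.
#' @param n_nulls Number of surrogates (>= 20 for stable z-scores).
#' @param T,rho,c,b_diag,n_steps Control configuration, as in
#'   [transition_energy_matrix].
#' @param seed Integer; surrogate i uses seed `seed + i`.
#' @param ... Extra arguments passed to the rewiring function.
#' @return List with `empirical` (mean energy), `null_values`, `z`, `p`,
#'   `kind`, `seeds`, and a `degenerate` flag when the null distribution
#'   has zero spread.
#' @export
empirical_vs_null_energy <- function(x, states,
                                     null_kind = c("degree_preserving",
                                                   "geometry_preserving"),
                                     n_nulls = 50, T = 1, rho = 1, c = 0,
                                     b_diag = 1, n_steps = 1000, seed = 1,
                                     ...) {
  null_kind <- match.arg(null_kind)
  stopifnot(inherits(x, "connectome"))
  mean_energy <- function(g) {
    tem <- transition_energy_matrix(g, states, T = T, rho = rho, c = c,
                                    b_diag = b_diag, n_steps = n_steps)
    mean(tem$energies)
  }
  empirical <- mean_energy(x)
  seeds <- seed + seq_len(n_nulls)
  rewire <- switch(null_kind,
                   degree_preserving = function(s)
                     maslov_sneppen_rewire(x, seed = s, ...),
                   geometry_preserving = function(s)
                     geometry_preserving_rewire(x, seed = s, ...))
  null_values <- vapply(seeds, function(s) mean_energy(rewire(s)), numeric(1))
  if (stats::sd(null_values) == 0) {
    z <- if (empirical == mean(null_values)) 0 else
      sign(empirical - mean(null_values)) * Inf
    degenerate <- TRUE
  } else {
    z <- null_zscore(empirical, null_values)$z
    degenerate <- FALSE
  }
  list(empirical = empirical, null_values = null_values, z = z,
       p = (sum(null_values <= empirical) + 1) / (n_nulls + 1),
       kind = null_kind, seeds = seeds, degenerate = degenerate)
}

#' Permutation test of domain-wise asymmetry
#'
#' Tests, for each cognitive domain, whether the median per-target net
#' asymmetry score of its terms is higher than expected for a random
#' equally sized subset of the labeled terms (labels permuted among
#' labeled terms; one-sided `p = (#{null >= observed} + 1) / (n_perm + 1)`).
#'
#' @param net_scores Named numeric vector of per-term net asymmetry scores.
#' @param domain_labels Vector of domain labels, NA for unlabeled terms.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return Data frame with one row per tested domain: `domain`, `n_terms`,
#'   `observed_median`, `p`. Domains with fewer than 2 terms are skipped
#'   with a warning.
#' @export
permutation_domain_test <- function(net_scores, domain_labels,
                                    n_perm = 1000, seed = 1) {
  if (length(net_scores) != length(domain_labels))
    stop("net_scores and domain_labels lengths differ")
  set.seed(seed)
  keep <- !is.na(domain_labels)
  sc <- as.numeric(net_scores[keep])
  lab <- as.character(domain_labels[keep])
  domains <- unique(lab)
  small <- domains[table(lab)[domains] < 2]
  if (length(small) > 0) {
    warning(sprintf("skipping domain(s) with < 2 terms: %s",
                    paste(small, collapse = ", ")))
    domains <- setdiff(domains, small)
  }
  perm_labs <- replicate(n_perm, sample(lab))
  out <- lapply(domains, function(d) {
    obs <- stats::median(sc[lab == d])
    nulls <- apply(perm_labs, 2, function(pl) stats::median(sc[pl == d]))
    data.frame(domain = d, n_terms = sum(lab == d), observed_median = obs,
               p = (sum(nulls >= obs) + 1) / (n_perm + 1))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
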