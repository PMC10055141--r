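#' Partial Spearman correlation
#'
#' Rank-transforms all variables, residualizes `x` and `y` on the
#' covariates by least squares (with intercept), and returns the Pearson
#' correlation of the residuals with a t-based p-value
#' (`df = n - 2 - n_covariates`). With no covariates this reduces to the
#' plain Spearman correlation.
#'
#' @param x,y Numeric vectors (>= 10 observations).
#' @param covariates Optional numeric vector, matrix, or data frame of
#'   covariates (full rank after ranking).
#' @return List with `rho`, `p`, and `df`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 10) stop("need at least 10 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant variable after ranking")
  k <- 0
  if (!is.null(covariates)) {
    Z <- apply(as.matrix(covariates), 2, rank)
    k <- ncol(Z)
    if (qr(cbind(1, Z))$rank < k + 1) stop("covariates are rank deficient")
    rx <- stats::lm.fit(cbind(1, Z), rx)$residuals
    ry <- stats::lm.fit(cbind(1, Z), ry)$residuals
  }
  # residuals at numerical-noise level carry no signal
  if (stats::sd(rx) < 1e-10 || stats::sd(ry) < 1e-10)
    return(list(rho = 0, p = 1, df = n - 2 - k))
  rho <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  list(rho = rho, p = 2 * stats::pt(-abs(tval), df = df), df = df)
}

#' Dominance analysis of a linear regression
#'
#' Decomposes the full model's R^2 into per-predictor contributions by
#' fitting ordinary least squares on every non-empty predictor subset
#' (2^p - 1 models). The general dominance of predictor k is the
#' size-stratified (Budescu) average of its incremental R^2: the mean,
#' over subset sizes s = 0..p-1, of the average increase in R^2 when k is
#' added to a subset of size s not containing it. General dominances sum
#' exactly to the full-model (unadjusted) R^2.
#'
#' @param predictors K x p numeric matrix or data frame (p <= 8; the
#'   exhaustive sweep fits 2^p - 1 models).
#' @param response Numeric K-vector (K > p + 2).
#' @param averaging `"size_stratified"` (default; exact sum identity) or
#'   `"uniform"` (plain mean over all submodels containing/excluding k;
#'   does not satisfy the sum identity exactly).
#' @param adjusted Also report dominance rescaled to the full model's
#'   adjusted R^2 (display convenience; the exact decomposition applies to
#'   unadjusted R^2).
#' @return List with `dominance` (named p-vector), `r2_full`,
#'   `r2_full_adjusted`, `subset_r2` (named vector over subsets), and, if
#'   `adjusted`, `dominance_adjusted`.
#' @export
dominance_analysis <- function(predictors, response,
                               averaging = c("size_stratified", "uniform"),
                               adjusted = FALSE) {
  averaging <- match.arg(averaging)
  X <- as.matrix(predictors)
  y <- as.numeric(response)
  p <- ncol(X)
  n <- nrow(X)
  if (p > 8) stop("at most 8 predictors (exhaustive subset sweep)")
  if (n <= p + 2) stop("need more observations than predictors + 2")
  if (qr(cbind(1, X))$rank < p + 1)
    stop(sprintf("collinear predictors (design condition number %.3g)",
                 kappa(cbind(1, X))))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  tss <- sum((y - mean(y))^2)
  r2_of <- function(idx) {
    if (length(idx) == 0) return(0)
    fit <- stats::lm.fit(cbind(1, X[, idx, drop = FALSE]), y)
    1 - sum(fit$residuals^2) / tss
  }
  subsets <- lapply(seq_len(2^p - 1), function(m)
    which(bitwAnd(m, 2^(seq_len(p) - 1)) > 0))
  r2 <- vapply(subsets, r2_of, numeric(1))
  names(r2) <- vapply(subsets, function(s)
    paste(colnames(X)[s], collapse = "+"), "")
  key <- vapply(subsets, function(s) sum(2^(s - 1)), numeric(1))
  r2_by_key <- stats::setNames(r2, key)
  get_r2 <- function(idx) {
    if (length(idx) == 0) 0 else unname(r2_by_key[as.character(sum(2^(idx - 1)))])
  }
  # combn(x, m) treats a scalar x as seq_len(x); guard against that
  subsets_of <- function(x, s) {
    if (s == 0) list(integer(0))
    else if (length(x) == 1 && s == 1) list(x)
    else utils::combn(x, s, simplify = FALSE)
  }
  dominance <- numeric(p)
  for (k in seq_len(p)) {
    others <- setdiff(seq_len(p), k)
    incr_by_size <- vapply(0:(p - 1), function(s) {
      mean(vapply(subsets_of(others, s), function(S)
        get_r2(sort(c(S, k))) - get_r2(S), numeric(1)))
    }, numeric(1))
    dominance[k] <- if (averaging == "size_stratified") mean(incr_by_size)
      else {
        subs <- unlist(lapply(0:(p - 1), function(s) subsets_of(others, s)),
                       recursive = FALSE)
        mean(vapply(subs, function(S)
          get_r2(sort(c(S, k))) - get_r2(S), numeric(1)))
      }
  }
  names(dominance) <- colnames(X)
  r2_full <- get_r2(seq_len(p))
  out <- list(dominance = dominance, r2_full = r2_full,
              r2_full_adjusted = 1 - (1 - r2_full) * (n - 1) / (n - p - 1),
              subset_r2 = r2, averaging = averaging)
  if (adjusted)
    out$dominance_adjusted <- dominance / r2_full * out$r2_full_adjusted
  out
}

#' Build the per-term predictor table for transition cost
#'
#' One row per state/term: response = mean energy to reach the term's
#' state from all other states; predictors = the map's mean, SD, network
#' variance (effective-resistance based), and its Spearman correlations
#' with nodal degree, strength, participation coefficient, and any extra
#' annotation columns.
#'
#' @param states Regions x terms matrix.
#' @param x A [connectome].
#' @param tem A `"transition_energy_matrix"` over the same terms.
#' @param module_assignment Node-to-module assignment for the
#'   participation coefficient.
#' @param annotations Optional named list / data frame of per-node
#'   annotation vectors; each contributes a `cor_<name>` column.
#' @return Data frame (class `"predictor_table"`), one row per term, with
#'   a `degenerate_response` attribute flag when the response is constant.
#' @export
build_predictor_table <- function(states, x, tem, module_assignment,
                                  annotations = NULL) {
  states <- as.matrix(states)
  stopifnot(inherits(x, "connectome"), nrow(states) == x$n_nodes)
  e <- .tem_matrix(tem)
  k <- ncol(states)
  if (nrow(e) != k) stop("tem dimension must match the number of states")
  np <- node_predictors(x, module_assignment, annotations)
  res <- effective_resistance(x)
  response <- (colSums(e) - diag(e)) / (k - 1)
  nv <- apply(states, 2, function(v) network_variance(res, map_to_distribution(v)))
  tab <- data.frame(
    term = colnames(states) %||% paste0("state", seq_len(k)),
    mean = colMeans(states),
    sd = apply(states, 2, stats::sd),
    network_variance = nv,
    cor_degree = apply(states, 2, function(v)
      stats::cor(v, np$degree, method = "spearman")),
    cor_strength = apply(states, 2, function(v)
      stats::cor(v, np$strength, method = "spearman")),
    cor_participation = apply(states, 2, function(v)
      stats::cor(v, np$participation, method = "spearman")),
    row.names = NULL)
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations)
    for (nm in names(ann))
      tab[[paste0("cor_", nm)]] <- apply(states, 2, function(v)
        stats::cor(v, ann[[nm]], method = "spearman"))
  }
  tab$mean_energy_to_reach <- response
  degen <- stats::sd(response) == 0
  if (degen)
    warning("constant response: predictor correlations with it are undefined")
  attr(tab, "degenerate_response") <- degen
  class(tab) <- c("predictor_table", "data.frame")
  tab
}
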