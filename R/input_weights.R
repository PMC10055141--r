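#' Control-input weightings
#'
#' Constructors for the diagonal of the control-input matrix B. Uniform
#' gains give whole-brain control; receptor-density and disease
#' cortical-abnormality maps give regionally heterogeneous gains.
#'
#' @param n_nodes Number of regions.
#' @return Object of class `"input_weighting"`: list with `b_diag`
#'   (nonnegative gains, at least one positive), `scheme`, and
#'   `source_map_name`.
#' @export
uniform_inputs <- function(n_nodes) {
  stopifnot(n_nodes >= 1)
  structure(list(b_diag = rep(1, n_nodes), scheme = "uniform",
                 source_map_name = NA_character_),
            class = "input_weighting")
}

#' @rdname uniform_inputs
#' @param cohens_d_map Numeric vector of per-region Cohen's d cortical
#'   thickness abnormalities (all > -1 so gains stay positive). Gains are
#'   `1 + d`: atrophied regions inject less input, thickened regions more.
#' @param name Optional map name recorded in the weighting.
#' @export
disease_inputs <- function(cohens_d_map, name = NULL) {
  d <- as.numeric(cohens_d_map)
  if (any(d <= -1))
    stop("Cohen's d values <= -1 would give non-positive input gains")
  structure(list(b_diag = 1 + d, scheme = "disease",
                 source_map_name = name %||% deparse(substitute(cohens_d_map))),
            class = "input_weighting")
}

#' @rdname uniform_inputs
#' @param density_map Nonconstant numeric vector of regional receptor
#'   densities. The map is min-max scaled to `[0, 1]` and added to the
#'   uniform gains, so gains lie in `[1, 2]` (map minimum -> 1, map
#'   maximum -> 2); invariant to affine rescaling of the input map.
#' @export
receptor_inputs <- function(density_map, name = NULL) {
  v <- as.numeric(density_map)
  rng <- range(v)
  if (diff(rng) == 0)
    stop("constant receptor map: min-max scaling is degenerate")
  structure(list(b_diag = 1 + (v - rng[1]) / diff(rng), scheme = "receptor",
                 source_map_name = name %||% deparse(substitute(density_map))),
            class = "input_weighting")
}

#' @export
print.input_weighting <- function(x, ...) {
  cat(sprintf("<input_weighting> scheme = %s, gains in [%.3g, %.3g]\n",
              x$scheme, min(x$b_diag), max(x$b_diag)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared machinery: per-target mean reach energy for an annotation map and
# its spin surrogates, all passed through the same gain construction
.weighting_energy_sweep <- function(x, states, maps, gain_fun, n_rot, seed,
                                    T, rho, c, n_steps, rotations = NULL) {
  stopifnot(inherits(x, "connectome"))
  maps <- as.matrix(maps)
  system <- normalize_adjacency(x, c = c)
  reach_tem <- function(b_diag) {
    transition_energy_matrix(
      control_operators(system, T = T, rho = rho, b_diag = b_diag,
                        n_steps = n_steps), states)$energies
  }
  lapply(seq_len(ncol(maps)), function(mi) {
    map <- maps[, mi]
    ens <- spin_surrogates(map, x, n_rot = n_rot, seed = seed + mi,
                           rotations = rotations)
    emp <- reach_tem(gain_fun(map))
    nulls <- lapply(seq_len(ncol(ens$members)), function(r)
      reach_tem(gain_fun(ens$members[, r])))
    list(map_name = colnames(maps)[mi] %||% paste0("map", mi),
         empirical = emp, nulls = nulls)
  })
}

#' Disease-map z-scores per target state
#'
#' For each disorder map, builds the empirical `1 + d` input weighting and
#' one weighting per spin surrogate of the map, computes for each target
#' state the mean energy to reach it from all other states in the reduced
#' set, and z-scores the empirical value against the surrogate
#' distribution. Negative z = the empirical anatomical layout of
#' abnormality makes that target cheaper to reach than random layouts with
#' the same value distribution and spatial autocorrelation.
#'
#' @param x A [connectome] with spherical coordinates and hemisphere
#'   labels.
#' @param states_reduced Regions x states matrix (the reduced state set;
#'   the study-scale analysis used 25 states).
#' @param disease_maps Regions x disorders matrix of Cohen's d values.
#' @param n_rot Number of spin surrogates per map (default 100).
#' @param seed Integer seed.
#' @param rotations Optional explicit list of rotation matrices forwarded
#'   to [spin_surrogates] (overrides `n_rot`).
#' @param T,rho,c,n_steps Control configuration.
#' @return List with `z` (disorders x targets matrix; `NA` with a flag for
#'   degenerate all-zero maps) and `params`.
#' @export
disease_target_zscores <- function(x, states_reduced, disease_maps,
                                   n_rot = 100, seed = 1,
                                   T = 1, rho = 1, c = 0, n_steps = 1000,
                                   rotations = NULL) {
  res <- .weighting_energy_sweep(
    x, states_reduced, disease_maps,
    gain_fun = function(m) disease_inputs(m, name = "d")$b_diag,
    n_rot = n_rot, seed = seed, T = T, rho = rho, c = c, n_steps = n_steps,
    rotations = rotations)
  targets <- colnames(as.matrix(states_reduced)) %||%
    paste0("state", seq_len(ncol(as.matrix(states_reduced))))
  reach_means <- function(tem) {
    k <- nrow(tem)
    (colSums(tem) - diag(tem)) / (k - 1)   # mean energy to reach each target
  }
  z <- t(vapply(res, function(r) {
    emp <- reach_means(r$empirical)
    nullm <- vapply(r$nulls, reach_means, numeric(length(emp)))
    vapply(seq_along(emp), function(j) {
      s <- stats::sd(nullm[j, ])
      if (s == 0) NA_real_ else (emp[j] - mean(nullm[j, ])) / s
    }, numeric(1))
  }, numeric(length(targets))))
  dimnames(z) <- list(vapply(res, `[[`, "", "map_name"), targets)
  if (anyNA(z))
    warning("degenerate map(s): zero null spread, z reported as NA")
  list(z = z, params = list(n_rot = n_rot, seed = seed, T = T, rho = rho,
                            c = c, n_steps = n_steps))
}

#' Receptor facilitation percentages per target state
#'
#' For each receptor map and each ordered transition in the reduced state
#' set, compares the empirical transition energy against the energy under
#' each spin surrogate of the map. The per-target percentage pools the
#' (source, surrogate) comparisons for that target: the share of
#' comparisons in which the empirical receptor layout needs strictly less
#' energy ("facilitates" the transition). A per-transition percentage
#' table is also returned so either aggregation can be read off.
#'
#' @inheritParams disease_target_zscores
#' @param receptor_maps Regions x receptors matrix of nonnegative
#'   densities.
#' @return List with `percent` (receptors x targets), `per_transition`
#'   (list of K x K matrices of per-pair facilitation percentages, one per
#'   receptor), and `params`.
#' @export
receptor_facilitation <- function(x, states_reduced, receptor_maps,
                                  n_rot = 100, seed = 1,
                                  T = 1, rho = 1, c = 0, n_steps = 1000,
                                  rotations = NULL) {
  res <- .weighting_energy_sweep(
    x, states_reduced, receptor_maps,
    gain_fun = function(m) receptor_inputs(m, name = "r")$b_diag,
    n_rot = n_rot, seed = seed, T = T, rho = rho, c = c, n_steps = n_steps,
    rotations = rotations)
  states_reduced <- as.matrix(states_reduced)
  k <- ncol(states_reduced)
  targets <- colnames(states_reduced) %||% paste0("state", seq_len(k))
  per_transition <- list()
  percent <- matrix(NA_real_, length(res), k,
                    dimnames = list(vapply(res, `[[`, "", "map_name"),
                                    targets))
  off <- row(matrix(0, k, k)) != col(matrix(0, k, k))
  for (ri in seq_along(res)) {
    r <- res[[ri]]
    wins <- matrix(0, k, k)
    for (null_tem in r$nulls) wins <- wins + (r$empirical < null_tem)
    pt <- 100 * wins / length(r$nulls)
    dimnames(pt) <- list(source = targets, target = targets)
    per_transition[[r$map_name]] <- pt
    # pool (source, surrogate) comparisons within each target column
    for (j in seq_len(k))
      percent[ri, j] <- 100 * sum(wins[off[, j], j]) /
        ((k - 1) * length(r$nulls))
  }
  list(percent = percent, per_transition = per_transition,
       params = list(n_rot = n_rot, seed = seed, T = T, rho = rho, c = c,
                     n_steps = n_steps))
}
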