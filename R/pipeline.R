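#' Assemble a run configuration
#'
#' Resolves the parameters for a full analysis run. Defaults reproduce the
#' main-analysis settings: `T = 1`, `rho = 1`, `c = 0`, uniform
#' whole-brain inputs, states used as-is. Every `run_*` function writes
#' the resolved configuration beside its outputs.
#'
#' @param T,rho,c Control parameters.
#' @param normalize_states Scale each state to unit Euclidean norm before
#'   use (supplementary variant).
#' @param n_steps Quadrature grid intervals.
#' @param n_nulls,n_rot,n_perm Surrogate counts for rewiring nulls, spin
#'   tests, and domain permutation tests.
#' @param reduced_state_count States retained (by column order) for the
#'   perturbation analyses.
#' @param seed Master seed; stages derive their own seeds from it.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(T = 1, rho = 1, c = 0, normalize_states = FALSE,
                       n_steps = 1000, n_nulls = 50, n_rot = 100,
                       n_perm = 1000, reduced_state_count = 25, seed = 1) {
  structure(list(T = T, rho = rho, c = c,
                 normalize_states = normalize_states, n_steps = n_steps,
                 n_nulls = n_nulls, n_rot = n_rot, n_perm = n_perm,
                 reduced_state_count = reduced_state_count, seed = seed),
            class = "run_config")
}

.write_outputs <- function(out_dir, config, files) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(config),
                         file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
    for (nm in names(files)) files[[nm]](file.path(out_dir, nm))
  }
  invisible(NULL)
}

#' Run the transition-energy analysis
#'
#' Computes the all-pairs transition energy matrix plus the derived
#' statistics: asymmetry matrix and per-target net scores, source/target
#' variability test, indirect-transition fraction, Spearman correlation of
#' energy with Euclidean state distance, and (when domain labels are
#' supplied) the domain permutation test on net asymmetry.
#'
#' @param x A [connectome].
#' @param states Regions x terms matrix.
#' @param config A [run_config].
#' @param domain_labels Optional per-term domain labels (NA = unlabeled).
#' @param out_dir Optional directory; the TEM, asymmetry and net scores are
#'   written as labeled CSVs with a JSON summary.
#' @return List with `tem`, `asymmetry`, `variability`, `indirect`,
#'   `distance_energy_spearman`, and optionally `domain_test`.
#' @export
run_transition_analysis <- function(x, states, config = run_config(),
                                    domain_labels = NULL, out_dir = NULL) {
  tem <- transition_energy_matrix(x, states, T = config$T, rho = config$rho,
                                  c = config$c, n_steps = config$n_steps,
                                  normalize_states = config$normalize_states)
  asym <- transition_asymmetry(tem)
  vari <- source_target_variability(tem)
  indir <- indirect_transition_fraction(tem)
  dmat <- euclidean_state_distance(states)
  off <- upper.tri(dmat) | lower.tri(dmat)
  dist_cor <- stats::cor(dmat[off], tem$energies[off], method = "spearman")
  out <- list(tem = tem, asymmetry = asym, variability = vari,
              indirect = indir, distance_energy_spearman = dist_cor)
  if (!is.null(domain_labels))
    out$domain_test <- permutation_domain_test(asym$net, domain_labels,
                                               n_perm = config$n_perm,
                                               seed = config$seed)
  summary_json <- list(
    parameters = list(T = config$T, rho = config$rho, c = config$c,
                      n_steps = config$n_steps,
                      normalize_states = config$normalize_states),
    net_scores = as.list(asym$net),
    variability = list(t = vari$t, df = vari$df, cohens_d = vari$cohens_d),
    indirect_fraction = indir$fraction,
    distance_energy_spearman = dist_cor)
  .write_outputs(out_dir, config, list(
    "transition_energy.csv" = function(f)
      .write_labeled_matrix(tem$energies, f),
    "asymmetry.csv" = function(f) .write_labeled_matrix(asym$asymmetry, f),
    "summary.json" = function(f)
      jsonlite::write_json(summary_json, f, auto_unbox = TRUE, digits = NA)))
  out
}

#' Run the rewired-null comparison
#'
#' z-scores and one-sided empirical p-values of the mean all-to-all
#' transition energy against both rewiring null ensembles.
#'
#' @inheritParams run_transition_analysis
#' @return List with one `empirical_vs_null_energy` report per null kind.
#' @export
run_null_comparison <- function(x, states, config = run_config(),
                                out_dir = NULL) {
  reports <- lapply(c("degree_preserving", "geometry_preserving"),
                    function(kind)
    empirical_vs_null_energy(x, states, null_kind = kind,
                             n_nulls = config$n_nulls, T = config$T,
                             rho = config$rho, c = config$c,
                             n_steps = config$n_steps, seed = config$seed))
  names(reports) <- c("degree_preserving", "geometry_preserving")
  .write_outputs(out_dir, config, list(
    "null_comparison.json" = function(f)
      jsonlite::write_json(lapply(reports, function(r)
        r[c("empirical", "z", "p", "kind", "null_values")]),
        f, auto_unbox = TRUE, digits = NA)))
  reports
}

#' Run the input-perturbation analysis
#'
#' Disease z-score table and receptor facilitation-percentage table over
#' the reduced state set, each map compared against its own spin-surrogate
#' ensemble.
#'
#' @inheritParams run_transition_analysis
#' @param receptor_maps,disease_maps Regions x maps annotation matrices
#'   (either may be NULL to skip that arm).
#' @return List with `disease` ([disease_target_zscores] output) and
#'   `receptor` ([receptor_facilitation] output).
#' @export
run_perturbation_analysis <- function(x, states, receptor_maps = NULL,
                                      disease_maps = NULL,
                                      config = run_config(),
                                      out_dir = NULL) {
  k <- min(config$reduced_state_count, ncol(states))
  reduced <- as.matrix(states)[, seq_len(k), drop = FALSE]
  out <- list()
  files <- list()
  if (!is.null(disease_maps)) {
    out$disease <- disease_target_zscores(
      x, reduced, disease_maps, n_rot = config$n_rot, seed = config$seed,
      T = config$T, rho = config$rho, c = config$c,
      n_steps = config$n_steps)
    files[["disease_zscores.csv"]] <- local({
      z <- out$disease$z
      function(f) .write_labeled_matrix(z, f)
    })
  }
  if (!is.null(receptor_maps)) {
    out$receptor <- receptor_facilitation(
      x, reduced, receptor_maps, n_rot = config$n_rot,
      seed = config$seed + 1000, T = config$T, rho = config$rho,
      c = config$c, n_steps = config$n_steps)
    files[["receptor_facilitation.csv"]] <- local({
      pc <- out$receptor$percent
      function(f) .write_labeled_matrix(pc, f)
    })
  }
  .write_outputs(out_dir, config, files)
  out
}
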