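#!/usr/bin/env Rscript
# Stage 5: what makes a state expensive to reach?
#
# Characterises each state map (mean, SD, effective-resistance network
# variance, correlations with nodal degree/strength/participation) and
# relates those characterisations to the mean energy needed to reach the
# state: a partial Spearman screen controlling for map mean and SD, then
# a dominance analysis decomposing the full regression R^2.

suppressPackageStartupMessages(library(nctr))

dat <- "results/data"
g <- read_connectome(file.path(dat, "connectome.csv"),
                     file.path(dat, "coords.csv"))
maps <- read_state_set(file.path(dat, "state_maps.csv"), g$node_labels)

tem <- transition_energy_matrix(g, maps, n_steps = 400)
modules <- as.integer(cut(seq_len(g$n_nodes), 4))
tab <- build_predictor_table(maps, g, tem, modules)

out <- "results/predictors"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write.csv(tab, file.path(out, "predictor_table.csv"), row.names = FALSE)

screen <- c("network_variance", "cor_degree", "cor_strength",
            "cor_participation")
message("partial Spearman with mean energy to reach (mean, SD partialled out):")
part <- lapply(screen, function(v) {
  r <- partial_spearman(tab[[v]], tab$mean_energy_to_reach,
                        covariates = tab[, c("mean", "sd")])
  message(sprintf("  %-18s rho = %+.3f (p = %.3f)", v, r$rho, r$p))
  data.frame(predictor = v, rho = r$rho, p = r$p)
})
write.csv(do.call(rbind, part), file.path(out, "partial_spearman.csv"),
          row.names = FALSE)

pred <- as.matrix(tab[, c("mean", "sd", "network_variance", "cor_strength",
                          "cor_participation")])
dom <- dominance_analysis(pred, tab$mean_energy_to_reach)
message(sprintf("dominance analysis: full R^2 = %.3f", dom$r2_full))
for (nm in names(dom$dominance))
  message(sprintf("  %-18s %.3f (%.0f%% of fit)", nm, dom$dominance[nm],
                  100 * dom$dominance[nm] / dom$r2_full))
write.csv(data.frame(predictor = names(dom$dominance),
                     dominance = unname(dom$dominance),
                     share = unname(dom$dominance) / dom$r2_full),
          file.path(out, "dominance.csv"), row.names = FALSE)
message("wrote ", out)
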