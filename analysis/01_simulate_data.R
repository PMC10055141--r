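#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the three data families the analysis consumes: a geometric
# 68-node connectome at 27% density with weight-length anticorrelation,
# 20 spatially autocorrelated activation maps with heterogeneous
# means/SDs, and receptor-like plus disease-like annotation maps.
# Everything is written as labeled CSV so later stages (and any external
# tool) can reload it.

suppressPackageStartupMessages(library(nctr))

seed <- 1
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

g <- synth_connectome(n_nodes = 68, target_density = 0.27, seed = seed)
maps <- synth_state_maps(g, k_maps = 20, seed = seed + 1)
rec <- synth_annotation_maps(g, "receptor", n_maps = 4, seed = seed + 2)
dis <- synth_annotation_maps(g, "disease", n_maps = 4, seed = seed + 3)

write_connectome(g, file.path(out, "connectome.csv"),
                 file.path(out, "coords.csv"))
write_state_set(maps, file.path(out, "state_maps.csv"))
write_state_set(rec, file.path(out, "receptor_maps.csv"))
write_state_set(dis, file.path(out, "disease_maps.csv"))

ed <- connectome_edges(g)
message(sprintf("connectome: %d nodes, %d edges, density %.3f",
                g$n_nodes, nrow(ed),
                nrow(ed) / (g$n_nodes * (g$n_nodes - 1) / 2)))
message(sprintf("weight-length Spearman rho = %.3f (expected negative)",
                cor(ed$weight, ed$length, method = "spearman")))
message(sprintf("state maps: %d, mean in [%.2f, %.2f], SD in [%.2f, %.2f]",
                ncol(maps), min(colMeans(maps)), max(colMeans(maps)),
                min(apply(maps, 2, sd)), max(apply(maps, 2, sd))))
message("wrote ", out)
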