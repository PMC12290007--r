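#!/usr/bin/env Rscript

# Cluster the adsorbed-state conformations of the reference synthetic
# benchmark with the GROMOS neighbor-count algorithm (Kabsch RMSD over
# peptide heavy atoms, 0.15 nm cutoff) and summarise cluster populations
# with their mean SSD/EED in a per-cluster report table.

suppressPackageStartupMessages(library(surfpep))
dir.create("results", showWarnings = FALSE)

spec <- synthetic_spec(n_frames = 1500L)
sys <- generate_synthetic_system(spec, seed = 1L)
tr <- generate_trajectory(sys, seed = 2L)
prof <- binding_profile(tr$frames, sys$topology)
cat(sprintf("benchmark trajectory: %d frames, %.2f%% bound\n",
            prof$n_frames, prof$percent_bound))

bframes <- extract_bound_frames(tr$frames, prof)
bidx <- which(prof$bound)
stride <- max(1L, ceiling(length(bframes) / 300L))
m <- rmsd_matrix(bframes, topology = sys$topology, stride = stride,
                 unwrap = TRUE)
cl <- gromos_cluster(m, cutoff = 0.15)
print(cl)

kept <- bidx[attr(m, "frame_ids")]
summ <- cluster_summary(cl, prof$times[kept], prof$ssd[kept],
                        prof$eed[kept], population_floor_percent = 10)
print(summ)
cat("planted conformer weights in the bound state: 70 / 30;\n")
cat("template end-to-end distances: 0.65 / 1.40 nm\n")

write.table(summ, "results/cluster_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_cluster_assignments(cl, prof$times[kept],
                          "results/cluster_assignments.tsv")
cat("wrote results/cluster_summary.tsv and results/cluster_assignments.tsv\n")
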