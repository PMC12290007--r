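#!/usr/bin/env Rscript

# Radial distribution functions of typed peptide atoms against the two
# surface oxygen types (OF hydroxyl, OB bridging) over the bound frames of
# the reference benchmark, plus the conditional RDF restricted to Na+ ions
# satisfying the dual 3 Angstrom bridging criterion. Peak positions below
# 4 Angstrom are tabulated; peak heights are normalisation-dependent.

suppressPackageStartupMessages(library(surfpep))
dir.create("results", showWarnings = FALSE)
dir.create("results/rdf", showWarnings = FALSE)

spec <- synthetic_spec(n_frames = 1200L)
sys <- generate_synthetic_system(spec, seed = 3L)
tr <- generate_trajectory(sys, seed = 4L)
prof <- binding_profile(tr$frames, sys$topology)
cls <- classify_atoms(sys$topology, tr$frames[[1]])
bframes <- extract_bound_frames(tr$frames, prof)
bframes <- bframes[seq(1L, length(bframes), by = 2L)]
cat(sprintf("%d bound frames analysed (of %d total)\n", length(bframes),
            prof$n_frames))

selections <- c("sidechain N pos 1", "sidechain N pos 2", "nterm N",
                "sidechain O pos 5", "cterm O", "CA pos 3")
peaks <- NULL
for (sel in selections) {
  sel_a <- resolve_selection(sel, sys$topology, cls)
  if (!length(sel_a)) next
  for (target in c("surface OF", "surface OB")) {
    sel_b <- resolve_selection(target, sys$topology, cls)
    r <- compute_rdf(bframes, sel_a, sel_b)
    pk <- first_peak(r, window_max = 0.4)
    tag <- gsub("\\s+", "_", paste(sel, target))
    write_rdf(r, file.path("results/rdf", paste0(tag, ".rdf")),
              label = paste(sel, "vs", target))
    peaks <- rbind(peaks, data.frame(selection = sel, target = target,
                                     r_peak_nm = pk$r_peak,
                                     g_peak = pk$g_peak,
                                     sub_4A = !pk$outside_window))
  }
}

# conditional RDF: bridging Na+ against the ASP carboxylate oxygens
sel_od <- resolve_selection("sidechain O pos 5", sys$topology, cls)
crdf <- conditional_rdf(bframes, cls, sel_od)
cpk <- first_peak(crdf)
write_rdf(crdf, "results/rdf/bridging_na_vs_asp_O.rdf",
          label = "bridging Na+ vs ASP O")
peaks <- rbind(peaks, data.frame(selection = "bridging NA",
                                 target = "sidechain O pos 5",
                                 r_peak_nm = cpk$r_peak, g_peak = cpk$g_peak,
                                 sub_4A = !cpk$outside_window))

print(peaks)
cat(sprintf("planted contact 0.28 nm; planted Na bridge 0.23 nm\n"))
cat(sprintf("mean bridging Na+ per bound frame: %.3f\n", crdf$mean_n_a))
write.table(peaks, "results/rdf_peaks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("RDF curves under results/rdf/, peak table in results/rdf_peaks.tsv\n")
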