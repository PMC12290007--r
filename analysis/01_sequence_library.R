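#!/usr/bin/env Rscript

# Build the hexapeptide permutation library: all 720 orderings of the
# residues of the titanium-binding peptide RKLPDA, collapsed to 360
# directionally-distinct composition classes (one member per reverse pair).

suppressPackageStartupMessages(library(surfpep))
dir.create("results", showWarnings = FALSE)

lib <- enumerate_permutations("RKLPDA")
cat("enumerated", length(lib), "orderings of {R,K,L,P,D,A}\n")

can <- canonicalize_reverse_pairs(lib)
cat("reverse-pair canonicalization retains", length(can), "sequences\n")
cat("default policy keeps the lexicographically smaller member, so the\n")
cat("pair {RKLPDA, ADPLKR} is represented by ADPLKR; a keep_list override\n")
cat("reproduces any other published choice of representatives:\n")

keep <- ifelse(can$sequences == "ADPLKR", "RKLPDA", can$sequences)
can_keep <- canonicalize_reverse_pairs(lib, policy = "keep_list",
                                       keep_list = keep)
cat("  keep_list variant retains RKLPDA:",
    "RKLPDA" %in% can_keep$sequences, "\n")

write_sequence_list(lib, "results/permutations_720.txt")
write_sequence_list(can, "results/library_360.txt")
cat("wrote results/permutations_720.txt and results/library_360.txt\n")
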