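#!/usr/bin/env Rscript
# Polymorphism panel for an aligned allele set: segregating sites, total
# mutations, mean pairwise differences, nucleotide diversity, amino-acid
# p-distance and mean pairwise identity. Defaults to the simulated allele
# set from 01_simulate_data.R; pass a FASTA path and frame to analyze a
# downloaded allele alignment instead, e.g.
#   Rscript analysis/02_diversity.R my_alleles.fasta 3

suppressPackageStartupMessages(library(mhcselect))

args <- commandArgs(trailingOnly = TRUE)
fasta <- if (length(args) >= 1) args[1] else "results/simdata/alleles.fasta"
frame <- if (length(args) >= 2) as.integer(args[2]) else 1L

seqs <- read_fasta(fasta)
panel <- diversity_stats(seqs, frame = frame, name = basename(fasta))

dir.create("results", showWarnings = FALSE)
write.table(panel, "results/diversity.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf(
  "%s: N = %d alleles, %d bp\n  S = %d, Eta = %d, k = %.3f, Pi = %.3f\n",
  panel$name, panel$n_seqs, panel$n_nucleotides, panel$S, panel$Eta,
  panel$k, panel$Pi))
cat(sprintf("  AA p-distance = %.3f, pairwise identity = %.1f%%\n",
            panel$aa_p_distance, panel$pairwise_identity_pct))
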