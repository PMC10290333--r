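#!/usr/bin/env Rscript
# Generate the synthetic study inputs every later step consumes: a codon
# alignment of MHC-like alleles with a planted positively-selected site
# mask, and a multi-locus amplicon genotype dataset with technical
# replicates, read counts and a partially expressed allele pool.

suppressPackageStartupMessages({
  library(mhcselect)
  library(jsonlite)
})

out_dir <- "results/simdata"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
seed <- 20260928L

# Alignment scale mirrors a class-II exon-2 allele set: 41 alleles, 85
# codons, 20 codons under strong diversifying selection (omega = 6),
# transition bias kappa = 2, pairwise synonymous divergence 0.15.
sim <- simulate_codon_alignment(
  n_alleles = 41, n_codons = 85, mask = 11:30,
  omega_mask = 6, omega_background = 1, kappa = 2,
  syn_divergence = 0.15, seed = seed, name = "simulated alleles")
write_fasta(sim$alignment$seqs, file.path(out_dir, "alleles.fasta"))
write_json(sim$truth, file.path(out_dir, "alignment_truth.json"),
           auto_unbox = TRUE, digits = NA)
writeLines(c("numbering=alignment", as.character(sim$truth$mask)),
           file.path(out_dir, "planted_mask.txt"))

cat("alignment:", length(sim$alignment$ids), "alleles x",
    sim$alignment$n_codons, "codons; planted mask",
    min(sim$truth$mask), "-", max(sim$truth$mask), "\n")

# Genotype dataset mirrors the amplicon study design: 130 individuals
# sequenced of whom 17 fall under the 100-read genotyping threshold,
# 3 loci in one amplicon, skewed allele frequencies with one near-fixed
# allele, 57.5% technical replicates, 2% allele dropout, 35% of the
# allele pool expressed.
gsim <- simulate_genotype_dataset(
  n_individuals = 130, n_loci = 3, pool_size = 30, n_codons = 87,
  skewed_freqs = TRUE, cnv_prob = 0.03, replicate_fraction = 0.575,
  dropout = 0.02, read_mean = 1900, read_dispersion = 2,
  expressed_fraction = 0.35, n_low_read = 17, seed = seed + 1L)

write.table(gsim$table, file.path(out_dir, "genotypes.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write_fasta(gsim$alleles, file.path(out_dir, "allele_pool.fasta"))
write_fasta(gsim$transcripts, file.path(out_dir, "transcripts.fasta"))
write_json(gsim$truth, file.path(out_dir, "genotype_truth.json"),
           auto_unbox = TRUE, digits = NA)

cat("genotypes:", length(unique(gsim$table$individual)), "individuals,",
    length(gsim$alleles), "alleles in pool,",
    length(gsim$transcripts), "expressed transcripts,",
    length(gsim$truth$low_read_individuals), "planted low-read samples\n")
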