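# mhcselect

Codon-level selection and diversity analysis for MHC amplicon allele
sets, written for researchers characterizing a multigene immune family
(typically 1–4 loci amplified together) who need the standard
molecular-evolution panel without a desktop GUI: polymorphism statistics,
site-mask-restricted dN/dS with bootstrap Z-tests, permutation tests of
the overlap between positively selected sites (PSS) and peptide-binding
residues (PBR), a between-class selection comparison, and the genotype
quality control that comes before any of it. A seeded simulator generates
codon alignments under site-specific selection and full amplicon genotype
datasets, so every stage is testable with planted truth.

## What it computes

* **Polymorphism** — segregating sites *S*, total mutations η, mean
  pairwise differences *k*, nucleotide diversity π, amino-acid
  p-distance, mean pairwise % identity; all pairwise statistics under
  pairwise deletion of gaps.
* **dN/dS** — mean pairwise dN and dS by Nei–Gojobori pathway counting
  with Jukes–Cantor correction, or by Pamilo–Bianchi–Li with Kimura
  2-parameter distances on the L0/L2/L4 degeneracy classes
  (dS = (L₂A₂ + L₄A₄)/(L₂+L₄) + B₄, dN = A₀ + (L₀B₀ + L₂B₂)/(L₀+L₂)),
  restricted to site masks resolved through a reference-numbering site
  map (e.g. HLA-A2 residues 92–179).
* **Z-test of positive selection** — Z = (dN − dS)/SE with the SE from a
  codon-column bootstrap (default 1000 replicates) and one-sided
  p = 1 − Φ(Z).
* **PSS–PBR association** — Pearson χ² (no continuity correction) on the
  2×2 site classification plus a permutation p-value (10,000 replicates,
  or the exact hypergeometric tail when the subset space is small).
* **Between-class comparison** —
  Z = (d₁ − d₂)/√(SE₁² + SE₂²) on two dN − dS estimates, with direction
  conventions for one-sided hypotheses and codon-column concatenation for
  composite peptide-binding grooves.
* **Genotype QC** — min-read filtering with an allele-count flag,
  replicate reproducibility 100·2|A∩B|/(|A|+|B|), stop-codon and
  anchor-residue allele validation, exact-substring expression
  cross-check against transcripts, carrier-frequency summaries.

## Worked example

Simulate a 41-allele, 85-codon alignment with ω = 6 planted on codons
11–30, then test for selection on and off the mask:

```r
library(mhcselect)

sim <- simulate_codon_alignment(41, 85, mask = 11:30, omega_mask = 6,
                                kappa = 2, seed = 20260928)
res <- z_test_positive_selection(sim$alignment, mask = 11:30,
                                 reps = 1000, seed = 20260928,
                                 mask_tag = "planted mask")
res
#> Z-test of positive selection (dN > dS)
#>   mask: planted mask  method: NG86-JC  sites: 20
#>   dN = 0.1760  dS = 0.0672  dN/dS = 2.618
#>   dN-dS = 0.1088  SE = 0.0188  Z = 5.788  one-sided p = 3.57e-09
```

dN/dS ≈ 2.6 with p ≈ 10⁻⁹ on the planted mask: the masked codons carry
far more amino-acid change than their synonymous background, exactly what
a peptide-binding region under diversifying selection looks like. The
same test on all 85 sites gives dN/dS ≈ 1.1, p ≈ 0.12 — selection on a
fifth of the sites is invisible without the mask.

Association between two site sets on 87 residues (17 PBRs, 14 PSS, 7
shared):

```r
permutation_independence(87, 1:17, c(1:7, 30:36), R = 10000, seed = 1)
#> site-set association test
#>   87 sites; |A| = 17, |B| = 14, overlap = 7
#>   chi2 = 9.846, p = 0.006 (10000 permutations)
```

The `analysis/` directory runs the full pipeline on simulated data in
order: `01_simulate_data.R` … `06_genotype_qc.R`, writing tables under
`results/`.

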