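---
title: "Selection and diversity analysis of MHC amplicon alignments"
author: "mhcselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection and diversity analysis of MHC amplicon alignments}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhcselect)
```

# The analysis problem

Classical MHC genes are the canonical example of long-term balancing
selection in vertebrates: the codons encoding the peptide-binding groove
accumulate nonsynonymous substitutions faster than synonymous ones, while
the structural scaffold around them is conserved. A characterization study
of an MHC multigene family typically runs the same sequence of analyses:

1. assemble in-frame codon alignments of the amplified exon alleles;
2. summarize polymorphism (segregating sites, nucleotide diversity,
   amino-acid p-distance, pairwise identity);
3. estimate pairwise dN/dS restricted to biologically defined site masks
   (peptide-binding residues from crystal structures, or positively
   selected sites from site-wise scans) and test dN > dS with a
   codon-bootstrap Z-test;
4. test whether the positively selected sites coincide with the
   peptide-binding residues more than chance allows;
5. compare the strength of selection between MHC classes; and
6. validate the amplicon genotypes themselves: read-depth filtering,
   technical-replicate reproducibility, stop-codon and anchor-residue
   checks, and an expression cross-check against transcripts.

`mhcselect` implements each stage as ordinary R functions over plain
containers (named character vectors of sequences, data frames of genotype
rows), and ships a seeded simulator so the whole pipeline can be exercised
and power-checked without any sequence download. The `analysis/` scripts
in the source repository run the stages in order on simulated data.

# Codon alignments and reference numbering

`codon_alignment()` applies a reading frame to an aligned set of
sequences: frame $f$ drops the leading $f-1$ alignment columns and any
trailing remainder shorter than a codon. The trailing trim is necessary
because amplicon boundaries rarely respect codon boundaries — a 258 bp
exon amplicon read in frame 3 leaves 256 usable columns, of which one
trailing column must be dropped to give 85 whole codons. Both trims are
recorded on the object. Ambiguity codes are rejected at load rather than
resolved: the substitution-pathway counting downstream has no principled
way to average over an `N`, and amplicon allele sets are normally reported
unambiguous, so failing fast is safer than guessing.

Site masks are defined in a *reference numbering* (e.g. residues 92–179 of
the HLA-A2 structure for a class-I exon-3 alignment). `build_site_map()`
aligns an ungapped reference fragment to the column-wise consensus of the
translated alignment by global alignment with match = 1, mismatch = 0,
gap = −1; ties in the traceback fall to Biostrings' deterministic
leftmost-gap convention, so mappings are reproducible. Each column aligned
to a reference residue receives that residue's number; columns aligned to
a gap in the reference (insertions relative to the reference) are flagged
unmapped and silently excluded when a mask is resolved. A mapping is
refused when fewer than half of the reference residues land on a column
where the reference residue matches the consensus or any aligned sequence
— below that, the numbering would be numerology.

# Polymorphism statistics

All pairwise statistics use *pairwise deletion*: a site enters a pair's
comparison only when both sequences carry a non-gap state there. This is
the default of the standard desktop tools for this analysis and the only
option that treats a 3 bp deletion allele (common in class IIB exon 2)
without discarding the whole column for every pair.

* `segregating_sites()`: a site is segregating when ≥ 2 distinct non-gap
  bases occur; the total mutation count Eta adds (distinct bases − 1) per
  site, so a triallelic site contributes 2. Sites observed in fewer than
  two sequences cannot segregate and are skipped.
* `nucleotide_diversity()`: $k$ is the mean pairwise difference count and
  $\pi$ the mean pairwise per-site difference; on gap-free data
  $\pi = k/L$ exactly, which the test suite asserts.
* `aa_p_distance()`: mean pairwise proportion of differing residues,
  pairwise-deleting gaps *and* stops.
* `pairwise_identity()`: mean over pairs of identical columns over scored
  columns, where a gap aligned against a base is a mismatch and gap–gap
  columns are unscored. This is the convention of the alignment viewers
  that report "pairwise % identity", and it is deliberately different
  from the pairwise-deletion rule used for $\pi$; the two dialects are
  kept in separate functions rather than behind a switch.

# Pairwise dN/dS

## Nei–Gojobori with Jukes–Cantor correction

Synonymous site counts use the per-position fraction of synonymous
single-base alternatives, with alternatives that create stop codons
excluded from the denominator (a mutation to a stop is not an observable
substitution in sense-codon data). Pathway counting for a codon pair
averages the synonymous/nonsynonymous classification over the 2 or 6
orderings of the differing positions; orderings that pass through a stop
codon are excluded from the average, and in the degenerate case where
every ordering does, all orderings are restored with stop-involving steps
counted as nonsynonymous. Both conventions match the widely used
implementations of the method.

Per pair, counts are summed over the masked codon columns under pairwise
deletion, converted to proportions against the pair-averaged site counts,
and corrected as $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. A proportion
$\ge 3/4$ leaves the corrected distance undefined; such pairs are dropped
from the mean with a warning and a count, never clipped, because clipping
would bias the mean toward an arbitrary ceiling.

## Pamilo–Bianchi–Li (Kimura 2-parameter)

Each compared position is classified as nondegenerate (L0), twofold (L2)
or fourfold (L4) using the strict rule: fourfold if *all* three
alternatives are synonymous, nondegenerate if *none* is, twofold
otherwise, with changes to stops counted as nonsynonymous alternatives.
Where the two codons of a pair disagree on a position's class, membership
is split half-and-half — the method's sources leave this open and the
half-split is the symmetric choice. Transitions $P_i$ and transversions
$Q_i$ are tallied per class, converted to the Kimura 2-parameter
components $A_i$ (transitional) and $B_i$ (transversional), and combined
as

$$d_S = \frac{L_2 A_2 + L_4 A_4}{L_2 + L_4} + B_4, \qquad
  d_N = A_0 + \frac{L_0 B_0 + L_2 B_2}{L_0 + L_2}.$$

Classes with no sites contribute zero; a non-positive logarithm argument
(saturation) drops the pair, as above. Rate-heterogeneity (gamma)
adjustments are deliberately not applied to these distances: the
reference desktop implementations do not document gamma-adjusted dN/dS
semantics precisely enough to reproduce, and none of the quantities this
package pins its tests to depend on them.

## Bootstrap and the Z-test

`bootstrap_se()` resamples the masked codon *columns* with replacement —
one resampling per replicate applied to every sequence, i.e. the codon
bootstrap of the standard tools, not per-pair resampling — and recomputes
the pair-averaged dN and dS. The SE of $d_N - d_S$ is the standard
deviation across replicates. Replicates where no pair has a defined
distance are dropped; if more than half are, the bootstrap errors out
rather than returning a fiction. Within a replicate, individual saturated
pairs are dropped exactly as in the point estimate, keeping the bootstrap
distribution consistent with the statistic it estimates.

`z_test_positive_selection()` reports $Z = (d_N - d_S)/SE$ with one-sided
$p = 1 - \Phi(Z)$. When the SE is zero (monomorphic data) the test
degenerates to $Z = 0, p = 0.5$ if $d_N = d_S$, otherwise $p$ is 0 or 1
with a warning. dN/dS itself is reported as `NA` when mean dS is zero, as
happens for near-monomorphic loci; the difference $d_N - d_S$ remains
defined and is what the class comparison consumes.

The implementation precomputes 64×64 codon-pair lookup tables at install
time and expresses a bootstrap replicate as a column reweighting, so a
41-allele × 85-codon alignment with 1000 bootstrap replicates runs in
well under a second.

# Site-set association

`chi_square_2x2()` is the Pearson statistic without continuity correction
on the table `[[overlap, A only], [B only, neither]]`. No correction is
applied because the statistic is only used as an ordering device for the
permutation test, and because the published values for this analysis
reproduce exactly without it.

`permutation_independence()` fixes one mask and redraws the other as a
uniform random subset of the same size (redrawing both is equivalent
under exchangeability). The tail rule is $\ge$ with a small numeric
epsilon, and the sampled p-value is smoothed as $(\text{hits}+1)/(R+1)$,
which avoids reporting $p = 0$ from finite replication. When
$\binom{n}{|B|} \le 10^5$ the null is computed exactly instead: the
statistic depends on the redrawn mask only through its overlap with the
fixed mask, and that overlap is hypergeometric, so the exact tail is a
hypergeometric sum — identical to enumerating all subsets, without
enumerating them. Results carry an `exact` flag.

# Between-class comparison

`class_z()` implements
$Z = (d_1 - d_2)/\sqrt{SE_1^2 + SE_2^2}$ on two $d_N - d_S$ estimates
with one-sided $p = 1 - \Phi(Z)$. `compare_classes()` always reports $Z$
on the first-minus-second scale and lets `direction` choose the tested
tail, so a comparison hypothesizing the *second* class stronger prints a
negative $Z$ with the small one-sided $p$ — the convention of the
published tables this statistic comes from. Composite-groove comparisons
(class II α1+β1) are supported by `concat_alignments()`, which appends
codon columns under an explicit caller-supplied pairing table: which
α allele is haplotype-paired with which β allele is biological knowledge
the package cannot infer.

# Genotype quality control

* `filter_genotypes()` removes samples (individual × replicate ×
  amplicon) whose total reads fall below the threshold (default 100) and
  *flags without removing* genotypes above the allele cap (default 6 for
  a three-locus amplicon): oversized genotypes can be real copy-number
  variation and deserve scrutiny, not silent deletion.
* `replicate_reproducibility()` is $100 \cdot 2|A \cap B|/(|A|+|B|)$;
  `mean_reproducibility()` averages it over all replicate pairs. Under
  independent per-allele dropout at rate $d$ its expectation is
  approximately $100(1-d)$, which the tests verify against the simulator.
* `validate_allele()` reports, never raises: stop codons in the
  translation, and per anchor position `match` / `tolerated` /
  `mismatch` / `unmapped`. The bundled `mhc_anchor_spec()` encodes the
  classical class-I peptide-terminus anchors (T143, K146, W147, Y159,
  Y171 in HLA-A2 numbering, with R tolerated at 146 as a conservative
  basic substitution widespread outside mammals) and the class-IIB
  invariants (W61, H81, N82 in HLA-DRB1 numbering).
* `expression_crosscheck()` declares an allele expressed iff its full
  ungapped sequence occurs exactly as a substring of a transcript or its
  reverse complement. At 100% identity over a ≥ 250 bp allele this is
  equivalent to a stringent megablast hit and is reproducible bit for
  bit, which a local-alignment E-value is not.
* Replicates are collapsed to a consensus genotype by *set union* in
  `allele_summary()`. Union is the conservative reconstruction when the
  final per-individual genotypes are produced upstream by a denoising
  genotyper; intersection would delete true alleles lost to dropout in
  one replicate. This is a dialect choice and is stated here rather than
  hidden.

# The simulator

`simulate_codon_alignment()` evolves each allele independently from a
shared uniform-random sense-codon root (a star genealogy). Proposals are
single-base changes with transitions weighted by $\kappa$; proposals
creating stops are rejected; nonsynonymous proposals are accepted with
probability $\min(1, \omega)$ and synonymous proposals with probability
$\min(1, 1/\omega)$ at the proposal's codon site. The two-sided rule
matters: accepting only nonsynonymous proposals at $\min(1,\omega)$
would make every $\omega \ge 1$ behave identically to neutral, whereas
with the two-sided rule the nonsynonymous-to-synonymous acceptance ratio
equals $\omega$ on both sides of 1, so planted diversifying selection
($\omega = 6$) is actually detectable by the statistics under test.
Branch lengths are controlled by accumulating synonymous substitutions
until half the target *pairwise* synonymous divergence is reached,
counted against the root's synonymous site total; per-branch targets
above 3 substitutions per synonymous site are refused as saturated.

The star genealogy is a deliberate simplification: it induces the
pairwise-divergence structure the statistics consume and keeps the truth
record exact, but it produces no shared internal branches, no
recombination and no gene conversion. Passing power checks on simulated
data therefore demonstrate the statistics' behaviour under independent
divergence, not robustness to the reticulate history real MHC alleles
have.

`simulate_genotype_dataset()` emulates the amplicon study design: three
loci amplified in one reaction (two alleles drawn per locus,
homozygosity allowed, so 1–6 distinct alleles per genotype; an optional
extra locus with small probability emulates copy-number variation),
negative-binomial read counts, a configurable fraction of individuals
with a technical replicate, independent per-allele dropout between
replicates, a planted subset of individuals scaled below the 100-read
threshold, and a planted expressed subset of the allele pool emitted as
transcripts embedded in random flanks. Defaults mirror the study system
the package is modelled on: 130 sequenced individuals of which 17 fail
the read threshold, 57.5% replicated, mean reads per sample 1900, a
skewed allele-frequency pool with one near-fixed allele, and 35% of
alleles expressed. The dropout rate (2%) is not reported by such studies
directly; it was chosen once so that simulated reproducibility lands in
the high-90s range reported for careful amplicon protocols, and it is a
config parameter, not a constant.

# Problem sizes and numerical choices

The test suite and the acceptance script use: 30 alleles × 90 codons
with a 20-codon mask, $\kappa = 2$, $\omega \in \{1, 6\}$ and 1000
bootstrap replicates for the power/size characterization (50 simulation
replicates per arm: planted selection is detected at $p < 0.05$ in
≥ 80% of replicates, neutral data rejected in ≤ 10%); 41 alleles × 85
codons for the diversity panel; 10,000 replicates for sampled
permutation p-values. Exhaustive oracle checks (all 61 sense codons, 500
random codon pairs against an independent pathway enumerator) are exact,
not tolerance-based. Equality tolerances elsewhere are $10^{-9}$ or
tighter except where a statistic is compared against an independent
Monte-Carlo estimate, where three binomial standard errors are used.

# Known limitations

* No recombination detection or recombination-aware simulation;
  recombination-pruned alignments are accepted as alternative inputs.
* Site-wise selection inference (FUBAR/MEME-style) is out of scope: PSS
  masks are inputs.
* Gamma rate heterogeneity is not applied to dN/dS distances (see above).
* The site map assumes a colinear reference fragment; large
  rearrangements between reference and alignment will fail the placement
  threshold rather than map partially.
* The simulator's star genealogy understates the variance of pairwise
  statistics relative to a coalescent with recombination.
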