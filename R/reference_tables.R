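# Bundled reference inputs for the common buzzard / HLA study system:
# printed site counts for the PSS-vs-PBR overlap comparisons and the
# (dN - dS, SE) inputs for the between-class selection comparisons. These
# are inputs to the statistics, not results.

#' Site counts for the PSS / peptide-binding-residue overlap tests
#'
#' One row per comparison of positively selected sites (PSS) against a
#' peptide-binding-residue (PBR) set on a common buzzard MHC exon
#' alignment: total amino-acid sites, PBR set size, PSS set size, and the
#' observed overlap. PBR definitions: human and chicken from crystal
#' structures, non-passerine from a comparative selection scan. The
#' `mhc_iib_norecomb` rows use the PSS set inferred after removing
#' recombinant segments.
#'
#' @return Data frame with columns `locus`, `pbr_set`, `n_sites`,
#'   `n_pbr`, `n_pss`, `n_overlap`.
#' @export
pbr_pss_overlap_counts <- function() {
  df <- rbind(
    data.frame(locus = "mhc_i_exon3", pbr_set = "human",
               n_sites = 87, n_pbr = 17, n_pss = 14, n_overlap = 7),
    data.frame(locus = "mhc_i_exon3", pbr_set = "non_passerine",
               n_sites = 87, n_pbr = 13, n_pss = 14, n_overlap = 5),
    data.frame(locus = "mhc_i_exon3", pbr_set = "chicken",
               n_sites = 87, n_pbr = 9, n_pss = 14, n_overlap = 7),
    data.frame(locus = "mhc_iib_exon2", pbr_set = "human",
               n_sites = 85, n_pbr = 24, n_pss = 16, n_overlap = 11),
    data.frame(locus = "mhc_iib_exon2", pbr_set = "non_passerine",
               n_sites = 85, n_pbr = 22, n_pss = 16, n_overlap = 11),
    data.frame(locus = "mhc_iib_exon2", pbr_set = "chicken",
               n_sites = 85, n_pbr = 24, n_pss = 16, n_overlap = 14),
    data.frame(locus = "mhc_iib_norecomb", pbr_set = "human",
               n_sites = 85, n_pbr = 24, n_pss = 15, n_overlap = 8),
    data.frame(locus = "mhc_iib_norecomb", pbr_set = "non_passerine",
               n_sites = 85, n_pbr = 22, n_pss = 15, n_overlap = 10),
    data.frame(locus = "mhc_iib_norecomb", pbr_set = "chicken",
               n_sites = 85, n_pbr = 24, n_pss = 15, n_overlap = 11))
  df
}

#' Between-class selection comparison inputs
#'
#' dN - dS estimates with bootstrap standard errors for the human HLA and
#' common buzzard peptide-binding-domain allele sets (Nei-Gojobori
#' distances on human PBR sites, 1000 bootstraps), for single domains and
#' for the composite groove (class I alpha1+alpha2; class II
#' alpha1+beta1 concatenation).
#'
#' @return Data frame with columns `species`, `region`, `dnds_diff`,
#'   `se`.
#' @export
class_selection_inputs <- function() {
  data.frame(
    species = c(rep("human", 5), rep("buzzard", 5)),
    region = c("hla_i_exon2", "hla_i_exon3", "hla_i_exon2_3",
               "hla_drb1_exon2", "hla_ii_a_b1_exon2",
               "mhc_i_exon2", "mhc_i_exon3", "mhc_i_exon2_3",
               "mhc_iib_exon2", "mhc_ii_a_b_exon2"),
    dnds_diff = c(0.203, 0.123, 0.161, 0.117, 0.050,
                  0.219, 0.121, 0.166, 0.367, 0.175),
    se = c(0.081, 0.076, 0.054, 0.086, 0.046,
           0.075, 0.059, 0.042, 0.105, 0.047),
    stringsAsFactors = FALSE)
}

#' Conserved anchor-residue specifications for classical MHC molecules
#'
#' Class I: the five peptide-terminus-binding positions T143, K146, W147,
#' Y159, Y171 in HLA-A2 numbering, with arginine tolerated at 146 (a
#' conservative basic substitution widespread in non-mammals). Class IIB:
#' the three invariant main-chain-binding positions W61, H81, N82 in
#' HLA-DRB1 numbering.
#'
#' @param class_tag `"I"` or `"IIB"`.
#' @return An [anchor_spec()].
#' @export
mhc_anchor_spec <- function(class_tag = c("I", "IIB")) {
  class_tag <- match.arg(class_tag)
  if (class_tag == "I") {
    anchor_spec("HLA-A2",
                positions = c(143, 146, 147, 159, 171),
                required = c("T", "K", "W", "Y", "Y"),
                tolerated = list(character(0), "R", character(0),
                                 character(0), character(0)))
  } else {
    anchor_spec("HLA-DRB1",
                positions = c(61, 81, 82),
                required = c("W", "H", "N"))
  }
}
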