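# Polymorphism statistics on aligned sequence sets. All pairwise statistics
# use pairwise deletion: a site enters a pair's comparison only when both
# sequences carry a non-gap state there.

.seq_matrix <- function(seqs) {
  seqs <- if (inherits(seqs, "codon_alignment")) seqs$seqs else seqs
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences are not all the same length")
  do.call(rbind, strsplit(toupper(unname(seqs)), ""))
}

.check_n <- function(m) {
  if (nrow(m) < 2L) stop("need at least 2 sequences")
}

#' Segregating sites and total mutations
#'
#' A site is segregating (counted in `S`) when at least two distinct
#' non-gap bases occur there; `Eta`, the total number of mutations, adds
#' the number of distinct non-gap bases minus one at every such site, so
#' triallelic sites contribute 2. Sites where fewer than two sequences
#' carry a non-gap base cannot segregate and are skipped.
#'
#' @param seqs Named character vector of aligned sequences, or a
#'   `codon_alignment`.
#' @return List with elements `S` and `Eta`.
#' @export
segregating_sites <- function(seqs) {
  m <- .seq_matrix(seqs)
  .check_n(m)
  S <- 0L; Eta <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col) < 2L) next
    nb <- length(unique(col))
    if (nb >= 2L) {
      S <- S + 1L
      Eta <- Eta + (nb - 1L)
    }
  }
  list(S = S, Eta = Eta)
}

#' Average pairwise differences and nucleotide diversity
#'
#' `k` is the mean, over all unordered sequence pairs, of the number of
#' sites at which the two sequences differ and both carry a non-gap base.
#' `Pi` is the mean over pairs of that count divided by the number of
#' sites the pair can be compared at, i.e. per-site nucleotide diversity
#' under pairwise deletion. On gap-free data `Pi = k / length` exactly.
#'
#' @inheritParams segregating_sites
#' @return List with elements `k` and `Pi`.
#' @export
nucleotide_diversity <- function(seqs) {
  m <- .seq_matrix(seqs)
  .check_n(m)
  n <- nrow(m)
  diffs <- 0; pis <- 0; npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      nd <- sum(m[i, ok] != m[j, ok])
      diffs <- diffs + nd
      if (sum(ok) > 0L) pis <- pis + nd / sum(ok)
      npair <- npair + 1L
    }
  }
  list(k = diffs / npair, Pi = pis / npair)
}

#' Mean amino-acid p-distance
#'
#' Mean over all unordered pairs of (differing residues / compared
#' residues), with pairwise deletion of positions where either sequence
#' carries a gap or a stop. Pairs with no comparable residues are skipped
#' with a warning.
#'
#' @param paln A `protein_alignment` or named character vector of aligned
#'   amino-acid sequences.
#' @return Mean p-distance (numeric scalar).
#' @export
aa_p_distance <- function(paln) {
  aa <- if (inherits(paln, "protein_alignment")) paln$aa else paln
  m <- do.call(rbind, strsplit(toupper(unname(aa)), ""))
  .check_n(m)
  n <- nrow(m)
  total <- 0; npair <- 0L; skipped <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !(m[i, ] %in% c("-", "*")) & !(m[j, ] %in% c("-", "*"))
      if (sum(ok) == 0L) { skipped <- skipped + 1L; next }
      total <- total + sum(m[i, ok] != m[j, ok]) / sum(ok)
      npair <- npair + 1L
    }
  }
  if (skipped > 0L) {
    warning(skipped, " pair(s) had no comparable residues and were skipped")
  }
  total / npair
}

#' Mean pairwise percent identity
#'
#' Mean over all unordered pairs of 100 x (identical columns / scored
#' columns), where a column is scored for a pair when at least one of the
#' two sequences has a non-gap base; a gap aligned to a base counts as a
#' mismatch, and gap-gap columns are excluded.
#'
#' @inheritParams segregating_sites
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(seqs) {
  m <- .seq_matrix(seqs)
  .check_n(m)
  n <- nrow(m)
  total <- 0; npair <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      scored <- !(m[i, ] == "-" & m[j, ] == "-")
      ident <- sum(m[i, scored] == m[j, scored] & m[i, scored] != "-")
      total <- total + 100 * ident / sum(scored)
      npair <- npair + 1L
    }
  }
  total / npair
}

#' All polymorphism statistics for one alignment
#'
#' Convenience wrapper computing the full diversity panel for an aligned
#' allele set: sample size, alignment length, segregating sites, total
#' mutations, mean pairwise differences, nucleotide diversity, mean
#' amino-acid p-distance of the in-frame translation, and mean pairwise
#' percent identity.
#'
#' @param seqs Named character vector of aligned nucleotide sequences.
#' @param frame Reading frame used for the protein-level statistics.
#' @param name Row label.
#' @return One-row data frame.
#' @export
diversity_stats <- function(seqs, frame = 1L, name = NA_character_) {
  seg <- segregating_sites(seqs)
  nd <- nucleotide_diversity(seqs)
  aln <- codon_alignment(seqs, frame = frame)
  aap <- aa_p_distance(translate_codons(aln))
  data.frame(
    name = name,
    n_seqs = length(seqs),
    n_nucleotides = unique(nchar(seqs)),
    S = seg$S, Eta = seg$Eta,
    k = nd$k, Pi = nd$Pi,
    aa_p_distance = aap,
    pairwise_identity_pct = pairwise_identity(seqs))
}
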