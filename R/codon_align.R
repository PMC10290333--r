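#' Build an in-frame codon alignment
#'
#' Applies a reading frame to an aligned set of nucleotide sequences:
#' frame `f` drops the leading `f - 1` alignment columns, and any trailing
#' remainder shorter than a codon is trimmed. The trim is recorded on the
#' returned object. Only `A`, `C`, `G`, `T` and the gap character `-` are
#' accepted; ambiguity codes are rejected so that downstream pathway
#' counting never has to guess a base.
#'
#' @param seqs Named character vector of equal-length aligned sequences.
#' @param frame Reading frame, 1, 2 or 3 (number of leading bases skipped
#'   is `frame - 1`).
#' @param name Optional free-text label for the alignment.
#' @return An object of class `codon_alignment` with elements `ids`,
#'   `seqs` (trimmed), `codons` (sequences x codon columns character
#'   matrix), `frame`, `n_codons`, `trim` (leading/trailing columns
#'   dropped) and `name`.
#' @export
codon_alignment <- function(seqs, frame = 1L, name = NULL) {
  frame <- as.integer(frame)
  if (!frame %in% 1:3) stop("frame must be 1, 2 or 3")
  if (length(seqs) < 1L) stop("empty sequence set")
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("sequences must be named")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(seqs)
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("sequences are not all the same length")
  bad <- unique(unlist(strsplit(gsub("[ACGT-]", "", seqs), "")))
  if (length(bad) > 0L) {
    stop("disallowed characters in sequences: ", paste(bad, collapse = ", "))
  }
  lead <- frame - 1L
  usable <- len - lead
  if (usable < 3L) stop("alignment too short for frame ", frame)
  tail_trim <- usable %% 3L
  n_codons <- usable %/% 3L
  trimmed <- substr(seqs, lead + 1L, lead + 3L * n_codons)
  codons <- matrix("", length(seqs), n_codons,
                   dimnames = list(ids, NULL))
  for (k in seq_len(n_codons)) {
    codons[, k] <- substr(trimmed, 3L * k - 2L, 3L * k)
  }
  structure(
    list(ids = ids, seqs = stats::setNames(trimmed, ids), codons = codons,
         frame = frame, n_codons = n_codons,
         trim = c(leading = lead, trailing = tail_trim),
         name = name),
    class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment", if (!is.null(x$name)) sQuote(x$name), "\n")
  cat(" ", length(x$ids), "sequences x", x$n_codons, "codons (frame",
      paste0(x$frame, ";"), "trimmed", x$trim["leading"], "leading,",
      x$trim["trailing"], "trailing columns)\n")
  invisible(x)
}

#' Translate a codon alignment
#'
#' Standard genetic code. A codon containing any gap character translates
#' to `-`; stop codons translate to `*`. Translation never errors: gaps
#' and stops are encoded, not raised.
#'
#' @param aln A `codon_alignment`.
#' @return An object of class `protein_alignment` with elements `ids`,
#'   `aa` (named character vector of aligned amino-acid strings),
#'   `n_sites` and `frame`.
#' @export
translate_codons <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  idx <- match(aln$codons, .CODONS)
  aa <- ifelse(is.na(idx), "-", .AA[idx])
  aam <- matrix(aa, nrow(aln$codons))
  seqs <- apply(aam, 1, paste, collapse = "")
  structure(
    list(ids = aln$ids, aa = stats::setNames(seqs, aln$ids),
         n_sites = aln$n_codons, frame = aln$frame),
    class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", length(x$ids), "sequences x", x$n_sites,
      "residues\n")
  invisible(x)
}

#' Classify codon-position degeneracy
#'
#' For a sense codon, classifies each of the three positions as 4-fold
#' degenerate (every single-base alternative is synonymous), 0-fold (none
#' is), or 2-fold (some but not all). Changes to stop codons count as
#' nonsynonymous alternatives. These are the L0/L2/L4 site classes consumed
#' by the Pamilo-Bianchi-Li distance.
#'
#' @param codon A single 3-letter codon string.
#' @return Integer vector of length 3 with values in `c(0, 2, 4)`.
#' @export
classify_degeneracy <- function(codon) {
  i <- match(toupper(codon), .CODONS)
  if (is.na(i)) stop("not a valid codon: ", codon)
  if (!.IS_SENSE[i]) stop("stop codon has no degeneracy classes: ", codon)
  .DEG[i, ]
}

.aa_matrix <- function(paln) {
  do.call(rbind, strsplit(unname(paln$aa), ""))
}

#' Map alignment columns to a reference residue numbering
#'
#' Aligns an ungapped reference amino-acid fragment to the column-wise
#' consensus of a protein alignment by global alignment (match = 1,
#' mismatch = 0, gap = -1) and assigns each reference-aligned column the
#' reference number of the residue it pairs with. Columns pairing with a
#' gap in the reference are flagged unmapped. This realizes the convention
#' of numbering MHC residues against a structural reference such as HLA-A2
#' or HLA-DRB1.
#'
#' @param paln A `protein_alignment`.
#' @param reference_aa Ungapped reference amino-acid string.
#' @param reference_start Reference number of the first reference residue.
#' @param numbering_id Label for the numbering system (e.g. "HLA-A2").
#' @return A `site_map`: data frame with columns `column` (1-based codon
#'   column) and `ref_position` (integer, `NA` for unmapped columns), with
#'   attributes `numbering_id` and `identity` (fraction of reference
#'   residues placed on an identical consensus residue).
#' @export
build_site_map <- function(paln, reference_aa, reference_start = 1L,
                           numbering_id = "reference") {
  stopifnot(inherits(paln, "protein_alignment"))
  reference_aa <- toupper(gsub("[-*]", "", reference_aa))
  if (nchar(reference_aa) < 1L) stop("empty reference sequence")
  aam <- .aa_matrix(paln)
  consensus <- apply(aam, 2, function(col) {
    col <- col[!col %in% c("-", "*")]
    if (length(col) == 0L) return("X")
    tt <- sort(table(col), decreasing = TRUE)
    names(tt)[1]
  })
  cons <- paste(consensus, collapse = "")
  letters_all <- unique(c(strsplit(reference_aa, "")[[1]],
                          strsplit(cons, "")[[1]], "X"))
  sm <- matrix(0, length(letters_all), length(letters_all),
               dimnames = list(letters_all, letters_all))
  diag(sm) <- 1
  pw <- Biostrings::pairwiseAlignment(
    pattern = reference_aa, subject = cons, type = "global",
    substitutionMatrix = sm, gapOpening = 0, gapExtension = 1)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pw)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pw)), "")[[1]]
  ref_positions <- rep(NA_integer_, nchar(cons))
  ref_count <- 0L
  col_count <- 0L
  placed <- 0L
  for (k in seq_along(ap)) {
    ref_here <- ap[k] != "-"
    col_here <- as[k] != "-"
    if (col_here) col_count <- col_count + 1L
    if (ref_here) ref_count <- ref_count + 1L
    if (ref_here && col_here) {
      ref_positions[col_count] <- reference_start + ref_count - 1L
      # a residue counts as placed when it matches the consensus or any
      # aligned sequence at that column
      if (ap[k] == as[k] || ap[k] %in% aam[, col_count]) {
        placed <- placed + 1L
      }
    }
  }
  identity <- placed / nchar(reference_aa)
  if (identity < 0.5) {
    stop("unreliable mapping: only ", round(100 * identity, 1),
         "% of reference residues placed on matching alignment residues")
  }
  structure(
    data.frame(column = seq_len(nchar(cons)), ref_position = ref_positions),
    numbering_id = numbering_id, identity = identity,
    class = c("site_map", "data.frame"))
}

#' Define a site mask in reference numbering
#'
#' @param name Mask label (e.g. "Human PBR", "PSS").
#' @param numbering_id Numbering system the positions refer to.
#' @param positions Integer positions; duplicates are removed.
#' @return A `site_mask` object.
#' @export
site_mask <- function(name, numbering_id, positions) {
  positions <- sort(unique(as.integer(positions)))
  if (anyNA(positions)) stop("positions must be integers")
  structure(list(name = name, numbering_id = numbering_id,
                 positions = positions),
            class = "site_mask")
}

#' @export
print.site_mask <- function(x, ...) {
  cat("site_mask", sQuote(x$name), "in", x$numbering_id, "numbering:",
      length(x$positions), "positions\n")
  invisible(x)
}

#' Read a site mask from a text file
#'
#' Two formats are accepted: a two-column TSV with columns
#' `numbering_id` and `position`, or a one-position-per-line file whose
#' first line is a header of the form `numbering=<id>`.
#'
#' @param path Path to the mask file.
#' @param name Mask label; defaults to the file name.
#' @return A `site_mask`.
#' @export
read_site_mask <- function(path, name = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mask file: ", path)
  first <- trimws(lines[1])
  if (grepl("numbering\\s*=", first)) {
    numbering <- trimws(sub(".*numbering\\s*=\\s*", "", first))
    positions <- as.integer(trimws(lines[-1]))
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("numbering_id", "position") %in% names(df))) {
      stop("mask TSV must have columns numbering_id, position")
    }
    numbering <- unique(df$numbering_id)
    if (length(numbering) != 1L) stop("mixed numbering ids in ", path)
    positions <- as.integer(df$position)
  }
  site_mask(name, numbering, positions)
}

#' Resolve a site mask to codon columns
#'
#' @param map A `site_map`.
#' @param mask A `site_mask` or an integer vector of reference positions.
#' @return Sorted integer vector of 1-based codon columns. Positions not
#'   represented in the map are dropped with a warning.
#' @export
resolve_mask <- function(map, mask) {
  stopifnot(inherits(map, "site_map"))
  positions <- if (inherits(mask, "site_mask")) mask$positions
               else sort(unique(as.integer(mask)))
  hit <- match(positions, map$ref_position)
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " mask position(s) not present in the site map")
  }
  sort(map$column[hit[!is.na(hit)]])
}

#' Concatenate two codon alignments column-wise
#'
#' Appends the codon columns of `b` to those of `a`, pairing sequences by
#' an explicit pairing table. Used to analyze a composite peptide-binding
#' groove (e.g. class II alpha-1 + beta-1 domains) as one alignment.
#'
#' @param a,b `codon_alignment` objects.
#' @param pairing Data frame with columns `id_a`, `id_b` and optionally
#'   `id` (output label; defaults to `id_a`-`id_b`).
#' @return A `codon_alignment` with `frame = 1` and no trimming.
#' @export
concat_alignments <- function(a, b, pairing) {
  stopifnot(inherits(a, "codon_alignment"), inherits(b, "codon_alignment"))
  stopifnot(all(c("id_a", "id_b") %in% names(pairing)))
  ia <- match(pairing$id_a, a$ids)
  ib <- match(pairing$id_b, b$ids)
  if (anyNA(ia) || anyNA(ib)) stop("pairing refers to unknown ids")
  out_ids <- if ("id" %in% names(pairing)) pairing$id
             else paste(pairing$id_a, pairing$id_b, sep = "-")
  seqs <- stats::setNames(
    paste0(unname(a$seqs)[ia], unname(b$seqs)[ib]), out_ids)
  codon_alignment(seqs, frame = 1L,
                  name = paste(a$name %||% "a", b$name %||% "b", sep = "+"))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
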