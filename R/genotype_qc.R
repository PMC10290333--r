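# Amplicon-genotype quality control: read-count filtering, replicate
# reproducibility, allele validation against conserved anchor residues,
# transcript expression cross-check, and genotype summaries.

.check_genotype_table <- function(table) {
  need <- c("individual", "replicate", "amplicon", "allele", "reads")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop("genotype table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(table) == 0L) stop("empty genotype table")
  if (any(table$reads < 0)) stop("negative read counts")
  key <- paste(table$individual, table$replicate, table$amplicon,
               table$allele, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (individual, replicate, amplicon, allele) rows")
  }
  invisible(table)
}

#' Read a genotype table from TSV
#'
#' Expected header: `individual`, `replicate`, `amplicon`, `allele`,
#' `reads`.
#'
#' @param path Path to a tab-separated file.
#' @return Data frame (validated).
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_genotype_table(tab)
}

#' Filter amplicon genotypes by read depth and flag oversized genotypes
#'
#' A sample is one (individual, replicate, amplicon) combination. Samples
#' whose total reads fall below `min_reads` are removed. Samples carrying
#' more than `max_alleles` alleles are kept but flagged in the log:
#' genotypes exceeding the expected locus-derived allele cap warrant
#' scrutiny (e.g. for copy-number variation) but are not discarded
#' automatically.
#'
#' @param table Genotype data frame (see [read_genotype_table()]).
#' @param min_reads Minimum total reads per sample (default 100).
#' @param max_alleles Allele-count cap used for flagging (default 6).
#' @return List with `kept` (filtered table), `removed` (rows of removed
#'   samples), and `log` (one row per sample: totals, allele counts,
#'   `removed` and `flagged` indicators).
#' @export
filter_genotypes <- function(table, min_reads = 100, max_alleles = 6) {
  .check_genotype_table(table)
  if (min_reads < 0) stop("min_reads must be >= 0")
  key <- paste(table$individual, table$replicate, table$amplicon, sep = "\r")
  totals <- tapply(table$reads, key, sum)
  counts <- tapply(table$allele, key, function(a) length(unique(a)))
  ukey <- names(totals)
  parts <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  log <- data.frame(
    individual = parts[, 1], replicate = parts[, 2], amplicon = parts[, 3],
    total_reads = as.vector(totals), n_alleles = as.vector(counts),
    removed = as.vector(totals) < min_reads,
    flagged = as.vector(counts) > max_alleles,
    stringsAsFactors = FALSE)
  keep_keys <- ukey[!log$removed]
  list(kept = table[key %in% keep_keys, , drop = FALSE],
       removed = table[!(key %in% keep_keys), , drop = FALSE],
       log = log)
}

#' Percent reproducibility between two technical replicates
#'
#' `100 * 2 |A intersect B| / (|A| + |B|)` on the two allele sets.
#'
#' @param alleles_rep1,alleles_rep2 Character vectors of allele ids.
#' @return Percent in `[0, 100]`.
#' @export
replicate_reproducibility <- function(alleles_rep1, alleles_rep2) {
  a <- unique(alleles_rep1); b <- unique(alleles_rep2)
  if (length(a) == 0L || length(b) == 0L) stop("empty replicate allele set")
  100 * 2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Mean replicate reproducibility across a genotype table
#'
#' For every individual/amplicon with two or more replicates, computes
#' [replicate_reproducibility()] for each replicate pair and returns the
#' mean over pairs, plus the per-pair table.
#'
#' @param table Genotype data frame.
#' @return List with `mean` and `pairs` (data frame).
#' @export
mean_reproducibility <- function(table) {
  .check_genotype_table(table)
  key <- paste(table$individual, table$amplicon, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- table[key == k, , drop = FALSE]
    reps <- unique(sub$replicate)
    if (length(reps) < 2L) next
    pr <- utils::combn(reps, 2L)
    for (c in seq_len(ncol(pr))) {
      r <- replicate_reproducibility(
        sub$allele[sub$replicate == pr[1, c]],
        sub$allele[sub$replicate == pr[2, c]])
      out[[length(out) + 1L]] <- data.frame(
        individual = sub$individual[1], amplicon = sub$amplicon[1],
        rep1 = pr[1, c], rep2 = pr[2, c], reproducibility = r,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop("no replicated samples in table")
  pairs <- do.call(rbind, out)
  list(mean = mean(pairs$reproducibility), pairs = pairs)
}

#' Anchor-residue specification
#'
#' Describes the conserved positions (in a reference numbering) that an
#' allele's translation is validated against, e.g. the peptide-terminus
#' anchors of classical class I molecules.
#'
#' @param numbering_id Numbering system of the positions.
#' @param positions Integer reference positions.
#' @param required Required residue per position (single letters).
#' @param tolerated Optional list (one element per position) of additional
#'   residues accepted as functionally conservative.
#' @return An `anchor_spec`.
#' @export
anchor_spec <- function(numbering_id, positions, required,
                        tolerated = NULL) {
  positions <- as.integer(positions)
  stopifnot(length(positions) == length(required))
  if (is.null(tolerated)) tolerated <- rep(list(character(0)),
                                           length(positions))
  stopifnot(length(tolerated) == length(positions))
  structure(list(numbering_id = numbering_id, positions = positions,
                 required = toupper(required),
                 tolerated = lapply(tolerated, toupper)),
            class = "anchor_spec")
}

#' Validate an allele against stop codons and anchor residues
#'
#' Translates the allele in the stated frame, records whether any stop
#' codon is present, and compares the residue at each anchor position
#' (resolved through a `site_map`) with the required residue. Residues in
#' the tolerated set are reported as `"tolerated"`; positions absent from
#' the map are `"unmapped"`. All findings are report fields; nothing is
#' raised.
#'
#' @param allele_seq Nucleotide sequence (may contain gaps).
#' @param frame Reading frame (1-3).
#' @param spec An [anchor_spec()].
#' @param map A `site_map` from the allele set's protein alignment to the
#'   anchor numbering.
#' @param allele_id Optional id recorded on the report.
#' @return A `validation_report`: list with `allele`, `frame`,
#'   `has_stop`, and `anchors` (data frame: position, required, observed,
#'   status).
#' @export
validate_allele <- function(allele_seq, frame, spec, map,
                            allele_id = NA_character_) {
  stopifnot(inherits(spec, "anchor_spec"), inherits(map, "site_map"))
  aln <- codon_alignment(stats::setNames(allele_seq, "allele"),
                         frame = frame)
  aa <- strsplit(unname(translate_codons(aln)$aa), "")[[1]]
  status <- character(length(spec$positions))
  observed <- character(length(spec$positions))
  for (i in seq_along(spec$positions)) {
    col <- map$column[match(spec$positions[i], map$ref_position)]
    if (is.na(col) || col > length(aa)) {
      status[i] <- "unmapped"; observed[i] <- NA_character_
      next
    }
    observed[i] <- aa[col]
    status[i] <- if (observed[i] == spec$required[i]) "match"
      else if (observed[i] %in% spec$tolerated[[i]]) "tolerated"
      else "mismatch"
  }
  structure(
    list(allele = allele_id, frame = frame,
         has_stop = any(aa == "*"),
         anchors = data.frame(position = spec$positions,
                              required = spec$required,
                              observed = observed, status = status,
                              stringsAsFactors = FALSE)),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("allele validation:", x$allele, "(frame", paste0(x$frame, ")"),
      if (x$has_stop) "- CONTAINS STOP" else "- no stops", "\n")
  print(x$anchors, row.names = FALSE)
  invisible(x)
}

#' Expression cross-check of alleles against transcripts
#'
#' An allele counts as expressed when its full ungapped nucleotide
#' sequence occurs exactly (100% identity over the whole allele) as a
#' substring of any transcript or of its reverse complement.
#'
#' @param alleles Named character vector of allele sequences.
#' @param transcripts Named character vector of transcript sequences.
#' @return Named logical vector, one element per allele.
#' @export
expression_crosscheck <- function(alleles, transcripts) {
  if (length(transcripts) == 0L) stop("empty transcript set")
  tx <- toupper(unname(transcripts))
  tx_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(tx)))
  haystack <- c(tx, tx_rc)
  query <- gsub("-", "", toupper(alleles))
  vapply(query, function(q) {
    any(vapply(haystack, function(h) grepl(q, h, fixed = TRUE), logical(1)))
  }, logical(1), USE.NAMES = TRUE)
}

#' Per-allele carrier frequencies and per-individual allele counts
#'
#' Replicates are collapsed to one genotype per individual by set union,
#' then carrier proportion (individuals carrying / individuals genotyped)
#' is reported per allele, along with the distribution and mean of
#' per-individual allele counts.
#'
#' @param table Genotype data frame (typically the `kept` part of
#'   [filter_genotypes()]).
#' @return List with `carriers` (data frame: allele, n_carriers,
#'   proportion), `per_individual` (data frame: individual, n_alleles),
#'   `mean_alleles`, `range_alleles`, `n_individuals`.
#' @export
allele_summary <- function(table) {
  .check_genotype_table(table)
  geno <- unique(table[, c("individual", "allele")])
  inds <- unique(geno$individual)
  counts <- as.vector(table(factor(geno$individual, levels = inds)))
  carrier_n <- table(geno$allele)
  carriers <- data.frame(
    allele = names(carrier_n),
    n_carriers = as.vector(carrier_n),
    proportion = as.vector(carrier_n) / length(inds),
    stringsAsFactors = FALSE)
  carriers <- carriers[order(-carriers$proportion, carriers$allele), ]
  list(carriers = carriers,
       per_individual = data.frame(individual = inds, n_alleles = counts,
                                   stringsAsFactors = FALSE),
       mean_alleles = mean(counts),
       range_alleles = range(counts),
       n_individuals = length(inds))
}
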