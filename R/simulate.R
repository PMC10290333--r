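# Seeded simulators for the two input classes the analyses consume:
# codon alignments evolved under site-specific selection, and multi-locus
# amplicon genotype datasets with technical replicates, read counts and
# partial transcript expression. Truth records make planted structure
# recoverable in tests.

.random_sense_codons <- function(n) {
  sense <- which(.IS_SENSE)
  .CODONS[sample(sense, n, replace = TRUE)]
}

.propose_base <- function(base, kappa) {
  # single-base proposal with transition weighted kappa : 1 : 1
  partners <- setdiff(.BASES, base)
  w <- ifelse(.is_transition(base, partners), kappa, 1)
  sample(partners, 1L, prob = w)
}

#' Simulate a codon alignment under site-specific selection
#'
#' Alleles evolve independently from a common root (star genealogy): a
#' uniform-random sense-codon root sequence is perturbed by single-base
#' proposals (transitions weighted by `kappa`); proposals creating stop
#' codons are rejected, nonsynonymous proposals are accepted with
#' probability `min(1, omega)` and synonymous proposals with probability
#' `min(1, 1/omega)` of the proposal's codon site (`omega_mask` on
#' masked codons, `omega_background` elsewhere), so the acceptance-rate
#' ratio of nonsynonymous to synonymous change equals omega on both
#' sides of 1. Each branch accumulates synonymous
#' substitutions until it reaches half the target expected pairwise
#' synonymous divergence, so pairs of alleles sit at the configured dS
#' scale.
#'
#' @param n_alleles Number of alleles to simulate.
#' @param n_codons Codons per allele.
#' @param mask Integer codon positions under `omega_mask` selection.
#' @param omega_mask,omega_background Nonsynonymous acceptance ratios.
#' @param kappa Transition/transversion rate ratio.
#' @param syn_divergence Target expected pairwise synonymous divergence
#'   (synonymous substitutions per synonymous site between two alleles).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param name Alignment label.
#' @return List with `alignment` (a `codon_alignment`) and `truth`
#'   (root sequence, mask, per-allele realized substitution counts,
#'   config echo).
#' @export
simulate_codon_alignment <- function(n_alleles, n_codons, mask = integer(0),
                                     omega_mask = 6, omega_background = 1,
                                     kappa = 2, syn_divergence = 0.15,
                                     seed = 1L, name = "simulated") {
  stopifnot(n_alleles >= 2, n_codons >= 2,
            omega_mask > 0, omega_background > 0, kappa > 0,
            syn_divergence >= 0)
  mask <- sort(unique(as.integer(mask)))
  if (length(mask) > 0 && (min(mask) < 1 || max(mask) > n_codons)) {
    stop("mask must be a subset of codon indices")
  }
  omega_site <- rep(omega_background, n_codons)
  omega_site[mask] <- omega_mask
  if (syn_divergence / 2 > 3) {
    stop("target synonymous divergence unattainable (saturation): more ",
         "than 3 substitutions per synonymous site per branch")
  }
  .with_seed(seed, {
    root <- .random_sense_codons(n_codons)
    syn_sites_root <- sum(.NG_S[match(root, .CODONS)])
    branch_target <- syn_divergence / 2
    max_proposals <- 1000L * n_codons
    seqs <- character(n_alleles)
    syn_counts <- integer(n_alleles)
    nonsyn_counts <- integer(n_alleles)
    for (al in seq_len(n_alleles)) {
      cod <- root
      syn_done <- 0L
      nonsyn_done <- 0L
      proposals <- 0L
      while (syn_done / syn_sites_root < branch_target) {
        proposals <- proposals + 1L
        if (proposals > max_proposals) {
          stop("target synonymous divergence unattainable (saturation)")
        }
        site <- sample.int(n_codons, 1L)
        pos <- sample.int(3L, 1L)
        chars <- strsplit(cod[site], "")[[1]]
        newb <- .propose_base(chars[pos], kappa)
        chars2 <- chars; chars2[pos] <- newb
        newcod <- paste(chars2, collapse = "")
        i_old <- match(cod[site], .CODONS)
        i_new <- match(newcod, .CODONS)
        if (!.IS_SENSE[i_new]) next
        if (.AA[i_old] == .AA[i_new]) {
          if (stats::runif(1) < min(1, 1 / omega_site[site])) {
            cod[site] <- newcod
            syn_done <- syn_done + 1L
          }
        } else if (stats::runif(1) < min(1, omega_site[site])) {
          cod[site] <- newcod
          nonsyn_done <- nonsyn_done + 1L
        }
      }
      seqs[al] <- paste(cod, collapse = "")
      syn_counts[al] <- syn_done
      nonsyn_counts[al] <- nonsyn_done
    }
    ids <- sprintf("allele%03d", seq_len(n_alleles))
    aln <- codon_alignment(stats::setNames(seqs, ids), frame = 1L,
                           name = name)
    list(alignment = aln,
         truth = list(root = paste(root, collapse = ""), mask = mask,
                      omega_mask = omega_mask,
                      omega_background = omega_background,
                      kappa = kappa, syn_divergence = syn_divergence,
                      syn_substitutions = syn_counts,
                      nonsyn_substitutions = nonsyn_counts,
                      seed = as.integer(seed)))
  })
}

.random_allele_pool <- function(locus, pool_size, n_codons) {
  root <- .random_sense_codons(n_codons)
  seqs <- character(pool_size)
  for (k in seq_len(pool_size)) {
    cod <- root
    n_mut <- stats::rpois(1, lambda = 0.08 * n_codons) + 1L
    for (mm in seq_len(n_mut)) {
      repeat {
        site <- sample.int(n_codons, 1L)
        pos <- sample.int(3L, 1L)
        chars <- strsplit(cod[site], "")[[1]]
        chars[pos] <- sample(setdiff(.BASES, chars[pos]), 1L)
        newcod <- paste(chars, collapse = "")
        if (.IS_SENSE[match(newcod, .CODONS)]) {
          cod[site] <- newcod
          break
        }
      }
    }
    seqs[k] <- paste(cod, collapse = "")
  }
  stats::setNames(seqs, sprintf("L%d-A%02d", locus, seq_len(pool_size)))
}

.skewed_freqs <- function(pool_size, skewed) {
  if (!skewed) return(rep(1 / pool_size, pool_size))
  # one near-fixed allele, the rest geometric-ish
  w <- c(pool_size, 0.8^(seq_len(pool_size - 1)))
  w / sum(w)
}

#' Simulate a multi-locus amplicon genotype dataset
#'
#' Per individual, two alleles per locus are drawn from the locus pool
#' (homozygosity allowed), with an optional extra locus appearing with
#' probability `cnv_prob`; the genotype is the union of the drawn alleles
#' within one amplicon. Read counts per allele are negative-binomial; a
#' fraction of individuals receives a second technical replicate with
#' independent per-allele dropout; a planted fraction of individuals'
#' total reads is scaled below a read threshold to emulate failed
#' amplifications; and a planted subset of the allele pool is expressed,
#' emitted as transcripts embedding the allele sequence in random flanks.
#'
#' @param n_individuals Individuals genotyped.
#' @param n_loci Loci amplified in the single amplicon.
#' @param pool_size Alleles per locus pool.
#' @param n_codons Codons per allele sequence.
#' @param skewed_freqs If `TRUE`, one allele of locus 1 is near-fixed and
#'   the remaining frequencies decay geometrically; otherwise uniform.
#' @param cnv_prob Probability that an individual carries an extra locus.
#' @param replicate_fraction Fraction of individuals with a technical
#'   replicate.
#' @param dropout Per-allele, per-replicate dropout probability.
#' @param read_mean,read_dispersion Negative-binomial mean (per sample)
#'   and dispersion for read counts.
#' @param expressed_fraction Fraction of the allele pool planted as
#'   expressed.
#' @param n_low_read Number of individuals whose total reads are scaled
#'   into `[10, 99]` to fall below a 100-read genotyping threshold.
#' @param seed Integer seed.
#' @return List with `table` (genotype data frame), `alleles` (named
#'   character vector), `transcripts` (named character vector) and
#'   `truth` (genotypes, CNV individuals, expressed set, low-read
#'   individuals, config echo).
#' @export
simulate_genotype_dataset <- function(n_individuals = 113, n_loci = 3,
                                      pool_size = 30, n_codons = 87,
                                      skewed_freqs = TRUE, cnv_prob = 0.03,
                                      replicate_fraction = 0.575,
                                      dropout = 0.02,
                                      read_mean = 1900,
                                      read_dispersion = 2,
                                      expressed_fraction = 0.35,
                                      n_low_read = 0, seed = 1L) {
  stopifnot(n_individuals >= 1, n_loci >= 1, pool_size >= 1,
            cnv_prob >= 0, cnv_prob <= 1,
            replicate_fraction >= 0, replicate_fraction <= 1,
            dropout >= 0, dropout <= 1,
            expressed_fraction >= 0, expressed_fraction <= 1,
            n_low_read >= 0, n_low_read <= n_individuals)
  .with_seed(seed, {
    pools <- lapply(seq_len(n_loci), .random_allele_pool,
                    pool_size = pool_size, n_codons = n_codons)
    alleles <- do.call(c, pools)
    freqs <- lapply(seq_len(n_loci), function(l) {
      .skewed_freqs(pool_size, skewed_freqs && l == 1L)
    })
    inds <- sprintf("ID-%03d", seq_len(n_individuals))
    cnv <- stats::runif(n_individuals) < cnv_prob
    low_read <- rep(FALSE, n_individuals)
    if (n_low_read > 0) {
      low_read[sample.int(n_individuals, n_low_read)] <- TRUE
    }
    genotypes <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      drawn <- character(0)
      for (l in seq_len(n_loci)) {
        drawn <- c(drawn, sample(names(pools[[l]]), 2L, replace = TRUE,
                                 prob = freqs[[l]]))
      }
      if (cnv[i]) {
        l <- sample.int(n_loci, 1L)
        drawn <- c(drawn, sample(names(pools[[l]]), 2L, replace = TRUE,
                                 prob = freqs[[l]]))
      }
      genotypes[[i]] <- sort(unique(drawn))
    }
    has_rep <- stats::runif(n_individuals) < replicate_fraction
    rows <- list()
    for (i in seq_len(n_individuals)) {
      g <- genotypes[[i]]
      for (rep_id in if (has_rep[i]) c("R1", "R2") else "R1") {
        present <- g[stats::runif(length(g)) >= dropout]
        if (length(present) == 0L) present <- sample(g, 1L)
        reads <- pmax(1L, stats::rnbinom(length(present),
                                         mu = read_mean / length(present),
                                         size = read_dispersion))
        if (low_read[i]) {
          total_target <- sample(10:99, 1L)
          reads <- pmax(1L, floor(reads * total_target / sum(reads)))
          while (sum(reads) >= 100L) reads[which.max(reads)] <-
              reads[which.max(reads)] - 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          individual = inds[i], replicate = rep_id, amplicon = "amp1",
          allele = present, reads = as.integer(reads),
          stringsAsFactors = FALSE)
      }
    }
    table <- do.call(rbind, rows)
    rownames(table) <- NULL
    n_expr <- round(expressed_fraction * length(alleles))
    expressed <- sort(sample(names(alleles), n_expr))
    transcripts <- vapply(expressed, function(id) {
      flank5 <- paste(sample(.BASES, 30, replace = TRUE), collapse = "")
      flank3 <- paste(sample(.BASES, 30, replace = TRUE), collapse = "")
      paste0(flank5, alleles[[id]], flank3)
    }, character(1))
    names(transcripts) <- paste0("tx-", expressed)
    list(table = table, alleles = alleles, transcripts = transcripts,
         truth = list(genotypes = stats::setNames(genotypes, inds),
                      cnv_individuals = inds[cnv],
                      expressed = expressed,
                      low_read_individuals = inds[low_read],
                      replicated_individuals = inds[has_rep],
                      seed = as.integer(seed)))
  })
}
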