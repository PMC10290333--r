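# Pairwise dN/dS by two distance methods with codon-bootstrap variance and
# the one-tailed Z-test of positive selection. Both methods use pairwise
# deletion: a codon column enters a pair's comparison only when both
# sequences carry a sense codon (no gap, not a stop) there.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Nei-Gojobori synonymous and nonsynonymous site counts of a codon
#'
#' At each of the three positions, the synonymous site fraction is the
#' number of synonymous single-base alternatives divided by the number of
#' alternatives that do not create a stop codon; `n = 3 - s`.
#'
#' @param codon A single sense codon string.
#' @return List with elements `s` and `n`.
#' @export
ng86_sites <- function(codon) {
  i <- match(toupper(codon), .CODONS)
  if (is.na(i)) stop("not a valid codon: ", codon)
  if (!.IS_SENSE[i]) stop("stop codon: ", codon)
  list(s = .NG_S[i], n = 3 - .NG_S[i])
}

#' Nei-Gojobori pathway-averaged difference counts for a codon pair
#'
#' Differences at one position are classified directly; at two (three)
#' positions the synonymous/nonsynonymous counts are averaged over the
#' 2 (6) orderings of intermediate codons. Orderings passing through a
#' stop codon are excluded; if all do, every ordering is kept with
#' stop-involving steps counted as nonsynonymous.
#'
#' @param codon_a,codon_b Sense codon strings.
#' @return List with elements `sd` and `nd`.
#' @export
ng86_pair_diffs <- function(codon_a, codon_b) {
  ia <- match(toupper(codon_a), .CODONS)
  ib <- match(toupper(codon_b), .CODONS)
  if (is.na(ia) || is.na(ib)) stop("not a valid codon pair")
  if (!.IS_SENSE[ia] || !.IS_SENSE[ib]) stop("stop codon in pair")
  list(sd = .NG_SD[ia, ib], nd = .NG_ND[ia, ib])
}

.codon_index_matrix <- function(aln, cols) {
  cm <- aln$codons[, cols, drop = FALSE]
  idx <- matrix(match(cm, .CODONS), nrow(cm))
  sense <- !is.na(idx)
  sense[sense] <- .IS_SENSE[idx[sense]]
  list(idx = idx, sense = sense)
}

# Per-pair, per-column contribution arrays for the NG86 method. Rows are
# unordered sequence pairs, columns are the selected codon columns; a
# bootstrap replicate is a reweighting of the columns.
.ng86_arrays <- function(aln, cols) {
  ci <- .codon_index_matrix(aln, cols)
  n <- nrow(ci$idx)
  if (n < 2L) stop("need at least 2 sequences")
  pr <- utils::combn(n, 2L)
  Ai <- ci$idx[pr[1, ], , drop = FALSE]
  Aj <- ci$idx[pr[2, ], , drop = FALSE]
  valid <- ci$sense[pr[1, ], , drop = FALSE] &
    ci$sense[pr[2, ], , drop = FALSE]
  npair <- ncol(pr); m <- length(cols)
  SD <- ND <- SB <- NB <- matrix(0, npair, m)
  lin <- (Aj - 1L) * 64L + Ai  # element [Ai, Aj] of the 64 x 64 tables
  SD[valid] <- .NG_SD[lin[valid]]
  ND[valid] <- .NG_ND[lin[valid]]
  SB[valid] <- (.NG_S[Ai[valid]] + .NG_S[Aj[valid]]) / 2
  NB[valid] <- 3 - SB[valid]
  list(SD = SD, ND = ND, SB = SB, NB = NB, pairs = pr)
}

.jc <- function(p) {
  d <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  d[ok] <- -0.75 * log(1 - 4 * p[ok] / 3)
  d
}

# Mean dN/dS over pairs for one column weighting (NG86).
.ng86_eval <- function(arr, w) {
  Sd <- as.vector(arr$SD %*% w)
  Nd <- as.vector(arr$ND %*% w)
  Sb <- as.vector(arr$SB %*% w)
  Nb <- as.vector(arr$NB %*% w)
  pS <- ifelse(Sb > 0, Sd / Sb, NA_real_)
  pN <- ifelse(Nb > 0, Nd / Nb, NA_real_)
  dS <- .jc(pS); dN <- .jc(pN)
  ok <- !is.na(dS) & !is.na(dN)
  list(dN = mean(dN[ok]), dS = mean(dS[ok]),
       per_pair = data.frame(dN = dN, dS = dS),
       n_pairs = length(ok), n_dropped = sum(!ok))
}

# Per-pair, per-column arrays of the nine PBL tallies (L0, L2, L4 and the
# transition/transversion counts per class).
.pbl_arrays <- function(aln, cols) {
  ci <- .codon_index_matrix(aln, cols)
  n <- nrow(ci$idx)
  if (n < 2L) stop("need at least 2 sequences")
  pr <- utils::combn(n, 2L)
  Ai <- ci$idx[pr[1, ], , drop = FALSE]
  Aj <- ci$idx[pr[2, ], , drop = FALSE]
  valid <- ci$sense[pr[1, ], , drop = FALSE] &
    ci$sense[pr[2, ], , drop = FALSE]
  npair <- ncol(pr); m <- length(cols)
  arrs <- vector("list", 9L)
  lin <- (Aj - 1L) * 64L + Ai  # index into .PBL_TAB[ , , k] slabs
  for (k in 1:9) {
    slab <- .PBL_TAB[, , k]
    A <- matrix(0, npair, m)
    A[valid] <- slab[lin[valid]]
    arrs[[k]] <- A
  }
  names(arrs) <- c("L0", "L2", "L4", "P0", "P2", "P4", "Q0", "Q2", "Q4")
  arrs$pairs <- pr
  arrs
}

.k2p_AB <- function(L, Pc, Qc) {
  # K2P transitional (A) and transversional (B) distance components per
  # class; classes with no sites contribute 0. Returns NA where the log
  # argument is non-positive (saturation).
  P <- ifelse(L > 0, Pc / L, 0)
  Q <- ifelse(L > 0, Qc / L, 0)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  A <- B <- numeric(length(L))
  pos <- L > 0
  A[pos] <- NA_real_
  B[pos] <- NA_real_
  okA <- pos & w1 > 0 & w2 > 0
  okB <- pos & w2 > 0
  A[okA] <- 0.5 * log(1 / w1[okA]) - 0.25 * log(1 / w2[okA])
  B[okB] <- 0.5 * log(1 / w2[okB])
  list(A = A, B = B)
}

.pbl_eval <- function(arr, w) {
  L0 <- as.vector(arr$L0 %*% w); L2 <- as.vector(arr$L2 %*% w)
  L4 <- as.vector(arr$L4 %*% w)
  ab0 <- .k2p_AB(L0, as.vector(arr$P0 %*% w), as.vector(arr$Q0 %*% w))
  ab2 <- .k2p_AB(L2, as.vector(arr$P2 %*% w), as.vector(arr$Q2 %*% w))
  ab4 <- .k2p_AB(L4, as.vector(arr$P4 %*% w), as.vector(arr$Q4 %*% w))
  dS <- ifelse(L2 + L4 > 0,
               (L2 * ab2$A + L4 * ab4$A) / (L2 + L4) + ab4$B, NA_real_)
  dN <- ifelse(L0 + L2 > 0,
               ab0$A + (L0 * ab0$B + L2 * ab2$B) / (L0 + L2), NA_real_)
  ok <- !is.na(dS) & !is.na(dN)
  list(dN = mean(dN[ok]), dS = mean(dS[ok]),
       per_pair = data.frame(dN = dN, dS = dS),
       n_pairs = length(ok), n_dropped = sum(!ok))
}

.resolve_cols <- function(aln, mask, site_map) {
  if (is.null(mask)) return(seq_len(aln$n_codons))
  if (inherits(mask, "site_mask")) {
    if (is.null(site_map)) stop("a site_map is needed to resolve a site_mask")
    return(resolve_mask(site_map, mask))
  }
  cols <- sort(unique(as.integer(mask)))
  if (any(cols < 1L | cols > aln$n_codons)) stop("mask columns out of range")
  cols
}

.method_arrays <- function(aln, cols, method) {
  switch(method,
         "NG86-JC" = .ng86_arrays(aln, cols),
         "PBL-K2P" = .pbl_arrays(aln, cols),
         stop("unknown method: ", method))
}

.method_eval <- function(arr, w, method) {
  switch(method, "NG86-JC" = .ng86_eval(arr, w), "PBL-K2P" = .pbl_eval(arr, w))
}

#' Mean pairwise dN and dS, Nei-Gojobori with Jukes-Cantor correction
#'
#' Pathway-counted synonymous/nonsynonymous differences and site counts
#' are summed per pair over the selected codon columns (pairwise deletion
#' of columns where either codon is a gap or stop), converted to
#' proportions against the pair-averaged site counts, Jukes-Cantor
#' corrected, and averaged over pairs. Pairs whose corrected distance is
#' undefined (proportion >= 3/4) are dropped with a warning and counted.
#'
#' @param aln A `codon_alignment`.
#' @param mask `NULL` for all columns, an integer vector of codon columns,
#'   or a `site_mask` (then `site_map` is required).
#' @param site_map Optional `site_map` used to resolve `mask`.
#' @return List with `dN`, `dS`, `per_pair`, `n_pairs`, `n_dropped`.
#' @export
dnds_ng86 <- function(aln, mask = NULL, site_map = NULL) {
  cols <- .resolve_cols(aln, mask, site_map)
  arr <- .ng86_arrays(aln, cols)
  out <- .ng86_eval(arr, rep(1, length(cols)))
  if (out$n_dropped > 0L) {
    warning(out$n_dropped, " pair(s) had undefined corrected distances ",
            "and were dropped")
  }
  out
}

#' Mean pairwise dN and dS, Pamilo-Bianchi-Li (Kimura 2-parameter)
#'
#' Each compared codon position is assigned to the nondegenerate (L0),
#' twofold (L2) or fourfold (L4) class; positions whose class differs
#' between the two codons are split half-and-half. Transitions and
#' transversions are tallied per class and converted to Kimura
#' 2-parameter transitional (A) and transversional (B) components;
#' `dS = (L2 A2 + L4 A4)/(L2 + L4) + B4` and
#' `dN = A0 + (L0 B0 + L2 B2)/(L0 + L2)`, averaged over pairs. Pairs with
#' saturated (undefined) logarithms are dropped with a warning.
#'
#' @inheritParams dnds_ng86
#' @return List with `dN`, `dS`, `per_pair`, `n_pairs`, `n_dropped`.
#' @export
dnds_pbl <- function(aln, mask = NULL, site_map = NULL) {
  cols <- .resolve_cols(aln, mask, site_map)
  arr <- .pbl_arrays(aln, cols)
  out <- .pbl_eval(arr, rep(1, length(cols)))
  if (out$n_dropped > 0L) {
    warning(out$n_dropped, " pair(s) had saturated distances and were dropped")
  }
  out
}

#' Codon-bootstrap standard error of dN - dS
#'
#' Each replicate resamples the selected codon columns with replacement
#' (one resampling applied to every sequence), recomputes the mean dN and
#' dS over pairs, and the standard error is the standard deviation of
#' dN - dS across replicates. Replicates on which the means are undefined
#' (no pair with a defined distance) are dropped; more than 50% dropped is
#' an error.
#'
#' @inheritParams dnds_ng86
#' @param method `"NG86-JC"` or `"PBL-K2P"`.
#' @param reps Number of bootstrap replicates (>= 2).
#' @param seed Integer seed for the column resampling.
#' @return Standard error (numeric scalar).
#' @export
bootstrap_se <- function(aln, mask = NULL, site_map = NULL,
                         method = c("NG86-JC", "PBL-K2P"),
                         reps = 1000L, seed = 1L) {
  method <- match.arg(method)
  if (reps < 2L) stop("reps must be >= 2")
  cols <- .resolve_cols(aln, mask, site_map)
  arr <- .method_arrays(aln, cols, method)
  m <- length(cols)
  diffs <- .with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      w <- tabulate(sample.int(m, m, replace = TRUE), nbins = m)
      ev <- .method_eval(arr, w, method)
      if (is.nan(ev$dN) || is.nan(ev$dS)) NA_real_ else ev$dN - ev$dS
    }, numeric(1))
  })
  if (mean(is.na(diffs)) > 0.5) {
    stop("more than half of the bootstrap replicates were undefined")
  }
  stats::sd(diffs[!is.na(diffs)])
}

#' Codon-based Z-test of positive selection (dN > dS)
#'
#' Computes mean pairwise dN and dS over the selected codon columns,
#' estimates the standard error of dN - dS by codon bootstrap, and tests
#' `Z = (dN - dS)/SE` against the one-sided normal tail
#' `p = 1 - pnorm(Z)`. When the bootstrap SE is zero the test degenerates:
#' `Z = 0, p = 0.5` if dN equals dS, otherwise p is 0 or 1 with a warning.
#'
#' @inheritParams bootstrap_se
#' @param mask_tag Label stored on the result (e.g. "All sites",
#'   "Human PBR").
#' @return A `selection_result`: list with `mask`, `method`, `dN`, `dS`,
#'   `dnds` (`NA` when `dS` is 0), `dnds_diff`, `se`, `Z`, `p`,
#'   `n_bootstrap`, `seed`, `n_pairs`, `n_pairs_dropped`, `n_sites`.
#' @export
z_test_positive_selection <- function(aln, mask = NULL, site_map = NULL,
                                      method = c("NG86-JC", "PBL-K2P"),
                                      reps = 1000L, seed = 1L,
                                      mask_tag = NULL) {
  method <- match.arg(method)
  cols <- .resolve_cols(aln, mask, site_map)
  arr <- .method_arrays(aln, cols, method)
  pt <- .method_eval(arr, rep(1, length(cols)), method)
  if (is.nan(pt$dN) || is.nan(pt$dS)) {
    stop("point estimate undefined: no pair with defined distances")
  }
  se <- bootstrap_se(aln, mask = cols, method = method,
                     reps = reps, seed = seed)
  diff <- pt$dN - pt$dS
  if (se == 0) {
    if (isTRUE(all.equal(pt$dN, pt$dS))) {
      Z <- 0; p <- 0.5
    } else {
      Z <- sign(diff) * Inf
      p <- if (diff > 0) 0 else 1
      warning("bootstrap SE is zero with dN != dS; p degenerate")
    }
  } else {
    Z <- diff / se
    p <- 1 - stats::pnorm(Z)
  }
  if (is.null(mask_tag)) {
    mask_tag <- if (inherits(mask, "site_mask")) mask$name
                else if (is.null(mask)) "All sites" else "custom"
  }
  structure(
    list(mask = mask_tag, method = method,
         dN = pt$dN, dS = pt$dS,
         dnds = if (pt$dS == 0) NA_real_ else pt$dN / pt$dS,
         dnds_diff = diff, se = se, Z = Z, p = p,
         n_bootstrap = as.integer(reps), seed = as.integer(seed),
         n_pairs = pt$n_pairs, n_pairs_dropped = pt$n_dropped,
         n_sites = length(cols)),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Z-test of positive selection (dN > dS)\n")
  cat("  mask:", x$mask, " method:", x$method, " sites:", x$n_sites, "\n")
  cat(sprintf("  dN = %.4f  dS = %.4f  dN/dS = %s\n", x$dN, x$dS,
              ifelse(is.na(x$dnds), "NA", sprintf("%.3f", x$dnds))))
  cat(sprintf("  dN-dS = %.4f  SE = %.4f  Z = %.3f  one-sided p = %.3g\n",
              x$dnds_diff, x$se, x$Z, x$p))
  invisible(x)
}
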