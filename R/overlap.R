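# Association between two site sets (e.g. positively selected sites and
# peptide-binding residues) on a common residue numbering: Pearson
# chi-square on the 2x2 site classification, with a permutation null.

#' Pearson chi-square for a 2x2 site-overlap table
#'
#' Builds the table `[[overlap, a - overlap], [b - overlap, neither]]`
#' from the total number of sites and the two mask sizes, and returns the
#' Pearson chi-square statistic without continuity correction (expected
#' cells from the margins).
#'
#' @param n_sites Total number of amino-acid sites.
#' @param n_a,n_b Sizes of the two site sets.
#' @param n_overlap Number of sites in both sets.
#' @return Chi-square statistic (numeric scalar).
#' @export
chi_square_2x2 <- function(n_sites, n_a, n_b, n_overlap) {
  if (n_overlap > min(n_a, n_b) || n_a + n_b - n_overlap > n_sites ||
      min(n_sites, n_a, n_b, n_overlap) < 0) {
    stop("inconsistent counts")
  }
  o <- n_overlap
  tab <- c(o, n_a - o, n_b - o, n_sites - n_a - n_b + o)
  r1 <- tab[1] + tab[2]; r2 <- tab[3] + tab[4]
  c1 <- tab[1] + tab[3]; c2 <- tab[2] + tab[4]
  if (min(r1, r2, c1, c2) == 0) stop("degenerate table: a margin is zero")
  n_sites * (tab[1] * tab[4] - tab[2] * tab[3])^2 / (r1 * r2 * c1 * c2)
}

#' Permutation chi-square test of independence of two site sets
#'
#' Computes the observed chi-square for the overlap of `mask_a` and
#' `mask_b` on `n_sites` sites, then redraws `mask_b` as a uniform random
#' subset of the same size (with `mask_a` fixed) and recomputes the
#' statistic. The p-value is `(#replicates with chi2 >= observed + 1) /
#' (R + 1)`. When `choose(n_sites, |mask_b|) <= 1e5` the null is computed
#' exactly instead of by sampling: the statistic depends on the redrawn
#' set only through its overlap with `mask_a`, whose null distribution is
#' hypergeometric, so the exact tail is the hypergeometric sum.
#'
#' @param n_sites Total number of sites on the shared numbering.
#' @param mask_a,mask_b `site_mask` objects (numbering ids must agree) or
#'   integer position vectors.
#' @param R Number of permutation replicates when sampling.
#' @param seed Integer seed for the replicate draws.
#' @return An `overlap_result`: list with `n_sites`, `n_a`, `n_b`,
#'   `n_overlap`, `chi2`, `p`, `R`, `seed`, `exact`.
#' @export
permutation_independence <- function(n_sites, mask_a, mask_b,
                                     R = 10000L, seed = 1L) {
  if (inherits(mask_a, "site_mask") && inherits(mask_b, "site_mask")) {
    if (!identical(mask_a$numbering_id, mask_b$numbering_id)) {
      stop("masks use different numbering systems: ",
           mask_a$numbering_id, " vs ", mask_b$numbering_id)
    }
  }
  a <- if (inherits(mask_a, "site_mask")) mask_a$positions else
    sort(unique(as.integer(mask_a)))
  b <- if (inherits(mask_b, "site_mask")) mask_b$positions else
    sort(unique(as.integer(mask_b)))
  if (R < 1L) stop("R must be >= 1")
  na <- length(a); nb <- length(b)
  obs_overlap <- length(intersect(a, b))
  obs <- chi_square_2x2(n_sites, na, nb, obs_overlap)
  eps <- 1e-12
  exact <- is.finite(choose(n_sites, nb)) && choose(n_sites, nb) <= 1e5
  if (exact) {
    support <- max(0L, na + nb - n_sites):min(na, nb)
    chis <- vapply(support, function(o) {
      tryCatch(chi_square_2x2(n_sites, na, nb, o), error = function(e) Inf)
    }, numeric(1))
    p <- sum(stats::dhyper(support[chis >= obs - eps], na,
                           n_sites - na, nb))
  } else {
    hits <- .with_seed(seed, {
      sum(vapply(seq_len(R), function(r) {
        # under a uniform redraw of B only |A| matters, so A can be
        # relabelled to the first na site indices
        draw <- sample.int(n_sites, nb)
        o <- sum(draw <= na)
        chi_square_2x2(n_sites, na, nb, o) >= obs - eps
      }, logical(1)))
    })
    p <- (hits + 1) / (R + 1)
  }
  structure(
    list(n_sites = n_sites, n_a = na, n_b = nb, n_overlap = obs_overlap,
         chi2 = obs, p = p, R = if (exact) NA_integer_ else as.integer(R),
         seed = as.integer(seed), exact = exact),
    class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("site-set association test\n")
  cat(sprintf("  %d sites; |A| = %d, |B| = %d, overlap = %d\n",
              x$n_sites, x$n_a, x$n_b, x$n_overlap))
  cat(sprintf("  chi2 = %.3f, p = %.4g (%s)\n", x$chi2, x$p,
              if (x$exact) "exact" else paste0(x$R, " permutations")))
  invisible(x)
}
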