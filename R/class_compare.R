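# Between-class comparison of selection strength: a Z statistic on the
# difference of two (dN - dS) estimates with their bootstrap standard
# errors, and a one-sided normal p-value.

#' Z statistic comparing two dN - dS estimates
#'
#' `Z = (d1 - d2) / sqrt(se1^2 + se2^2)` with one-sided
#' `p = 1 - pnorm(Z)`, testing the hypothesis that the first estimate is
#' larger. Callers order the arguments according to the hypothesized
#' direction.
#'
#' @param d1,d2 dN - dS estimates.
#' @param se1,se2 Their standard errors (bootstrap).
#' @return List with elements `Z` and `one_sided_p`.
#' @export
class_z <- function(d1, se1, d2, se2) {
  if (se1 < 0 || se2 < 0) stop("standard errors must be non-negative")
  if (se1 == 0 && se2 == 0) stop("both standard errors are zero")
  Z <- (d1 - d2) / sqrt(se1^2 + se2^2)
  list(Z = Z, one_sided_p = 1 - stats::pnorm(Z))
}

#' Compare selection strength between two allele sets
#'
#' Extracts (dN - dS, SE) from two `selection_result` objects (or lists
#' with `dnds_diff` and `se` elements) and applies the Z comparison. The
#' reported `Z` is always `(d1 - d2)/pooled SE`; `direction` selects which
#' one-sided tail is reported: `"1>2"` tests that the first set is under
#' stronger selection, `"2>1"` the reverse.
#'
#' @param result_1,result_2 `selection_result` objects or lists with
#'   `dnds_diff` and `se` (and optionally `method`, `mask`).
#' @param direction `"1>2"` or `"2>1"`.
#' @param label_1,label_2 Labels for the report.
#' @return A `class_comparison`: list with the inputs, `Z`,
#'   `one_sided_p` and `direction`.
#' @export
compare_classes <- function(result_1, result_2, direction = c("1>2", "2>1"),
                            label_1 = NULL, label_2 = NULL) {
  direction <- match.arg(direction)
  m1 <- result_1$method %||% NA_character_
  m2 <- result_2$method %||% NA_character_
  if (!is.na(m1) && !is.na(m2) && !identical(m1, m2)) {
    warning("comparing results from different methods: ", m1, " vs ", m2)
  }
  z <- class_z(result_1$dnds_diff, result_1$se,
               result_2$dnds_diff, result_2$se)
  p <- if (direction == "1>2") z$one_sided_p else 1 - z$one_sided_p
  structure(
    list(label_1 = label_1 %||% result_1$mask %||% "set 1",
         label_2 = label_2 %||% result_2$mask %||% "set 2",
         dnds_diff_1 = result_1$dnds_diff, se_1 = result_1$se,
         dnds_diff_2 = result_2$dnds_diff, se_2 = result_2$se,
         method_1 = m1, method_2 = m2,
         Z = z$Z, one_sided_p = p, direction = direction),
    class = "class_comparison")
}

#' @export
print.class_comparison <- function(x, ...) {
  cat("between-class selection comparison (", x$direction, ")\n", sep = "")
  cat(sprintf("  %s: dN-dS = %.3f (SE %.3f)\n", x$label_1, x$dnds_diff_1,
              x$se_1))
  cat(sprintf("  %s: dN-dS = %.3f (SE %.3f)\n", x$label_2, x$dnds_diff_2,
              x$se_2))
  cat(sprintf("  Z = %.3f, one-sided p = %.3f\n", x$Z, x$one_sided_p))
  invisible(x)
}
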