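# Codon lookup tables shared by the counting and distance methods.
# Built once at install time; all objects are internal.

.BASES <- c("A", "C", "G", "T")

.CODONS <- local({
  g <- expand.grid(p3 = .BASES, p2 = .BASES, p1 = .BASES,
                   stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
})

.AA <- unname(Biostrings::GENETIC_CODE[.CODONS])
.IS_SENSE <- .AA != "*"

.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

.codon_chars <- local({
  m <- matrix("", length(.CODONS), 3)
  for (i in seq_along(.CODONS)) m[i, ] <- strsplit(.CODONS[i], "")[[1]]
  m
})

.aa_of <- function(codon) .AA[match(codon, .CODONS)]

# Nei-Gojobori synonymous site count per codon: at each position, the
# fraction of non-stop single-base alternatives that are synonymous.
.NG_S <- local({
  s <- rep(NA_real_, 64)
  for (i in which(.IS_SENSE)) {
    b <- .codon_chars[i, ]
    tot <- 0
    for (pos in 1:3) {
      alts <- setdiff(.BASES, b[pos])
      alt_cod <- vapply(alts, function(x) {
        bb <- b; bb[pos] <- x; paste(bb, collapse = "")
      }, "")
      alt_aa <- .aa_of(alt_cod)
      valid <- alt_aa != "*"
      if (any(valid)) tot <- tot + sum(alt_aa[valid] == .AA[i]) / sum(valid)
    }
    s[i] <- tot
  }
  s
})

# Degeneracy class per codon position: 4-fold if every alternative base is
# synonymous, 0-fold if none is, else 2-fold. Changes to stops count as
# nonsynonymous alternatives.
.DEG <- local({
  d <- matrix(NA_integer_, 64, 3)
  for (i in which(.IS_SENSE)) {
    b <- .codon_chars[i, ]
    for (pos in 1:3) {
      alts <- setdiff(.BASES, b[pos])
      alt_cod <- vapply(alts, function(x) {
        bb <- b; bb[pos] <- x; paste(bb, collapse = "")
      }, "")
      syn <- .aa_of(alt_cod) == .AA[i]  # stops compare FALSE against sense AA
      d[i, pos] <- if (all(syn)) 4L else if (any(syn)) 2L else 0L
    }
  }
  d
})

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair. Orderings of the differing positions that pass through a stop codon
# are excluded; if every ordering does, all are kept with stop-involving
# steps counted as nonsynonymous.
.ng_pair_one <- function(ia, ib) {
  if (ia == ib) return(c(0, 0))
  a <- .codon_chars[ia, ]
  b <- .codon_chars[ib, ]
  dpos <- which(a != b)
  paths <- .permutations(dpos)
  count_path <- function(ord, allow_stops) {
    cur <- a
    sd <- 0; nd <- 0
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- .aa_of(paste(cur, collapse = ""))
      aa2 <- .aa_of(paste(nxt, collapse = ""))
      if (aa2 == "*" && !allow_stops) return(NULL)
      if (aa1 == aa2 && aa1 != "*" && aa2 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(paths, count_path, allow_stops = FALSE)
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0L) res <- lapply(paths, count_path, allow_stops = TRUE)
  colMeans(do.call(rbind, res))
}

.NG_SD <- matrix(NA_real_, 64, 64)
.NG_ND <- matrix(NA_real_, 64, 64)
local({
  sense <- which(.IS_SENSE)
  for (i in sense) for (j in sense) {
    sn <- .ng_pair_one(i, j)
    .NG_SD[i, j] <<- sn[1]
    .NG_ND[i, j] <<- sn[2]
  }
})

# Pamilo-Bianchi-Li position bookkeeping per codon pair: degeneracy-class
# site contributions (L0/L2/L4) and transition/transversion counts per class
# summed over the 3 positions. Positions whose class differs between the two
# codons are split half-and-half between the classes.
.PBL_TAB <- local({
  tab <- array(NA_real_, dim = c(64, 64, 9))
  cls_index <- function(cl) match(cl, c(0L, 2L, 4L))
  sense <- which(.IS_SENSE)
  for (i in sense) for (j in sense) {
    L <- numeric(3); P <- numeric(3); Q <- numeric(3)
    for (pos in 1:3) {
      ca <- cls_index(.DEG[i, pos])
      cb <- cls_index(.DEG[j, pos])
      if (ca == cb) {
        w <- c(1); cl <- c(ca)
      } else {
        w <- c(0.5, 0.5); cl <- c(ca, cb)
      }
      L[cl[1]] <- L[cl[1]] + w[1]
      if (length(cl) == 2) L[cl[2]] <- L[cl[2]] + w[2]
      ba <- .codon_chars[i, pos]; bb <- .codon_chars[j, pos]
      if (ba != bb) {
        ts <- .is_transition(ba, bb)
        for (kk in seq_along(cl)) {
          if (ts) P[cl[kk]] <- P[cl[kk]] + w[kk]
          else Q[cl[kk]] <- Q[cl[kk]] + w[kk]
        }
      }
    }
    tab[i, j, ] <- c(L, P, Q)
  }
  tab
})
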