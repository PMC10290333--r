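# Independent oracles: a second, hand-transcribed genetic code table and
# brute-force counterparts of the codon-level operations. These never call
# into the package's lookup tables.

# Standard genetic code, written out family by family.
oracle_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracle_bases <- c("A", "C", "G", "T")
oracle_sense <- names(oracle_code)[oracle_code != "*"]

oracle_neighbours <- function(codon, pos) {
  b <- strsplit(codon, "")[[1]]
  vapply(setdiff(oracle_bases, b[pos]), function(x) {
    bb <- b; bb[pos] <- x; paste(bb, collapse = "")
  }, "")
}

# degeneracy: stops count as nonsynonymous alternatives
oracle_degeneracy <- function(codon) {
  aa <- oracle_code[[codon]]
  vapply(1:3, function(pos) {
    syn <- oracle_code[oracle_neighbours(codon, pos)] == aa
    if (all(syn)) 4L else if (any(syn)) 2L else 0L
  }, integer(1))
}

# NG86 synonymous site count with stop-excluded denominators
oracle_ng86_s <- function(codon) {
  aa <- oracle_code[[codon]]
  sum(vapply(1:3, function(pos) {
    nb <- oracle_neighbours(codon, pos)
    valid <- oracle_code[nb] != "*"
    if (!any(valid)) return(0)
    sum(oracle_code[nb[valid]] == aa) / sum(valid)
  }, numeric(1)))
}

# NG86 pathway enumeration with the same stop rule
oracle_ng86_pair <- function(a, b) {
  if (a == b) return(c(sd = 0, nd = 0))
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  dpos <- which(av != bv)
  orders <- if (length(dpos) == 1) list(dpos) else {
    perms <- gtools_permute(dpos)
    perms
  }
  walk <- function(ord, allow) {
    cur <- av; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- bv[p]
      aa1 <- oracle_code[[paste(cur, collapse = "")]]
      aa2 <- oracle_code[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && !allow) return(NULL)
      if (aa1 == aa2 && aa1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(orders, walk, allow = FALSE))
  if (length(res) == 0) res <- lapply(orders, walk, allow = TRUE)
  colMeans(do.call(rbind, res))
}

gtools_permute <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in gtools_permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# explicit double-loop diversity statistics
oracle_k_pi <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  n <- nrow(m); ks <- c(); pis <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    d <- sum(m[i, ok] != m[j, ok])
    ks <- c(ks, d)
    pis <- c(pis, if (sum(ok) > 0) d / sum(ok) else NA)
  }
  list(k = mean(ks), Pi = mean(pis, na.rm = TRUE))
}

oracle_S_eta <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(unname(seqs)), ""))
  S <- 0; Eta <- 0
  for (j in seq_len(ncol(m))) {
    col <- m[, j][m[, j] != "-"]
    if (length(col) < 2) next
    u <- length(unique(col))
    if (u >= 2) { S <- S + 1; Eta <- Eta + u - 1 }
  }
  list(S = S, Eta = Eta)
}

# random gapped nucleotide alignment for property tests
random_alignment <- function(n_seq, n_sites, gap_prob = 0) {
  m <- matrix(sample(oracle_bases, n_seq * n_sites, replace = TRUE),
              n_seq, n_sites)
  if (gap_prob > 0) m[runif(length(m)) < gap_prob] <- "-"
  seqs <- apply(m, 1, paste, collapse = "")
  names(seqs) <- sprintf("s%02d", seq_len(n_seq))
  seqs
}

# random in-frame sense-codon alignment (no gaps)
random_codon_seqs <- function(n_seq, n_codons) {
  seqs <- replicate(n_seq, paste(
    sample(oracle_sense, n_codons, replace = TRUE), collapse = ""))
  names(seqs) <- sprintf("s%02d", seq_len(n_seq))
  seqs
}

# related sense-codon sequences: a shared root with a few single-codon
# substitutions per sequence, so pairwise distances stay unsaturated
related_codon_seqs <- function(n_seq, n_codons, n_mut = 3) {
  root <- sample(oracle_sense, n_codons, replace = TRUE)
  seqs <- vapply(seq_len(n_seq), function(i) {
    cod <- root
    at <- sample(n_codons, min(n_mut, n_codons))
    cod[at] <- sample(oracle_sense, length(at), replace = TRUE)
    paste(cod, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%02d", seq_len(n_seq))
  seqs
}
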