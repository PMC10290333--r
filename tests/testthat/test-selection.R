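test_that("NG86 site counts match brute-force enumeration on all codons", {
  expect_equal(ng86_sites("GGG")$s, 1.0)
  expect_equal(ng86_sites("ATG")$s, 0)
  for (codon in oracle_sense) {
    got <- ng86_sites(codon)
    expect_equal(got$s, oracle_ng86_s(codon), label = codon)
    expect_equal(got$s + got$n, 3, label = codon)  # s + n = 3 identity
  }
  expect_error(ng86_sites("TAA"), "stop")
})

test_that("NG86 pathway counts match an independent enumerator", {
  expect_equal(ng86_pair_diffs("TTT", "TTT"), list(sd = 0, nd = 0))
  expect_equal(ng86_pair_diffs("TTT", "TTC"), list(sd = 1, nd = 0))
  set.seed(201)
  for (rep in 1:500) {
    a <- sample(oracle_sense, 1); b <- sample(oracle_sense, 1)
    got <- ng86_pair_diffs(a, b)
    exp <- oracle_ng86_pair(a, b)
    expect_equal(got$sd, unname(exp["sd"]), label = paste(a, b))
    expect_equal(got$nd, unname(exp["nd"]), label = paste(a, b))
    # total differences are conserved by pathway averaging
    nd_pos <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(got$sd + got$nd, nd_pos, label = paste(a, b))
  }
})

test_that("NG86 mean distances compose from the per-codon operations", {
  a <- "ATGGGGTTT"; b <- "ATGGGATTA"
  aln <- codon_alignment(c(x = a, y = b))
  got <- dnds_ng86(aln)
  # hand-composition from the oracle primitives
  cod_a <- c("ATG", "GGG", "TTT"); cod_b <- c("ATG", "GGA", "TTA")
  sd <- sum(vapply(1:3, function(k)
    oracle_ng86_pair(cod_a[k], cod_b[k])["sd"], numeric(1)))
  nd <- sum(vapply(1:3, function(k)
    oracle_ng86_pair(cod_a[k], cod_b[k])["nd"], numeric(1)))
  sbar <- (sum(vapply(cod_a, oracle_ng86_s, numeric(1))) +
             sum(vapply(cod_b, oracle_ng86_s, numeric(1)))) / 2
  nbar <- 9 - sbar
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  expect_equal(got$dS, jc(sd / sbar))
  expect_equal(got$dN, jc(nd / nbar))
})

test_that("both methods return zero on identical sequences and are
           symmetric in sequence order", {
  set.seed(202)
  seqs <- related_codon_seqs(4, 20)
  ident <- stats::setNames(rep(seqs[1], 3), c("a", "b", "c"))
  aln0 <- codon_alignment(ident)
  expect_equal(dnds_ng86(aln0)[c("dN", "dS")], list(dN = 0, dS = 0))
  expect_equal(dnds_pbl(aln0)[c("dN", "dS")], list(dN = 0, dS = 0))

  aln <- codon_alignment(seqs)
  alnr <- codon_alignment(rev(seqs))
  expect_equal(dnds_ng86(aln)[c("dN", "dS")], dnds_ng86(alnr)[c("dN", "dS")])
  expect_equal(dnds_pbl(aln)[c("dN", "dS")], dnds_pbl(alnr)[c("dN", "dS")])
})

test_that("PBL distances match a position-by-position recount", {
  jc_k2p <- function(L, P, Q) {
    P <- ifelse(L > 0, P / L, 0); Q <- ifelse(L > 0, Q / L, 0)
    list(A = ifelse(L > 0, 0.5 * log(1 / (1 - 2 * P - Q)) -
                      0.25 * log(1 / (1 - 2 * Q)), 0),
         B = ifelse(L > 0, 0.5 * log(1 / (1 - 2 * Q)), 0))
  }
  is_ts <- function(x, y) paste0(x, y) %in% c("AG", "GA", "CT", "TC")
  set.seed(203)
  for (rep in 1:10) {
    seqs <- related_codon_seqs(2, 20, n_mut = 3)
    aln <- codon_alignment(seqs)
    got <- suppressWarnings(dnds_pbl(aln))
    # independent recount over the 60 positions
    ca <- substring(seqs[1], seq(1, 58, 3), seq(3, 60, 3))
    cb <- substring(seqs[2], seq(1, 58, 3), seq(3, 60, 3))
    L <- c(`0` = 0, `2` = 0, `4` = 0); P <- L; Q <- L
    for (k in 1:20) {
      da <- oracle_degeneracy(ca[k]); db <- oracle_degeneracy(cb[k])
      for (pos in 1:3) {
        cls <- as.character(c(da[pos], db[pos]))
        w <- if (cls[1] == cls[2]) c(1, 0) else c(0.5, 0.5)
        L[cls[1]] <- L[cls[1]] + w[1]; L[cls[2]] <- L[cls[2]] + w[2]
        x <- substr(ca[k], pos, pos); y <- substr(cb[k], pos, pos)
        if (x != y) {
          if (is_ts(x, y)) {
            P[cls[1]] <- P[cls[1]] + w[1]; P[cls[2]] <- P[cls[2]] + w[2]
          } else {
            Q[cls[1]] <- Q[cls[1]] + w[1]; Q[cls[2]] <- Q[cls[2]] + w[2]
          }
        }
      }
    }
    expect_equal(sum(L), 60)  # classes partition all compared positions
    ab0 <- jc_k2p(L["0"], P["0"], Q["0"])
    ab2 <- jc_k2p(L["2"], P["2"], Q["2"])
    ab4 <- jc_k2p(L["4"], P["4"], Q["4"])
    dS <- (L["2"] * ab2$A + L["4"] * ab4$A) / (L["2"] + L["4"]) + ab4$B
    dN <- ab0$A + (L["0"] * ab0$B + L["2"] * ab2$B) / (L["0"] + L["2"])
    expect_equal(got$dS, unname(dS), tolerance = 1e-12)
    expect_equal(got$dN, unname(dN), tolerance = 1e-12)
  }
})

test_that("a single synonymous transition at a fourfold site moves only dS", {
  # one GGA -> GGG transition among three fourfold-degenerate glycines
  aln <- codon_alignment(c(x = "GGAGGAGGA", y = "GGGGGAGGA"))
  got <- dnds_pbl(aln)
  expect_gt(got$dS, 0)
  expect_equal(got$dN, 0)
})

test_that("gapped codons are pairwise-deleted", {
  aln <- codon_alignment(c(x = "ATG---TTTTTTTTTTTTTTT",
                           y = "ATGGGGTTCTTTTTTTTTTTT"))
  got <- dnds_ng86(aln)
  # codon 2 is skipped for this pair; the only difference is synonymous
  expect_equal(got$dN, 0)
  expect_gt(got$dS, 0)
  gotp <- dnds_pbl(aln)
  expect_equal(gotp$dN, 0)
  expect_gt(gotp$dS, 0)
})

test_that("masked columns restrict the computation", {
  set.seed(204)
  seqs <- related_codon_seqs(3, 12, n_mut = 4)
  aln <- codon_alignment(seqs)
  full <- dnds_ng86(aln)
  sub <- dnds_ng86(aln, mask = 1:6)
  manual <- dnds_ng86(codon_alignment(
    stats::setNames(substr(seqs, 1, 18), names(seqs))))
  expect_equal(sub[c("dN", "dS")], manual[c("dN", "dS")])
  expect_error(dnds_ng86(aln, mask = c(1, 99)), "out of range")
  expect_false(isTRUE(all.equal(full$dS, sub$dS)))
})

test_that("bootstrap SE is deterministic under a seed and zero for
           monomorphic alignments", {
  set.seed(205)
  seqs <- related_codon_seqs(4, 15, n_mut = 4)
  aln <- codon_alignment(seqs)
  se1 <- bootstrap_se(aln, method = "NG86-JC", reps = 100, seed = 9)
  se2 <- bootstrap_se(aln, method = "NG86-JC", reps = 100, seed = 9)
  expect_identical(se1, se2)
  se3 <- bootstrap_se(aln, method = "NG86-JC", reps = 100, seed = 10)
  expect_false(identical(se1, se3))

  mono <- codon_alignment(stats::setNames(rep(seqs[1], 3), c("a", "b", "c")))
  expect_equal(bootstrap_se(mono, reps = 50, seed = 1), 0)
})

test_that("bootstrap SE stabilizes with replicate count", {
  sim <- simulate_codon_alignment(12, 40, mask = 1:10, omega_mask = 4,
                                  seed = 31)
  se_small <- bootstrap_se(sim$alignment, method = "NG86-JC",
                           reps = 1000, seed = 5)
  se_big <- bootstrap_se(sim$alignment, method = "NG86-JC",
                         reps = 10000, seed = 6)
  expect_lt(abs(se_small - se_big) / se_big, 0.15)
})

test_that("Z-test degenerates gracefully and reports NA dN/dS when dS = 0", {
  set.seed(206)
  seqs <- random_codon_seqs(3, 10)
  mono <- codon_alignment(stats::setNames(rep(seqs[1], 3), c("a", "b", "c")))
  res <- z_test_positive_selection(mono, reps = 50, seed = 1)
  expect_equal(res$Z, 0)
  expect_equal(res$p, 0.5)

  # a single nonsynonymous difference: dS = 0 -> ratio undefined
  aln <- codon_alignment(c(x = "ATGAAATTT", y = "CTGAAATTT"))
  res2 <- suppressWarnings(
    z_test_positive_selection(aln, reps = 50, seed = 1))
  expect_true(is.na(res2$dnds))
  expect_equal(res2$dS, 0)
})

test_that("estimated dN/dS rises with simulated omega on the mask", {
  omegas <- c(0.5, 1, 2, 4, 8)
  ratios <- vapply(seq_along(omegas), function(i) {
    sim <- simulate_codon_alignment(12, 60, mask = 1:20,
                                    omega_mask = omegas[i], kappa = 2,
                                    seed = 300 + i)
    r <- dnds_ng86(sim$alignment, mask = 1:20)
    r$dN / r$dS
  }, numeric(1))
  expect_gt(stats::cor(omegas, ratios, method = "spearman"), 0)
})
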