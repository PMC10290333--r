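make_table <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(individual = r[[1]], replicate = r[[2]], amplicon = r[[3]],
               allele = r[[4]], reads = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)
  }))
}

test_that("replicate reproducibility follows the shared-allele formula", {
  expect_equal(replicate_reproducibility(c("a", "b", "c"), c("a", "b", "c")),
               100)
  expect_equal(replicate_reproducibility(c("a", "b", "c"), c("a", "b", "d")),
               66.667, tolerance = 1e-3)
  expect_error(replicate_reproducibility(character(0), "a"), "empty")
})

test_that("reproducibility is symmetric and 100 iff the sets are equal", {
  set.seed(501)
  pool <- sprintf("al%02d", 1:20)
  for (rep in 1:20) {
    a <- sample(pool, sample(1:8, 1))
    b <- sample(pool, sample(1:8, 1))
    expect_equal(replicate_reproducibility(a, b),
                 replicate_reproducibility(b, a))
    r <- replicate_reproducibility(a, b)
    expect_equal(r == 100, setequal(a, b))
  }
})

test_that("read filtering removes exactly the below-threshold samples", {
  tab <- make_table(
    list("i1", "R1", "amp1", "a", 600), list("i1", "R1", "amp1", "b", 500),
    list("i2", "R1", "amp1", "a", 40), list("i2", "R1", "amp1", "c", 50),
    list("i3", "R1", "amp1", "d", 120))
  out <- filter_genotypes(tab, min_reads = 100)
  expect_setequal(unique(out$kept$individual), c("i1", "i3"))
  expect_setequal(unique(out$removed$individual), "i2")
  expect_equal(nrow(out$kept) + nrow(out$removed), nrow(tab))
  # identity under min_reads = 0
  out0 <- filter_genotypes(tab, min_reads = 0)
  expect_equal(nrow(out0$kept), nrow(tab))
})

test_that("oversized genotypes are flagged, not removed", {
  rows <- lapply(sprintf("a%d", 1:8), function(al)
    list("i1", "R1", "amp1", al, 200))
  tab <- do.call(make_table, rows)
  out <- filter_genotypes(tab, min_reads = 100, max_alleles = 6)
  expect_equal(nrow(out$kept), 8)
  expect_true(out$log$flagged[out$log$individual == "i1"])
})

test_that("filtering a planted 130-sample dataset keeps exactly 113", {
  sim <- simulate_genotype_dataset(n_individuals = 130, n_low_read = 17,
                                   replicate_fraction = 0, seed = 77)
  out <- filter_genotypes(sim$table, min_reads = 100)
  expect_equal(length(unique(out$kept$individual)), 113L)
  expect_setequal(unique(out$removed$individual),
                  sim$truth$low_read_individuals)
})

test_that("dataset-level reproducibility tracks the dropout expectation", {
  # with per-allele dropout d, each allele survives a replicate with
  # probability 1 - d, so expected reproducibility is about 100 (1 - d)
  d <- 0.02
  sim <- simulate_genotype_dataset(n_individuals = 113,
                                   replicate_fraction = 0.575,
                                   dropout = d, seed = 99)
  mr <- mean_reproducibility(sim$table)
  expect_gte(nrow(mr$pairs), 40)
  expect_lt(abs(mr$mean - 100 * (1 - d)), 2)
})

test_that("allele validation reports stops and anchor status", {
  # build a small allele set and map against its own consensus so anchor
  # positions land on known columns
  alleles <- c(a1 = "ATGACGAAATGGTAT",  # M T K W Y
               a2 = "ATGACGAGATGGTAT",  # M T R W Y (K -> R at anchor 2)
               a3 = "ATGACGAAATGGTAA")  # M T K W *
  paln <- translate_codons(codon_alignment(alleles))
  map <- build_site_map(paln, "MTKWY", reference_start = 142)
  spec <- anchor_spec("test", positions = c(143, 144, 145, 146),
                      required = c("T", "K", "W", "Y"),
                      tolerated = list("R", "R", character(0), character(0)))
  r1 <- validate_allele(alleles[["a1"]], 1, spec, map, "a1")
  expect_false(r1$has_stop)
  expect_equal(r1$anchors$status, c("match", "match", "match", "match"))
  r2 <- validate_allele(alleles[["a2"]], 1, spec, map, "a2")
  expect_equal(r2$anchors$status[2], "tolerated")
  r3 <- validate_allele(alleles[["a3"]], 1, spec, map, "a3")
  expect_true(r3$has_stop)
  # unmapped positions are reported, not raised
  spec2 <- anchor_spec("test", positions = 999, required = "Y")
  expect_equal(validate_allele(alleles[["a1"]], 1, spec2,
                               map)$anchors$status, "unmapped")
})

test_that("bundled MHC anchor specs are well-formed", {
  s1 <- mhc_anchor_spec("I")
  expect_equal(s1$positions, c(143L, 146L, 147L, 159L, 171L))
  expect_equal(s1$tolerated[[2]], "R")
  s2 <- mhc_anchor_spec("IIB")
  expect_equal(s2$required, c("W", "H", "N"))
})

test_that("expression cross-check requires exact full-length identity and
           is strand-symmetric", {
  allele <- "ATGACGAAATGGTAT"
  tx_fwd <- paste0("CCCC", allele, "GGGG")
  rc <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  tx_rev <- rc(tx_fwd)
  near <- sub("ATGACG", "ATGACT", tx_fwd)
  expect_true(expression_crosscheck(c(a = allele), c(t1 = tx_fwd))[["a"]])
  expect_true(expression_crosscheck(c(a = allele), c(t1 = tx_rev))[["a"]])
  expect_false(expression_crosscheck(c(a = allele), c(t1 = near))[["a"]])
})

test_that("planted expressed sets are recovered exactly", {
  sim <- simulate_genotype_dataset(n_individuals = 20, pool_size = 12,
                                   expressed_fraction = 0.35, seed = 13)
  expressed <- expression_crosscheck(sim$alleles, sim$transcripts)
  expect_setequal(names(expressed)[expressed], sim$truth$expressed)
})

test_that("allele summary collapses replicates by union", {
  tab <- make_table(
    list("i1", "R1", "amp1", "a", 100), list("i1", "R1", "amp1", "b", 100),
    list("i1", "R2", "amp1", "a", 100), list("i1", "R2", "amp1", "c", 100),
    list("i2", "R1", "amp1", "a", 100))
  s <- allele_summary(tab)
  expect_equal(s$n_individuals, 2)
  # i1 has union {a, b, c}
  expect_equal(s$per_individual$n_alleles[s$per_individual$individual ==
                                            "i1"], 3)
  expect_equal(s$mean_alleles, 2)
  expect_equal(s$carriers$proportion[s$carriers$allele == "a"], 1)
  expect_equal(s$carriers$proportion[s$carriers$allele == "b"], 0.5)
})

test_that("simulated carrier proportions sit near planted frequencies", {
  sim <- simulate_genotype_dataset(n_individuals = 200, n_loci = 1,
                                   pool_size = 10, skewed_freqs = TRUE,
                                   replicate_fraction = 0, dropout = 0,
                                   seed = 55)
  s <- allele_summary(sim$table)
  # the near-fixed allele of the skewed pool is carried by almost everyone
  top <- s$carriers$proportion[1]
  expect_gt(top, 0.9)
})

test_that("genotype table round-trips through TSV", {
  sim <- simulate_genotype_dataset(n_individuals = 5, seed = 3)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(sim$table, f, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  back <- read_genotype_table(f)
  expect_equal(nrow(back), nrow(sim$table))
  expect_equal(sort(unique(back$allele)), sort(unique(sim$table$allele)))
})
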