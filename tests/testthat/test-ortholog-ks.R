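hitRow <- function(q, s, evalue, bits) {
  data.frame(qseqid = q, sseqid = s, pident = 90, length = 100, mismatch = 5,
             gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = evalue, bitscore = bits, stringsAsFactors = FALSE)
}

test_that("reciprocal best hits require agreement in both directions", {
  ab <- hitRow("a", "b", 1e-40, 200)
  ba <- hitRow("b", "a", 1e-40, 200)
  expect_identical(reciprocalBestHits(ab, ba),
                   data.frame(geneA = "a", geneB = "b"))

  # b's best is a2, not a -> no pair
  ba2 <- rbind(hitRow("b", "a", 1e-40, 200), hitRow("b", "a2", 1e-50, 300))
  expect_identical(nrow(reciprocalBestHits(ab, ba2)), 0L)

  # equal bit scores: the lower e-value hit wins
  ab2 <- rbind(hitRow("a", "b", 1e-20, 200), hitRow("a", "c", 1e-40, 200))
  ba3 <- rbind(hitRow("c", "a", 1e-40, 200), hitRow("b", "a", 1e-40, 200))
  expect_identical(reciprocalBestHits(ab2, ba3),
                   data.frame(geneA = "a", geneB = "c"))

  # e-value cutoff removes weak hits entirely
  weak <- hitRow("a", "b", 1e-3, 500)
  expect_identical(nrow(reciprocalBestHits(weak, ba)), 0L)
})

test_that("RBH output mirrors when the two tables are swapped", {
  set.seed(42)
  genesA <- paste0("a", 1:8); genesB <- paste0("b", 1:8)
  ab <- do.call(rbind, lapply(genesA, function(g) {
    s <- sample(genesB, 3)
    do.call(rbind, Map(hitRow, g, s, 10^-sample(10:60, 3),
                       sample(50:300, 3)))
  }))
  ba <- do.call(rbind, lapply(genesB, function(g) {
    s <- sample(genesA, 3)
    do.call(rbind, Map(hitRow, g, s, 10^-sample(10:60, 3),
                       sample(50:300, 3)))
  }))
  fwd <- reciprocalBestHits(ab, ba)
  rev <- reciprocalBestHits(ba, ab)
  expect_setequal(paste(fwd$geneA, fwd$geneB), paste(rev$geneB, rev$geneA))
})

test_that("hit-table parser enforces the 12-column dialect", {
  tf <- tempfile()
  writeLines("q1\ts1\t90.0\t100\t5\t0\t1\t100\t1\t100\t1e-50\t200", tf)
  h <- readBlastTab(tf)
  expect_identical(names(h)[c(1, 11, 12)], c("qseqid", "evalue", "bitscore"))
  writeLines("q1\ts1\t90.0", tf)
  expect_error(readBlastTab(tf), "12 columns")
})

test_that("global protein alignment matches a brute-force affine-gap DP oracle", {
  al <- alignProteinsGlobal("HEAGAWGHEE", "PAWHEAE")
  expect_equal(al$score, oracleGotohScore("HEAGAWGHEE", "PAWHEAE"))

  ident <- alignProteinsGlobal("MKTAYIAK", "MKTAYIAK")
  expect_identical(ident$aligned1, "MKTAYIAK")
  expect_identical(ident$aligned2, "MKTAYIAK")

  single <- alignProteinsGlobal("M", "L")
  expect_identical(nchar(single$aligned1), 1L)

  set.seed(8)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    s1 <- paste(sample(aas, sample(5:12, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(aas, sample(5:12, 1), replace = TRUE), collapse = "")
    expect_equal(alignProteinsGlobal(s1, s2)$score, oracleGotohScore(s1, s2))
  }
  expect_error(alignProteinsGlobal("", "MK"), "empty")
})

test_that("back-translation maps residues to codons and strips gap columns", {
  # gapless: codons unchanged
  ca <- backTranslate("MK", "MK", "ATGAAA", "ATGAAG")
  expect_identical(ca@seq1, "ATGAAA")
  expect_identical(ca@seq2, "ATGAAG")

  # a gap column removes one codon from each output
  ca2 <- backTranslate("MEK", "M-K", "ATGGAAAAA", "ATGAAG")
  expect_identical(ca2@seq1, "ATGAAA")
  expect_identical(ca2@seq2, "ATGAAG")
  expect_identical(nchar(ca2@seq1), 6L)

  # terminal stop on the CDS is tolerated
  ca3 <- backTranslate("MK", "MK", "ATGAAATAA", "ATGAAG")
  expect_identical(ca3@seq1, "ATGAAA")

  # translation mismatch errors name the codon index
  expect_error(backTranslate("MK", "MK", "ATGCCC", "ATGAAG"), "codon 2")
  expect_error(backTranslate("MKV", "MKV", "ATGAAA", "ATGAAGGTT"),
               "not 3x")
})

test_that("NG86 counting matches the spec worked example and is symmetric", {
  ca <- CodonAlignment("TTTGGGAAA", "TTCGGGAAA")
  est <- ng86Ks(ca)
  expect_equal(est$syn_sites, 5 / 3)
  expect_equal(est$syn_diffs, 1)
  expect_equal(est$pS, 0.6)
  expect_equal(est$Ks, -0.75 * log(0.2))
  expect_identical(est$nonsyn_diffs, 0)
  expect_identical(est$Ka, 0)

  ident <- ng86Ks(CodonAlignment("ATGAAACCC", "ATGAAACCC"))
  expect_identical(ident$Ks, 0)
  expect_identical(ident$Ka, 0)

  # symmetry under sequence swap
  set.seed(12)
  sense <- mycohet:::senseCodons()
  s1 <- paste(sample(sense, 40, replace = TRUE), collapse = "")
  s2 <- paste(sample(sense, 40, replace = TRUE), collapse = "")
  a <- ng86Ks(CodonAlignment(s1, s2))
  b <- ng86Ks(CodonAlignment(s2, s1))
  expect_equal(a[, 1:9], b[, 1:9])
  # site partition identity
  expect_equal(a$syn_sites + a$nonsyn_sites, 3 * a$n_codons)
})

test_that("NG86 tables agree with path-enumeration oracle on random codon pairs", {
  tab <- mycohet:::ng86Tables()
  expect_equal(unname(tab$sites), unname(vapply(tab$sense, oracleSynSites,
                                                numeric(1))))
  set.seed(33)
  for (i in 1:100) {
    c1 <- sample(tab$sense, 1); c2 <- sample(tab$sense, 1)
    o <- oraclePairDiffs(c1, c2)
    if (is.null(o)) {
      expect_false(tab$valid[c1, c2])
    } else {
      expect_equal(tab$sd[c1, c2], o[1])
      expect_equal(tab$nd[c1, c2], o[2])
    }
  }
})

test_that("ambiguous codons are excluded and saturation is flagged", {
  est <- ng86Ks(CodonAlignment("ATGNNNAAA", "ATGCCCAAA"))
  expect_identical(est$n_codons, 2L)
  expect_match(est$flags, "ambiguous_codons=1")

  # recovery near a known dS on a simulated pair
  qs <- quartetScenario(c(outgroup = 0, reference = 0, internal = 0,
                          spA = 0.3, spB = 0), nGenes = 20,
                        codonsPerGene = 500, seed = 61)
  sim <- simulateCodonQuartet(qs)
  ks <- vapply(names(sim$sequences$spA), function(g)
    ng86Ks(CodonAlignment(sim$sequences$reference[[g]],
                          sim$sequences$spA[[g]]))$Ks, numeric(1))
  expect_lt(abs(mean(ks) - 0.3), 0.05)
})

test_that("Ks table import drops bad rows and groups the rest", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("geneA\tgeneB\tKs", "a1\tb1\t0.5", "a2\tb2\t-1",
               "a3\tb3\t0.8"), tf)
  expect_message(d <- importKsTable(tf), "dropped")
  expect_length(ksValues(d), 2)
  writeLines(c("geneA\tgeneB"), tf)
  expect_error(importKsTable(tf), "columns")
})
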