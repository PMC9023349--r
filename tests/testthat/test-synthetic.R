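test_that("count-matrix simulator honours degenerate retention probabilities", {
  sc <- lossScenario(50, c("A", "B", "C"), retentionProb = 1, seed = 1)
  m <- geneCounts(simulateCountMatrix(sc))
  expect_true(all(m > 0))

  sc0 <- lossScenario(40, c("A", "B", "C"),
                      retentionProb = c(A = 0, B = 1, C = 1), seed = 2)
  m0 <- geneCounts(simulateCountMatrix(sc0))
  expect_true(all(m0[, "A"] == 0))
  expect_identical(sum(m0[, "A"] == 0), 40L)
  expect_true(all(m0[, c("B", "C")] > 0))
})

test_that("simulators are bit-reproducible from their seed", {
  sc <- lossScenario(200, c("A", "B"), retentionProb = 0.9, seed = 7)
  expect_identical(geneCounts(simulateCountMatrix(sc)),
                   geneCounts(simulateCountMatrix(sc)))

  qs <- quartetScenario(c(outgroup = 0.1, reference = 0.05, internal = 0.02,
                          spA = 0.05, spB = 0.1), nGenes = 3,
                        codonsPerGene = 40, seed = 11)
  expect_identical(simulateCodonQuartet(qs), simulateCodonQuartet(qs))

  lp <- simulateLtrPairs(5, 1e-8, 1e6, ltrLength = 300, seed = 3)
  expect_identical(lp, simulateLtrPairs(5, 1e-8, 1e6, ltrLength = 300, seed = 3))

  rd <- simulateReads(5000, 2, 100, errorRate = 0.01, seed = 9)
  expect_identical(rd, simulateReads(5000, 2, 100, errorRate = 0.01, seed = 9))
})

test_that("simulator parameter validation rejects bad probabilities and pairs", {
  expect_error(lossScenario(10, c("A", "B"), retentionProb = 1.2),
               "probability")
  expect_error(lossScenario(10, c("A", "B"), sharedPair = c("A", "A"),
                            sharedLossProb = 0.1), "distinct")
  expect_error(lossScenario(10, c("A", "B"), meanFamilySize = 0.5),
               "exceed 1")
  expect_error(quartetScenario(c(outgroup = -0.1, reference = 0, internal = 0,
                                 spA = 0, spB = 0)), ">= 0")
})

test_that("quartet sequences carry no internal stops and zero-rate branches stay identical", {
  qs <- quartetScenario(c(outgroup = 0, reference = 0, internal = 0,
                          spA = 0, spB = 0), nGenes = 4, codonsPerGene = 35,
                        seed = 5)
  sim <- simulateCodonQuartet(qs)
  expect_identical(sim$sequences$outgroup, sim$sequences$reference)
  expect_identical(sim$sequences$spA, sim$sequences$spB)
  expect_identical(sim$sequences$outgroup, sim$sequences$spA)

  qs2 <- quartetScenario(c(outgroup = 0.3, reference = 0.2, internal = 0.1,
                           spA = 0.2, spB = 0.4), nGenes = 5,
                         codonsPerGene = 60, seed = 6)
  sim2 <- simulateCodonQuartet(qs2)
  stops <- c("TAA", "TAG", "TGA")
  for (taxon in names(sim2$sequences)) {
    for (s in sim2$sequences[[taxon]]) {
      cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      expect_false(any(cod %in% stops))
    }
  }
})

test_that("synonymous-only evolution leaves the protein unchanged", {
  qs <- quartetScenario(c(outgroup = 0.2, reference = 0.1, internal = 0.05,
                          spA = 0.1, spB = 0.2), nGenes = 3,
                        codonsPerGene = 50, seed = 13)
  sim <- simulateCodonQuartet(qs)
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  for (g in names(sim$sequences$outgroup)) {
    p <- tr(sim$sequences$outgroup[[g]])
    for (taxon in c("reference", "spA", "spB"))
      expect_identical(tr(sim$sequences[[taxon]][[g]]), p)
  }
})

test_that("LTR pairs at age zero are identical and Poisson divergence matches expectation", {
  lp0 <- simulateLtrPairs(3, 1e-8, 0, ltrLength = 500, seed = 1)
  for (pr in lp0$pairs) {
    expect_identical(pr[1], pr[2])
    expect_identical(jcDistance(pr[1], pr[2])$d, 0)
  }
  # rate 1e-8/site/yr, age 1e6 yr, length 2000: about 40 pairwise differences
  lp <- simulateLtrPairs(30, 1e-8, 1e6, ltrLength = 2000, seed = 21)
  diffs <- vapply(lp$pairs, function(pr) {
    a <- strsplit(pr[1], "")[[1]]; b <- strsplit(pr[2], "")[[1]]
    sum(a != b)
  }, numeric(1))
  # mean of 30 Poisson(~40) variables: 3 sigma ~ 3*sqrt(40/30) ~ 3.5
  expect_lt(abs(mean(diffs) - 2000 * 2 * 1e-8 * 1e6), 5)
})

test_that("read simulator respects coverage and error settings", {
  expect_length(simulateReads(10000, 0, 100, seed = 1)$reads, 0)
  sim <- simulateReads(20000, 5, 100, errorRate = 0, seed = 4)
  expect_length(sim$reads, 1000)
  expect_true(all(nchar(sim$reads) == 100))
  # error-free reads must occur verbatim (or as revcomp) in the genome
  hit <- vapply(sim$reads[1:20], function(r)
    grepl(r, sim$genome, fixed = TRUE) ||
      grepl(revcompChar(r), sim$genome, fixed = TRUE), logical(1))
  expect_true(all(hit))
})

test_that("annotation simulator builds a valid term map and marks its enriched term", {
  u <- sprintf("g%04d", 1:500)
  target <- u[1:60]
  ann <- simulateAnnotation(u, nTerms = 15, enrichedTermFraction = 0.9,
                            targetSet = target, seed = 31)
  expect_true(all(ann$termMap$gene %in% u))
  expect_identical(ann$enrichedTerm, "T001")
  enr <- ann$termMap$gene[ann$termMap$term == ann$enrichedTerm]
  expect_gt(mean(enr %in% target), 0.5)
})
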