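makeCounts <- function(m) GeneFamilyCounts(m)

test_that("groups text and TSV inputs are parsed and round-trip", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("OG1: spA|g1 spA|g2 spB|g3",
               "OG2: spB|g4 spC|g5"), tf)
  x <- readGroups(tf)
  expect_identical(dim(geneCounts(x)), c(2L, 3L))
  expect_identical(geneCounts(x)["OG1", "spA"], 2L)
  expect_identical(geneCounts(x)["OG2", "spA"], 0L)

  out <- tempfile(fileext = ".tsv")
  writeCounts(x, out)
  x2 <- readGroups(out)
  expect_identical(geneCounts(x2), geneCounts(x))

  writeLines(c("OG1: spA|g1", "OG1: spB|g2"), tf)
  expect_error(readGroups(tf), "duplicate family id")
  writeLines(c("OG1 spA|g1"), tf)
  expect_error(readGroups(tf, format = "groups"), "line 1")
})

test_that("conservation filter enforces the species threshold and the outgroup homolog", {
  set.seed(1)
  sp <- c(paste0("s", 1:18), "Atr")
  m <- matrix(1L, 3, 19, dimnames = list(c("all", "f15", "noOut"), sp))
  m["f15", 1:4] <- 0L       # present in 15 of 19
  m["noOut", "Atr"] <- 0L   # 18 species but no outgroup homolog
  x <- makeCounts(m)
  kept <- familyIds(filterConserved(x, 16, "Atr"))
  expect_identical(kept, "all")
  expect_error(filterConserved(x, 16, "nope"), "unknown outgroup")
})

test_that("F index obeys its boundary identities for random family shapes", {
  set.seed(99)
  for (i in 1:50) {
    S <- sample(3:19, 1)
    perSpecies <- sample(1:6, 1)
    N <- S * perSpecies
    expect_identical(fIndex(0, N, S), 0)
    expect_identical(fIndex(N, N, S), 1)
    expect_equal(fIndex(perSpecies, N, S), 0.5, tolerance = 1e-12)
    # strictly increasing in c for fixed (N, S)
    Fs <- fIndex(0:N, N, S)
    expect_true(all(diff(Fs) > 0))
    expect_true(all(Fs >= 0 & Fs <= 1))
  }
  expect_equal(fIndex(4, 32, 16), (log2(112 * 4 / 32 + 0.5) + 1) /
                 (log2(112.5) + 1))
  expect_error(fIndex(1, 4, 2), "S >= 3")
  expect_error(fIndex(5, 4, 3), "c_ij")
})

test_that("classification uses the stated category boundaries at full precision", {
  expect_identical(as.character(classifyFIndex(0)), "Missing")
  expect_identical(as.character(classifyFIndex(0.45)), "Less than average")
  expect_identical(as.character(classifyFIndex(0.450000001)),
                   "Around average (less)")
  expect_identical(as.character(classifyFIndex(0.5)), "Around average (less)")
  expect_identical(as.character(classifyFIndex(0.55)),
                   "Around average (greater)")
  expect_identical(as.character(classifyFIndex(0.550001)),
                   "Greater than average")
  expect_identical(as.character(classifyFIndex(1)), "Greater than average")
  expect_error(classifyFIndex(1.2), "0, 1")

  # every evaluable cell lands in exactly one category
  set.seed(7)
  m <- matrix(rpois(20 * 6, 2), 20, 6,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
  m[1, ] <- c(1L, 1L, 1L, 0L, 0L, 0L)
  tab <- fIndexTable(makeCounts(m))
  ok <- tab$evaluable
  expect_false(any(is.na(tab$category[ok])))
  expect_true(all(is.na(tab$F[!ok])))
})

test_that("missing-family summaries count zeros, shared zeros and category percentages", {
  m <- matrix(c(1L, 1L, 1L,
                0L, 0L, 2L,
                2L, 1L, 1L,
                3L, 2L, 1L), 4, 3, byrow = TRUE,
              dimnames = list(paste0("f", 1:4), c("A", "B", "C")))
  ms <- missingSummary(makeCounts(m))
  expect_identical(unname(ms$perSpeciesMissing["A"]), 1)
  expect_identical(unname(ms$sharedMissing["A", "B"]), 1)
  expect_identical(ms$sharedMissing, t(ms$sharedMissing))
  expect_true(all(ms$sharedMissing <= outer(ms$perSpeciesMissing,
                                            ms$perSpeciesMissing, pmin)))
  expect_equal(unname(rowSums(ms$categoryPercent)), rep(100, 3))
})

test_that("missing fractions recover the simulated loss probabilities", {
  n <- 10000
  sc <- lossScenario(n, c("ref1", "ref2", "ref3", "mycoA", "mycoB"),
                     retentionProb = c(ref1 = 0.99, ref2 = 0.99, ref3 = 0.99,
                                       mycoA = 0.92, mycoB = 0.90),
                     sharedPair = c("mycoA", "mycoB"), sharedLossProb = 0.02,
                     seed = 77)
  ms <- missingSummary(simulateCountMatrix(sc))
  # P(missing in mycoA) = 1 - 0.92 * (1 - 0.02)
  pA <- 1 - 0.92 * 0.98
  se <- sqrt(pA * (1 - pA) / n)
  expect_lt(abs(ms$perSpeciesMissing["mycoA"] / n - pA), 3 * se)
  # shared-missing at least the joint component
  pShared <- 0.02 + (1 - 0.02) * (1 - 0.92) * (1 - 0.90)
  seS <- sqrt(pShared * (1 - pShared) / n)
  expect_lt(abs(ms$sharedMissing["mycoA", "mycoB"] / n - pShared), 3 * seS)
})

test_that("short ORFs are removed at the 150 bp boundary", {
  cds <- c(short = strrep("ATG", 49), shorter = strrep("A", 149),
           exact = strrep("ATG", 50), long = strrep("ATG", 60))
  kept <- orfFilter(cds)
  expect_identical(sort(names(kept)), c("exact", "long"))
  expect_length(orfFilter(character(0)), 0)
  dss <- Biostrings::DNAStringSet(c(a = strrep("A", 149), b = strrep("A", 150)))
  expect_identical(names(orfFilter(dss)), "b")
})
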