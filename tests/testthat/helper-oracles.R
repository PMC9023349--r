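# Independent brute-force oracles used to check the package's computations.

oracleGeneticCode <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})

oracleSense <- names(oracleGeneticCode)[oracleGeneticCode != "*"]

# Synonymous site count of a codon: enumerate all nine single-nucleotide
# mutations; a mutation is synonymous iff it keeps the amino acid and does
# not create a stop.
oracleSynSites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  aa <- oracleGeneticCode[[codon]]
  total <- 0
  for (pos in 1:3) {
    syn <- 0
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (oracleGeneticCode[[mut]] == aa) syn <- syn + 1
    }
    total <- total + syn / 3
  }
  total
}

# Average synonymous/nonsynonymous differences between two sense codons by
# depth-first enumeration of all substitution orderings, skipping any path
# that passes through a stop codon. Returns NULL when no path is stop-free.
oraclePairDiffs <- function(c1, c2) {
  paths <- list()
  walk <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (oracleGeneticCode[[nxt]] == "*") next
      synStep <- oracleGeneticCode[[nxt]] == oracleGeneticCode[[cur]]
      walk(nxt, setdiff(remaining, p), sd + synStep, nd + !synStep)
    }
  }
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0) return(c(0, 0))
  walk(c1, pos, 0, 0)
  if (length(paths) == 0) return(NULL)
  colMeans(do.call(rbind, paths))
}

# Gotoh affine-gap global alignment score; a gap of length L costs
# open + ext * L (the same convention as the package aligner).
oracleGotohScore <- function(s1, s2, open = 10, ext = 0.5) {
  submat <- get(data("BLOSUM62", package = "Biostrings",
                     envir = environment()))
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  n <- length(a); m <- length(b); NEG <- -1e9
  g1 <- open + ext
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  if (n > 0) for (i in 2:(n + 1)) X[i, 1] <- -g1 - ext * (i - 2)
  if (m > 0) for (j in 2:(m + 1)) Y[1, j] <- -g1 - ext * (j - 2)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      sc <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
      X[i, j] <- max(M[i - 1, j] - g1, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - g1, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Exact hypergeometric upper tail P[X >= k] by direct combinatorial sum.
oracleHyperUpper <- function(k, K, N, n) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Reverse complement for plain character vectors.
revcompChar <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}
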