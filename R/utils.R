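# Shared internal helpers.

# Run code under a fixed RNG seed and restore the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero to `digits` decimals (printed-report style,
# as opposed to R's default round-half-even).
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assertProb <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must be a probability in [0, 1]", call. = FALSE)
  invisible(x)
}

assertCount <- function(x, what, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min)
    stop(what, " must be an integer >= ", min, call. = FALSE)
  invisible(as.integer(x))
}

# Sample from a zero-truncated Poisson whose *truncated* mean equals `mean`.
# The underlying rate lambda solves lambda / (1 - exp(-lambda)) = mean,
# which requires mean > 1.
rztpois <- function(n, mean) {
  if (mean <= 1) stop("zero-truncated Poisson mean must be > 1", call. = FALSE)
  lambda <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                           interval = c(1e-9, mean + 10), tol = 1e-12)$root
  p0 <- exp(-lambda)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qpois(u, lambda)
}

# Quartile-based box statistics with the 1.5 x IQR whisker rule:
# whiskers reach the most extreme data value within 1.5 IQR of the box.
boxStats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- x[x >= q[1] - 1.5 * iqr]
  hi <- x[x <= q[3] + 1.5 * iqr]
  list(median = q[2], q1 = q[1], q3 = q[3],
       whiskerLow = if (length(lo)) min(lo) else q[1],
       whiskerHigh = if (length(hi)) max(hi) else q[3],
       outliers = x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr])
}

# Minimal FASTA writer (60-column wrap) for plain character vectors.
writeFastaFile <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  nm <- names(seqs)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", nm[i]), con)
    s <- seqs[[i]]
    if (nchar(s) == 0) { next }
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
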