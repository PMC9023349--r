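#' KDE mode of a Ks distribution
#'
#' Gaussian kernel-density estimate on the filtered Ks values with Silverman
#' reference bandwidth (\code{bw.nrd0}), evaluated on a 512-point uniform
#' grid over the distribution's filter bounds; the mode is the grid point of
#' maximum density (ties broken toward the smallest Ks).
#'
#' @param dist A \linkS4class{KsDistribution} with at least 30 values.
#' @return list with \code{mode}, \code{bandwidth} and the density
#'   \code{grid} (data.frame x, y).
#' @export
kdeMode <- function(dist) {
  stopifnot(is(dist, "KsDistribution"))
  v <- ksValues(dist)
  if (length(v) < 30)
    stop("mode estimation requires n >= 30 Ks values (got ", length(v), ")",
         call. = FALSE)
  b <- filterBounds(dist)
  d <- stats::density(v, bw = "nrd0", n = 512, from = b[1], to = b[2])
  list(mode = d$x[which.max(d$y)], bandwidth = d$bw,
       grid = data.frame(x = d$x, y = d$y))
}

# mode of a resample, reusing the parent distribution's bounds
resampleMode <- function(values, bounds) {
  d <- stats::density(values, bw = "nrd0", n = 512, from = bounds[1],
                      to = bounds[2])
  d$x[which.max(d$y)]
}

#' Bootstrap mode estimate with 95 percent percentile interval
#'
#' Resamples the distribution with replacement \code{nBoot} times (default
#' 200), takes the KDE mode of each resample, and reports the median of the
#' bootstrap modes as point estimate with the 2.5/97.5 percentiles as the
#' confidence interval. Box statistics of the bootstrap modes (median,
#' quartiles, 1.5 x IQR whiskers, outliers) are attached for boxplot-style
#' summaries.
#'
#' @param dist A \linkS4class{KsDistribution}.
#' @param nBoot number of bootstrap resamples.
#' @param seed integer RNG seed; the caller's RNG state is untouched.
#' @return A \linkS4class{ModeEstimate}.
#' @export
bootstrapMode <- function(dist, nBoot = 200, seed = 1729) {
  full <- kdeMode(dist)
  v <- ksValues(dist)
  b <- filterBounds(dist)
  modes <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i)
      resampleMode(sample(v, length(v), replace = TRUE), b), numeric(1))
  })
  ci <- stats::quantile(modes, c(0.025, 0.975), names = FALSE, type = 7)
  new("ModeEstimate", mode = stats::median(modes), fullMode = full$mode,
      ciLow = ci[1], ciHigh = ci[2], nBoot = as.integer(nBoot),
      seed = as.integer(seed), bandwidth = full$bandwidth,
      bootModes = modes, boxplotStats = boxStats(modes))
}

#' Outgroup relative-rate decomposition
#'
#' Solves the three linear constraints of the unrooted (O, (A, B)) tree:
#' dA = (dAB + dOA - dOB)/2, dB = (dAB + dOB - dOA)/2,
#' dShared = (dOA + dOB - dAB)/2, so that dA + dB = dAB,
#' dA + dShared = dOA and dB + dShared = dOB hold by construction.
#' Negative outputs (triangle-inequality violations from noisy modes) are
#' permitted but flagged.
#'
#' @param dOA,dOB,dAB nonnegative pairwise mode distances.
#' @param taxa character(3): outgroup, species A, species B labels.
#' @return A \linkS4class{RateDecomposition}.
#' @export
relativeRate <- function(dOA, dOB, dAB, taxa = c("outgroup", "A", "B")) {
  if (any(!is.finite(c(dOA, dOB, dAB))) || any(c(dOA, dOB, dAB) < 0))
    stop("distances must be finite and nonnegative", call. = FALSE)
  dA <- (dAB + dOA - dOB) / 2
  dB <- (dAB + dOB - dOA) / 2
  dS <- (dOA + dOB - dAB) / 2
  flags <- character(0)
  if (any(c(dA, dB, dS) < 0)) flags <- "triangle_violation"
  new("RateDecomposition", taxa = as.character(taxa),
      inputs = c(dOA = dOA, dOB = dOB, dAB = dAB),
      dA = dA, dB = dB, dShared = dS,
      ci = matrix(numeric(0), 0, 2), flags = flags)
}

#' Relative-rate decomposition with joint bootstrap CIs
#'
#' Per replicate, each of the three Ks distributions is independently
#' resampled with replacement, the three KDE modes recomputed, and the
#' decomposition applied; 95 percent percentile intervals on dA, dB and
#' dShared are taken over replicates. The point estimate decomposes the
#' medians of the per-distribution bootstrap modes (so the three linear
#' identities hold exactly for the reported values).
#'
#' @param distOA,distOB,distAB \linkS4class{KsDistribution}s for the
#'   outgroup-A, outgroup-B and A-B species pairs.
#' @param nBoot number of bootstrap replicates (default 200).
#' @param seed integer RNG seed.
#' @param taxa character(3) labels: outgroup, A, B.
#' @return A \linkS4class{RateDecomposition} with a filled \code{ci} slot.
#' @export
relativeRateBootstrap <- function(distOA, distOB, distAB, nBoot = 200,
                                  seed = 1729, taxa = c("outgroup", "A", "B")) {
  dists <- list(distOA, distOB, distAB)
  lapply(dists, kdeMode)  # validates n >= 30 up front
  reps <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      m <- vapply(dists, function(d) {
        v <- ksValues(d)
        resampleMode(sample(v, length(v), replace = TRUE), filterBounds(d))
      }, numeric(1))
      c((m[3] + m[1] - m[2]) / 2, (m[3] + m[2] - m[1]) / 2,
        (m[1] + m[2] - m[3]) / 2, m)
    }, numeric(6))
  })
  med <- apply(reps[4:6, , drop = FALSE], 1, stats::median)
  out <- relativeRate(med[1], med[2], med[3], taxa)
  ci <- t(apply(reps[1:3, , drop = FALSE], 1,
                stats::quantile, probs = c(0.025, 0.975), names = FALSE))
  dimnames(ci) <- list(c("dA", "dB", "dShared"), c("low", "high"))
  out@ci <- ci
  out
}
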