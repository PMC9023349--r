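#' Jukes-Cantor distance between two aligned sequences
#'
#' Columns where either sequence has a gap (\code{-}) or ambiguous base
#' (\code{N}) are excluded from both numerator and denominator. The
#' multiple-hit corrected distance is d = -(3/4) log(1 - 4p/3); at
#' p >= 3/4 the correction is undefined and d is returned as NA with a
#' saturation flag.
#'
#' @param seq1,seq2 equal-length aligned nucleotide strings.
#' @return list with \code{p} (mismatch proportion), \code{d} (JC distance),
#'   \code{nCompared} (columns compared) and \code{saturated} (logical).
#' @export
jcDistance <- function(seq1, seq2) {
  s1 <- strsplit(toupper(as.character(seq1)), "")[[1]]
  s2 <- strsplit(toupper(as.character(seq2)), "")[[1]]
  if (length(s1) != length(s2))
    stop("sequences must have equal aligned length", call. = FALSE)
  ok <- s1 %in% NUCS & s2 %in% NUCS
  n <- sum(ok)
  if (n == 0) stop("no comparable (ungapped, unambiguous) sites", call. = FALSE)
  p <- sum(s1[ok] != s2[ok]) / n
  if (p >= 0.75)
    return(list(p = p, d = NA_real_, nCompared = n, saturated = TRUE))
  list(p = p, d = -0.75 * log(1 - 4 * p / 3), nCompared = n, saturated = FALSE)
}

#' Lineage substitution rate from a calibrated divergence
#'
#' r = d / (2 t): the per-branch substitution rate implied by a pairwise
#' genetic distance \code{d} accumulated over \code{t} years on each of the
#' two branches since divergence.
#'
#' @param d genetic distance (substitutions/site), >= 0.
#' @param t divergence time in years, > 0.
#' @return rate in substitutions/site/year.
#' @export
substitutionRate <- function(d, t) {
  if (any(d < 0)) stop("d must be nonnegative", call. = FALSE)
  if (any(t <= 0)) stop("t must be positive (years)", call. = FALSE)
  d / (2 * t)
}

#' LTR insertion time from 5'/3' LTR divergence
#'
#' At insertion the two LTRs of a retrotransposon are identical; their
#' subsequent divergence K dates the insertion as T = K / (2 r) years.
#'
#' @param K Jukes-Cantor distance between the element's two LTRs, >= 0.
#' @param r substitution rate in substitutions/site/year, > 0.
#' @return insertion time in years.
#' @export
insertionTime <- function(K, r) {
  if (any(K < 0)) stop("K must be nonnegative", call. = FALSE)
  if (any(r <= 0)) stop("rate must be positive", call. = FALSE)
  K / (2 * r)
}

#' Read aligned 5'/3' LTR pairs from FASTA
#'
#' Expects two records per element, named \code{<id>_5} and \code{<id>_3}.
#'
#' @param path FASTA file.
#' @return named list of character(2) vectors (5' then 3') per element id.
#' @export
readLtrPairs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  id <- sub("_[53]$", "", nm)
  end <- sub("^.*_([53])$", "\\1", nm)
  if (any(!end %in% c("5", "3")))
    stop("LTR records must be named <id>_5 / <id>_3", call. = FALSE)
  out <- list()
  for (el in unique(id)) {
    i5 <- which(id == el & end == "5")
    i3 <- which(id == el & end == "3")
    if (length(i5) != 1 || length(i3) != 1)
      stop("element ", el, " does not have exactly one 5' and one 3' LTR",
           call. = FALSE)
    out[[el]] <- c(as.character(seqs[[i5]]), as.character(seqs[[i3]]))
  }
  out
}

#' Date LTR insertions for a set of elements
#'
#' Computes per element the mismatch proportion p, the Jukes-Cantor distance
#' K and the insertion time T = K/(2r), reported in Ma.
#'
#' @param pairs list as returned by \code{\link{readLtrPairs}}, or a
#'   data.frame with columns \code{element} and \code{K}.
#' @param rate substitution rate in substitutions/site/year.
#' @return data.frame: element, p, K, T_Ma, saturated.
#' @export
ltrInsertionTimes <- function(pairs, rate) {
  if (is.data.frame(pairs)) {
    if (!all(c("element", "K") %in% names(pairs)))
      stop("data.frame input needs columns element, K", call. = FALSE)
    return(data.frame(element = pairs$element, p = NA_real_, K = pairs$K,
                      T_Ma = insertionTime(pairs$K, rate) / 1e6,
                      saturated = FALSE, stringsAsFactors = FALSE))
  }
  rows <- lapply(names(pairs), function(el) {
    jc <- jcDistance(pairs[[el]][1], pairs[[el]][2])
    data.frame(element = el, p = jc$p, K = jc$d,
               T_Ma = if (jc$saturated) NA_real_ else
                 insertionTime(jc$d, rate) / 1e6,
               saturated = jc$saturated, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fraction of insertions younger than a threshold, plus an age histogram
#'
#' "Occurred before x Ma" is read as T < x Ma, i.e. more recent than x
#' million years ago.
#'
#' @param timesMa insertion times in Ma (NA entries dropped).
#' @param thresholdMa age threshold in Ma.
#' @param binWidth histogram bin width in Ma (default 0.1).
#' @return list with \code{fraction} and \code{histogram} (data.frame
#'   bin_start_Ma, bin_end_Ma, n).
#' @export
eraFraction <- function(timesMa, thresholdMa, binWidth = 0.1) {
  timesMa <- timesMa[is.finite(timesMa)]
  if (length(timesMa) == 0) stop("no insertion times supplied", call. = FALSE)
  breaks <- seq(0, max(timesMa, binWidth) + binWidth, by = binWidth)
  h <- graphics::hist(timesMa, breaks = breaks, plot = FALSE, right = FALSE)
  list(fraction = mean(timesMa < thresholdMa),
       histogram = data.frame(bin_start_Ma = utils::head(h$breaks, -1),
                              bin_end_Ma = h$breaks[-1], n = h$counts))
}
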