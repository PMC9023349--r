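#' @import methods
NULL

#' Gene-family count matrix
#'
#' Orthogroup-by-species table of nonnegative gene counts, the substrate of
#' the F-index gene-loss analysis. Rows are gene families (orthogroups),
#' columns are species.
#'
#' @slot counts integer matrix, families x species, with unique dimnames.
#' @export
setClass("GeneFamilyCounts", representation(counts = "matrix"))

setValidity("GeneFamilyCounts", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("counts must have family (row) and species (column) names")
  if (anyDuplicated(rownames(m))) return("duplicate family ids")
  if (anyDuplicated(colnames(m))) return("duplicate species ids")
  if (!is.numeric(m) || any(is.na(m))) return("counts must be numeric and non-missing")
  if (any(m < 0) || any(m != round(m))) return("counts must be nonnegative integers")
  TRUE
})

#' Construct a GeneFamilyCounts object
#'
#' @param counts numeric matrix of nonnegative gene counts; rows are gene
#'   families, columns are species, both named.
#' @return A \linkS4class{GeneFamilyCounts} object.
#' @examples
#' m <- matrix(c(2L, 0L, 1L, 3L), 2, 2,
#'             dimnames = list(c("OG1", "OG2"), c("spA", "spB")))
#' GeneFamilyCounts(m)
#' @export
GeneFamilyCounts <- function(counts) {
  storage.mode(counts) <- "integer"
  new("GeneFamilyCounts", counts = counts)
}

#' K-mer frequency-of-frequencies histogram
#'
#' Stores, for each multiplicity (sequencing depth of a k-mer), the number of
#' distinct canonical k-mers observed at that multiplicity, plus the total
#' number of counted k-mer instances.
#'
#' @slot k odd integer, the k-mer size.
#' @slot entries data.frame with columns \code{multiplicity} and
#'   \code{n_distinct}, sorted by multiplicity.
#' @slot totalKmers numeric, total counted k-mer instances
#'   (\code{sum(multiplicity * n_distinct)}).
#' @export
setClass("KmerHistogram",
         representation(k = "integer", entries = "data.frame",
                        totalKmers = "numeric"))

setValidity("KmerHistogram", function(object) {
  e <- object@entries
  if (!all(c("multiplicity", "n_distinct") %in% names(e)))
    return("entries needs columns multiplicity, n_distinct")
  if (nrow(e) > 0 && any(e$multiplicity < 1)) return("multiplicities must be >= 1")
  if (anyDuplicated(e$multiplicity)) return("duplicate multiplicities")
  tot <- sum(e$multiplicity * e$n_distinct)
  if (!isTRUE(all.equal(tot, object@totalKmers)))
    return("totalKmers inconsistent with entries")
  TRUE
})

#' A set of per-ortholog Ks values for one species pair
#'
#' Values are filtered to \code{filterBounds} on construction; the bounds
#' guard against near-zero artefacts and saturated (Ks >> 1) estimates.
#'
#' @slot speciesPair character(2), ordered species identifiers.
#' @slot values numeric, Ks values inside the bounds.
#' @slot filterBounds numeric(2), (low, high) retention interval.
#' @export
setClass("KsDistribution",
         representation(speciesPair = "character", values = "numeric",
                        filterBounds = "numeric"))

setValidity("KsDistribution", function(object) {
  if (length(object@speciesPair) != 2) return("speciesPair must have length 2")
  if (length(object@filterBounds) != 2 ||
      object@filterBounds[1] >= object@filterBounds[2])
    return("filterBounds must be (low, high) with low < high")
  v <- object@values
  if (any(v < object@filterBounds[1] | v > object@filterBounds[2]))
    return("values outside filterBounds")
  TRUE
})

#' Construct a KsDistribution
#'
#' @param values numeric Ks values; entries outside \code{bounds} (and
#'   non-finite entries) are dropped.
#' @param speciesPair character(2) species identifiers.
#' @param bounds numeric(2) retention interval, default \code{c(0.01, 5)}.
#' @return A \linkS4class{KsDistribution}.
#' @export
KsDistribution <- function(values, speciesPair = c("A", "B"),
                           bounds = c(0.01, 5)) {
  values <- values[is.finite(values) & values >= bounds[1] & values <= bounds[2]]
  new("KsDistribution", speciesPair = as.character(speciesPair),
      values = as.numeric(values), filterBounds = as.numeric(bounds))
}

#' Bootstrap KDE-mode estimate of a Ks distribution
#'
#' @slot mode numeric, point estimate (median of bootstrap modes).
#' @slot fullMode numeric, KDE mode of the full (unresampled) sample.
#' @slot ciLow,ciHigh numeric, 2.5/97.5 bootstrap percentiles.
#' @slot nBoot integer, number of bootstrap resamples.
#' @slot seed integer, RNG seed used.
#' @slot bandwidth numeric, Silverman bandwidth of the full sample.
#' @slot bootModes numeric, the bootstrap replicate modes.
#' @slot boxplotStats list with median, q1, q3, whiskerLow, whiskerHigh,
#'   outliers computed on the bootstrap modes (1.5 x IQR whisker rule).
#' @export
setClass("ModeEstimate",
         representation(mode = "numeric", fullMode = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        nBoot = "integer", seed = "integer",
                        bandwidth = "numeric", bootModes = "numeric",
                        boxplotStats = "list"))

#' Outgroup relative-rate decomposition of three pairwise Ks distances
#'
#' Given mode distances d(O,A), d(O,B) and d(A,B) for an outgroup O and two
#' ingroup species A and B, the three linear constraints of the unrooted
#' three-taxon tree give branch-specific distances dA, dB (since the A/B
#' split) and dShared (outgroup to the split).
#'
#' @slot taxa character(3): outgroup, species A, species B.
#' @slot inputs numeric(3): d_OA, d_OB, d_AB.
#' @slot dA,dB,dShared numeric branch distances.
#' @slot ci numeric matrix (3 x 2; rows dA, dB, dShared) of bootstrap 95
#'   percent intervals, or a 0-row matrix when no bootstrap was run.
#' @slot flags character, e.g. "triangle_violation" when a branch distance
#'   is negative (noise in the input modes).
#' @export
setClass("RateDecomposition",
         representation(taxa = "character", inputs = "numeric",
                        dA = "numeric", dB = "numeric", dShared = "numeric",
                        ci = "matrix", flags = "character"))

#' Gap-free paired in-frame codon alignment
#'
#' The substrate of NG86 counting: two equal-length nucleotide strings whose
#' length is a multiple of 3, with no gap characters and no internal stop
#' codons.
#'
#' @slot seq1,seq2 character(1) codon sequences.
#' @export
setClass("CodonAlignment", representation(seq1 = "character", seq2 = "character"))

setValidity("CodonAlignment", function(object) {
  s1 <- object@seq1; s2 <- object@seq2
  if (length(s1) != 1 || length(s2) != 1) return("seq1/seq2 must be single strings")
  if (nchar(s1) != nchar(s2)) return("sequences must have equal length")
  if (nchar(s1) %% 3 != 0) return("length must be a multiple of 3")
  if (grepl("-", s1, fixed = TRUE) || grepl("-", s2, fixed = TRUE))
    return("gap characters are not allowed")
  for (s in c(s1, s2)) {
    cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (any(cod %in% c("TAA", "TAG", "TGA")))
      return("internal stop codon present")
  }
  TRUE
})

#' Construct a CodonAlignment
#'
#' @param seq1,seq2 character(1) gap-free in-frame nucleotide sequences of
#'   equal length.
#' @return A \linkS4class{CodonAlignment}.
#' @export
CodonAlignment <- function(seq1, seq2) {
  new("CodonAlignment", seq1 = toupper(as.character(seq1)),
      seq2 = toupper(as.character(seq2)))
}
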