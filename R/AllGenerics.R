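#' @rdname GeneFamilyCounts-class
#' @param x a package object.
#' @export
setGeneric("familyIds", function(x) standardGeneric("familyIds"))

#' @rdname GeneFamilyCounts-class
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname GeneFamilyCounts-class
#' @export
setGeneric("geneCounts", function(x) standardGeneric("geneCounts"))

#' @rdname KsDistribution-class
#' @param x a package object.
#' @export
setGeneric("ksValues", function(x) standardGeneric("ksValues"))

#' @rdname KsDistribution-class
#' @export
setGeneric("filterBounds", function(x) standardGeneric("filterBounds"))

#' @rdname ModeEstimate-class
#' @param x a package object.
#' @export
setGeneric("modeCI", function(x) standardGeneric("modeCI"))

#' @rdname ModeEstimate-class
#' @export
setGeneric("bootModes", function(x) standardGeneric("bootModes"))

#' @rdname RateDecomposition-class
#' @param x a package object.
#' @export
setGeneric("branchDistances", function(x) standardGeneric("branchDistances"))

#' Accessors

#' @rdname GeneFamilyCounts-class
#' @export
setMethod("familyIds", "GeneFamilyCounts", function(x) rownames(x@counts))

#' @rdname GeneFamilyCounts-class
#' @export
setMethod("speciesIds", "GeneFamilyCounts", function(x) colnames(x@counts))

#' @rdname GeneFamilyCounts-class
#' @export
setMethod("geneCounts", "GeneFamilyCounts", function(x) x@counts)

#' @rdname KsDistribution-class
#' @export
setMethod("ksValues", "KsDistribution", function(x) x@values)

#' @rdname KsDistribution-class
#' @export
setMethod("filterBounds", "KsDistribution", function(x) x@filterBounds)

#' @rdname ModeEstimate-class
#' @export
setMethod("modeCI", "ModeEstimate", function(x) c(low = x@ciLow, high = x@ciHigh))

#' @rdname ModeEstimate-class
#' @export
setMethod("bootModes", "ModeEstimate", function(x) x@bootModes)

#' @rdname RateDecomposition-class
#' @export
setMethod("branchDistances", "RateDecomposition",
          function(x) c(dA = x@dA, dB = x@dB, dShared = x@dShared))

setMethod("show", "GeneFamilyCounts", function(object) {
  m <- object@counts
  cat("GeneFamilyCounts:", nrow(m), "families x", ncol(m), "species\n")
  cat("  species:", paste(utils::head(colnames(m), 6), collapse = ", "),
      if (ncol(m) > 6) "..." else "", "\n")
  cat("  missing cells:", sum(m == 0), sprintf("(%.1f%%)\n", 100 * mean(m == 0)))
})

setMethod("show", "KmerHistogram", function(object) {
  cat("KmerHistogram: k =", object@k, "\n")
  cat("  distinct multiplicities:", nrow(object@entries), "\n")
  cat("  total k-mer instances:", format(object@totalKmers, big.mark = ","), "\n")
})

setMethod("show", "KsDistribution", function(object) {
  cat("KsDistribution:", paste(object@speciesPair, collapse = " vs "), "\n")
  cat("  n =", length(object@values), "values in [",
      object@filterBounds[1], ",", object@filterBounds[2], "]\n")
  if (length(object@values))
    cat("  median Ks =", signif(stats::median(object@values), 4), "\n")
})

setMethod("show", "ModeEstimate", function(object) {
  cat("ModeEstimate: mode =", signif(object@mode, 4),
      sprintf("[95%% CI %.4g, %.4g]", object@ciLow, object@ciHigh), "\n")
  cat("  ", object@nBoot, "bootstrap resamples, bandwidth =",
      signif(object@bandwidth, 4), ", seed =", object@seed, "\n")
})

setMethod("show", "RateDecomposition", function(object) {
  cat("RateDecomposition: outgroup", object@taxa[1], "; ingroup",
      object@taxa[2], "/", object@taxa[3], "\n")
  cat(sprintf("  dA = %.4g  dB = %.4g  dShared = %.4g\n",
              object@dA, object@dB, object@dShared))
  if (nrow(object@ci) > 0) {
    for (b in rownames(object@ci))
      cat(sprintf("  %s 95%% CI [%.4g, %.4g]\n", b,
                  object@ci[b, 1], object@ci[b, 2]))
  }
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", nchar(object@seq1) / 3, "codons\n")
})
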