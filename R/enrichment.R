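#' One-sided hypergeometric over-representation test
#'
#' For each term with at least one study-set hit, computes the upper-tail
#' probability P[X >= k] of drawing k or more of the term's K genes when
#' sampling the study set of size n from the universe of size N (exact,
#' evaluated in log space via \code{phyper}), and Bonferroni-adjusts over
#' the number of terms actually tested. Terms with k = 0 are skipped.
#'
#' @param studySet character vector of gene ids (e.g. lost families); must
#'   be a subset of \code{universe}.
#' @param termMap data.frame with columns \code{term} and \code{gene}.
#' @param universe character vector of all gene ids.
#' @return data.frame sorted by p_bonf then term id: term, k, n, K, N, p,
#'   p_bonf.
#' @export
hypergeomEnrich <- function(studySet, termMap, universe) {
  studySet <- unique(as.character(studySet))
  universe <- unique(as.character(universe))
  if (!all(c("term", "gene") %in% names(termMap)))
    stop("termMap needs columns term, gene", call. = FALSE)
  outside <- setdiff(studySet, universe)
  if (length(outside))
    stop("study gene not in universe: ", outside[1], call. = FALSE)
  outsideT <- setdiff(unique(termMap$gene), universe)
  if (length(outsideT))
    stop("annotated gene not in universe: ", outsideT[1], call. = FALSE)
  if (length(studySet) == 0) {
    message("empty study set: no test performed")
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_bonf = numeric(0)))
  }
  N <- length(universe)
  n <- length(studySet)
  terms <- sort(unique(as.character(termMap$term)))
  genesOf <- lapply(terms, function(t)
    unique(termMap$gene[termMap$term == t]))
  K <- vapply(genesOf, length, integer(1))
  k <- vapply(genesOf, function(g) length(intersect(g, studySet)), integer(1))
  tested <- k >= 1
  if (!any(tested)) {
    message("no term overlaps the study set: no test performed")
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_bonf = numeric(0)))
  }
  p <- stats::phyper(k[tested] - 1, K[tested], N - K[tested], n,
                     lower.tail = FALSE)
  out <- data.frame(term = terms[tested], k = k[tested], n = n,
                    K = K[tested], N = N, p = p,
                    p_bonf = bonferroni(p), stringsAsFactors = FALSE)
  out[order(out$p_bonf, out$term), , drop = FALSE]
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the number of tests and capped at 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return adjusted p-values.
#' @export
bonferroni <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni")
}
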