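#' Read a 12-column BLAST/DIAMOND tabular hit file
#'
#' Parses the standard outfmt-6 dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Coordinates are 1-based
#' inclusive.
#'
#' @param path path to a tab-separated hit table without header.
#' @return data.frame with the 12 standard columns.
#' @export
readBlastTab <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  dt <- tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE),
    error = function(e) stop("malformed hit table '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(dt) != 12)
    stop("malformed hit table '", path, "': expected 12 columns, got ",
         ncol(dt), call. = FALSE)
  names(dt) <- cols
  if (any(dt$evalue < 0)) stop("negative e-value in ", path, call. = FALSE)
  dt
}

bestHitPerQuery <- function(hits) {
  # highest bit score, then lowest e-value, then smallest subject id
  o <- order(hits$qseqid, -hits$bitscore, hits$evalue, hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$qseqid), c("qseqid", "sseqid"), drop = FALSE]
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is retained iff a's best hit in the A-to-B table is b, b's
#' best hit in the B-to-A table is a, and both hits pass the e-value cutoff.
#' Per query the best hit is the highest bit score, ties broken by lowest
#' e-value, then lexicographically smallest subject id.
#'
#' @param hitsAB,hitsBA data.frames as returned by \code{\link{readBlastTab}}.
#' @param maxEvalue e-value cutoff; hits with \code{evalue >= maxEvalue} are
#'   discarded (default 1e-5).
#' @return data.frame with columns \code{geneA}, \code{geneB}.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA, maxEvalue = 1e-5) {
  ab <- hitsAB[hitsAB$evalue < maxEvalue, , drop = FALSE]
  ba <- hitsBA[hitsBA$evalue < maxEvalue, , drop = FALSE]
  if (nrow(ab) == 0 || nrow(ba) == 0)
    return(data.frame(geneA = character(0), geneB = character(0)))
  bestAB <- bestHitPerQuery(ab)
  bestBA <- bestHitPerQuery(ba)
  back <- stats::setNames(bestBA$sseqid, bestBA$qseqid)
  keep <- !is.na(back[bestAB$sseqid]) & back[bestAB$sseqid] == bestAB$qseqid
  keep[is.na(keep)] <- FALSE
  out <- data.frame(geneA = bestAB$qseqid[keep], geneB = bestAB$sseqid[keep],
                    stringsAsFactors = FALSE)
  out[order(out$geneA), , drop = FALSE]
}

#' Global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under BLOSUM62 with affine gap cost
#' 10 + 0.5 per gapped residue, computed by
#' \code{Biostrings::pairwiseAlignment}. Deterministic: identical inputs give
#' identical alignments.
#'
#' @param seq1,seq2 character(1) amino-acid sequences.
#' @return list with \code{aligned1}, \code{aligned2} (gapped strings) and
#'   \code{score}.
#' @export
alignProteinsGlobal <- function(seq1, seq2) {
  if (nchar(seq1) == 0 || nchar(seq2) == 0)
    stop("cannot align an empty sequence", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq1), Biostrings::AAString(seq2),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  list(aligned1 = as.character(Biostrings::alignedPattern(pa)),
       aligned2 = as.character(Biostrings::alignedSubject(pa)),
       score = Biostrings::score(pa))
}

stripTerminalStop <- function(cds) {
  if (nchar(cds) %% 3 == 0 && nchar(cds) >= 3) {
    last <- substr(cds, nchar(cds) - 2, nchar(cds))
    if (last %in% STOP_CODONS) return(substr(cds, 1, nchar(cds) - 3))
  }
  cds
}

#' Back-translate an aligned protein pair to a gap-free codon alignment
#'
#' Maps every aligned residue pair to its codon pair and removes columns with
#' a gap in either sequence. Each CDS must translate exactly to its ungapped
#' protein under the standard genetic code (a terminal stop codon, if
#' present, is stripped first).
#'
#' @param aligned1,aligned2 gapped amino-acid strings of equal length.
#' @param cds1,cds2 the corresponding coding sequences.
#' @return A \linkS4class{CodonAlignment}.
#' @export
backTranslate <- function(aligned1, aligned2, cds1, cds2) {
  if (nchar(aligned1) != nchar(aligned2))
    stop("aligned sequences must have equal length", call. = FALSE)
  cds1 <- stripTerminalStop(toupper(cds1))
  cds2 <- stripTerminalStop(toupper(cds2))
  checkOne <- function(aln, cds, label) {
    prot <- gsub("-", "", aln, fixed = TRUE)
    if (nchar(cds) != 3 * nchar(prot))
      stop("CDS length of ", label, " (", nchar(cds),
           ") is not 3x its protein length (", nchar(prot), ")", call. = FALSE)
    gc <- codonTable()
    cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    tr <- unname(gc[cod])
    tr[is.na(tr)] <- "X"
    pr <- strsplit(prot, "")[[1]]
    bad <- which(tr != pr & pr != "X")
    if (length(bad))
      stop("translation mismatch in ", label, " at codon ", bad[1], " (",
           cod[bad[1]], " -> ", tr[bad[1]], ", protein has ", pr[bad[1]], ")",
           call. = FALSE)
    cod
  }
  cod1 <- checkOne(aligned1, cds1, "sequence 1")
  cod2 <- checkOne(aligned2, cds2, "sequence 2")
  a1 <- strsplit(aligned1, "")[[1]]
  a2 <- strsplit(aligned2, "")[[1]]
  i1 <- cumsum(a1 != "-")
  i2 <- cumsum(a2 != "-")
  keep <- a1 != "-" & a2 != "-"
  CodonAlignment(paste(cod1[i1[keep]], collapse = ""),
                 paste(cod2[i2[keep]], collapse = ""))
}

#' NG86 synonymous/nonsynonymous estimation on a codon alignment
#'
#' Counts synonymous sites and differences per Nei & Gojobori (1986):
#' synonymous site fractions are averaged over the two sequences; differences
#' are averaged over all substitution orderings per codon pair, orderings
#' through stop codons excluded; mutations to stops count as nonsynonymous
#' sites. The proportions are Jukes-Cantor corrected,
#' Ks = -(3/4) log(1 - 4 pS / 3) (undefined at pS >= 3/4, flagged
#' "saturated"), and analogously for Ka.
#'
#' Codon pairs containing an ambiguous base (N) and pairs whose every
#' substitution pathway crosses a stop codon are excluded from counting; the
#' number excluded is reported in \code{flags}.
#'
#' @param aln A \linkS4class{CodonAlignment}.
#' @return one-row data.frame with n_codons, syn_sites, nonsyn_sites,
#'   syn_diffs, nonsyn_diffs, pS, pN, Ks, Ka and a flags string.
#' @export
ng86Ks <- function(aln) {
  stopifnot(is(aln, "CodonAlignment"))
  tab <- ng86Tables()
  n <- nchar(aln@seq1) / 3
  starts <- seq(1, by = 3, length.out = n)
  cod1 <- substring(aln@seq1, starts, starts + 2)
  cod2 <- substring(aln@seq2, starts, starts + 2)
  i1 <- match(cod1, tab$sense)
  i2 <- match(cod2, tab$sense)
  usable <- !is.na(i1) & !is.na(i2)
  flags <- character(0)
  nAmbig <- sum(!usable)
  if (nAmbig > 0) flags <- c(flags, sprintf("ambiguous_codons=%d", nAmbig))
  idx <- cbind(i1[usable], i2[usable])
  pathOk <- tab$valid[idx]
  if (any(!pathOk)) {
    warning(sum(!pathOk), " codon pair(s) excluded: every substitution ",
            "pathway crosses a stop codon")
    flags <- c(flags, sprintf("stop_blocked_pairs=%d", sum(!pathOk)))
    idx <- idx[pathOk, , drop = FALSE]
  }
  nUsed <- nrow(idx)
  if (nUsed == 0) {
    return(data.frame(n_codons = 0, syn_sites = 0, nonsyn_sites = 0,
                      syn_diffs = 0, nonsyn_diffs = 0, pS = NA_real_,
                      pN = NA_real_, Ks = NA_real_, Ka = NA_real_,
                      flags = paste(c(flags, "empty"), collapse = ";")))
  }
  sBar <- (sum(tab$sites[idx[, 1]]) + sum(tab$sites[idx[, 2]])) / 2
  nBar <- 3 * nUsed - sBar
  sd <- sum(tab$sd[idx])
  nd <- sum(tab$nd[idx])
  pS <- sd / sBar
  pN <- nd / nBar
  jc <- function(p) if (is.finite(p) && p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)
  if (is.finite(pS) && pS >= 0.75) flags <- c(flags, "saturated_Ks")
  if (is.finite(pN) && pN >= 0.75) flags <- c(flags, "saturated_Ka")
  data.frame(n_codons = nUsed, syn_sites = sBar, nonsyn_sites = nBar,
             syn_diffs = sd, nonsyn_diffs = nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Ks for every ortholog pair of two CDS sets
#'
#' Convenience wrapper: for each (geneA, geneB) pair, align the proteins
#' globally, back-translate to codons, and run \code{\link{ng86Ks}}.
#'
#' @param pairs data.frame with columns geneA, geneB (e.g. from
#'   \code{\link{reciprocalBestHits}}).
#' @param cdsA,cdsB named character vectors (or \code{DNAStringSet}) of
#'   coding sequences.
#' @param pepA,pepB optional named protein vectors; translated from the CDS
#'   when omitted.
#' @return data.frame: geneA, geneB plus the \code{\link{ng86Ks}} columns.
#' @export
ksForPairs <- function(pairs, cdsA, cdsB, pepA = NULL, pepB = NULL) {
  cdsA <- asCharSeqs(cdsA); cdsB <- asCharSeqs(cdsB)
  translateCds <- function(cds) {
    cds <- stripTerminalStop(cds)
    gc <- codonTable()
    cod <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    paste(unname(gc[cod]), collapse = "")
  }
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ga <- pairs$geneA[i]; gb <- pairs$geneB[i]
    if (!ga %in% names(cdsA)) stop("gene ", ga, " absent from cdsA", call. = FALSE)
    if (!gb %in% names(cdsB)) stop("gene ", gb, " absent from cdsB", call. = FALSE)
    pa <- if (is.null(pepA)) translateCds(cdsA[[ga]]) else asCharSeqs(pepA)[[ga]]
    pb <- if (is.null(pepB)) translateCds(cdsB[[gb]]) else asCharSeqs(pepB)[[gb]]
    al <- alignProteinsGlobal(pa, pb)
    ca <- backTranslate(al$aligned1, al$aligned2, cdsA[[ga]], cdsB[[gb]])
    rows[[i]] <- cbind(data.frame(geneA = ga, geneB = gb,
                                  stringsAsFactors = FALSE), ng86Ks(ca))
  }
  do.call(rbind, rows)
}

asCharSeqs <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    return(out)
  }
  if (is.character(x)) return(x)
  stop("expected a character vector or XStringSet", call. = FALSE)
}

#' Import externally computed Ks values
#'
#' Reads a TSV with columns geneA, geneB, Ks (for example CODEML output
#' reshaped to a table) and returns the usable Ks values; negative and
#' non-numeric entries are dropped with a message.
#'
#' @param path TSV file with a header row.
#' @param speciesPair character(2) labels for the resulting distribution.
#' @param bounds Ks retention bounds passed to \code{\link{KsDistribution}}.
#' @return A \linkS4class{KsDistribution}.
#' @export
importKsTable <- function(path, speciesPair = c("A", "B"), bounds = c(0.01, 5)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("geneA", "geneB", "Ks")
  if (!all(need %in% names(df)))
    stop("Ks table must have columns geneA, geneB, Ks", call. = FALSE)
  if (nrow(df) == 0) warning("empty Ks table: ", path)
  ks <- suppressWarnings(as.numeric(df$Ks))
  bad <- sum(!is.finite(ks) | ks < 0)
  if (bad > 0) message(bad, " row(s) with negative or non-numeric Ks dropped")
  KsDistribution(ks[is.finite(ks) & ks >= 0], speciesPair, bounds)
}
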