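# k-mer counting and genome-size estimation.

#' Count canonical k-mers in a read set
#'
#' Counts every k-long window over {A,C,G,T}; windows containing any other
#' character (N, separators) are skipped. Counting is canonical: each window
#' is recorded as the lexicographic minimum of itself and its reverse
#' complement, so the histogram is strand-symmetric. k-mers are 2-bit encoded
#' into doubles (exact up to k = 26) and tallied with data.table.
#'
#' @param reads \code{DNAStringSet}, character vector, or path to a
#'   FASTA/FASTQ file (gzip accepted).
#' @param k odd k-mer size between 3 and 26 (the 2-bit double encoding is
#'   exact up to 4^26; small odd k is allowed for hand-checkable examples);
#'   default 17.
#' @return A \linkS4class{KmerHistogram}.
#' @export
countKmers <- function(reads, k = 17) {
  if (k %% 2 == 0 || k < 3 || k > 26)
    stop("k must be odd and in [3, 26]", call. = FALSE)
  reads <- asReadChars(reads)
  if (length(reads) == 0 || sum(nchar(reads)) == 0)
    return(new("KmerHistogram", k = as.integer(k),
               entries = data.frame(multiplicity = integer(0),
                                    n_distinct = integer(0)),
               totalKmers = 0))
  # one long base-code vector; reads separated by an invalid code so no
  # window spans two reads
  s <- paste(toupper(reads), collapse = "N")
  codes <- utf8ToInt(s)
  lut <- rep(NA_real_, 128)
  lut[utf8ToInt("A")] <- 0; lut[utf8ToInt("C")] <- 1
  lut[utf8ToInt("G")] <- 2; lut[utf8ToInt("T")] <- 3
  b <- lut[codes]
  if (length(b) < k)
    return(new("KmerHistogram", k = as.integer(k),
               entries = data.frame(multiplicity = integer(0),
                                    n_distinct = integer(0)),
               totalKmers = 0))
  # windows ending at i: forward code reads left-to-right (high power first)
  fwd <- stats::filter(b, 4^(0:(k - 1)), method = "convolution", sides = 1)
  rc <- stats::filter(3 - b, 4^((k - 1):0), method = "convolution", sides = 1)
  canon <- pmin(as.numeric(fwd), as.numeric(rc))
  canon <- canon[!is.na(canon)]
  if (length(canon) == 0)
    return(new("KmerHistogram", k = as.integer(k),
               entries = data.frame(multiplicity = integer(0),
                                    n_distinct = integer(0)),
               totalKmers = 0))
  code <- NULL; N <- NULL  # appease R CMD check
  perKmer <- data.table::data.table(code = canon)[, .N, by = code]
  fof <- perKmer[, .N, by = "N"]
  names(fof) <- c("multiplicity", "n_distinct")
  fof <- as.data.frame(fof[order(fof$multiplicity)])
  new("KmerHistogram", k = as.integer(k), entries = fof,
      totalKmers = sum(as.numeric(fof$multiplicity) * fof$n_distinct))
}

asReadChars <- function(reads) {
  if (is(reads, "XStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    first <- substr(readLines(reads, n = 1), 1, 1)
    fmt <- if (identical(first, "@")) "fastq" else "fasta"
    return(as.character(Biostrings::readDNAStringSet(reads, format = fmt)))
  }
  if (is.character(reads)) return(reads)
  stop("reads must be a DNAStringSet, character vector or file path",
       call. = FALSE)
}

#' Genome size from a k-mer histogram
#'
#' Lander-Waterman style estimate: genome size = (total counted k-mers) /
#' (peak depth of the k-mer distribution). Multiplicities below
#' \code{minMult} (default 3) are excluded both from the total and from peak
#' detection, to keep the sequencing-error peak out of the estimate. When
#' the automatic argmax is ambiguous (e.g. a heterozygous peak at half the
#' homozygous depth), pass \code{peak} explicitly; all local maxima are
#' reported to support that choice.
#'
#' @param hist A \linkS4class{KmerHistogram}.
#' @param minMult minimum multiplicity retained.
#' @param peak optional explicit peak depth overriding the argmax.
#' @return list with \code{size} (bp), \code{peak} (depth),
#'   \code{totalKmersUsed} and \code{localMaxima} (depths of all local maxima
#'   of the retained histogram).
#' @export
estimateGenomeSize <- function(hist, minMult = 3, peak = NULL) {
  stopifnot(is(hist, "KmerHistogram"))
  e <- hist@entries
  e <- e[e$multiplicity >= minMult, , drop = FALSE]
  if (nrow(e) == 0)
    stop("no k-mers at multiplicity >= ", minMult,
         "; histogram maximum is ",
         if (nrow(hist@entries)) max(hist@entries$multiplicity) else 0,
         call. = FALSE)
  if (is.null(peak)) peak <- e$multiplicity[which.max(e$n_distinct)]
  n <- e$n_distinct
  isMax <- vapply(seq_along(n), function(i) {
    (i == 1 || n[i] >= n[i - 1]) && (i == length(n) || n[i] >= n[i + 1])
  }, logical(1))
  total <- sum(as.numeric(e$multiplicity) * e$n_distinct)
  list(size = total / peak, peak = peak, totalKmersUsed = total,
       localMaxima = e$multiplicity[isMax])
}

#' Write / read a k-mer histogram as two-column TSV
#'
#' The format (multiplicity, n_distinct; no header in the common counter
#' dialect, but a header row is written here) round-trips through
#' \code{readKmerHistogram}.
#'
#' @param hist A \linkS4class{KmerHistogram}.
#' @param path output TSV path.
#' @export
writeKmerHistogram <- function(hist, path) {
  utils::write.table(hist@entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeKmerHistogram
#' @param k k-mer size to record on the restored object.
#' @export
readKmerHistogram <- function(path, k = 17) {
  e <- utils::read.delim(path)
  new("KmerHistogram", k = as.integer(k), entries = e,
      totalKmers = sum(as.numeric(e$multiplicity) * e$n_distinct))
}
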