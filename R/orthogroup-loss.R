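#' Read an orthogroup count matrix
#'
#' Accepts either a TSV (header row; first column family ids, remaining
#' columns per-species gene counts) or OrthoMCL-style "groups" text
#' (\code{family_id: species|gene species|gene ...}), in which case counts
#' are tallied per species per family.
#'
#' @param path input file.
#' @param format "auto" (default), "tsv" or "groups".
#' @return A \linkS4class{GeneFamilyCounts}.
#' @export
readGroups <- function(path, format = c("auto", "tsv", "groups")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty input file: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\t", lines[1], fixed = TRUE)) "tsv" else "groups"
  if (format == "tsv") {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    fam <- as.character(df[[1]])
    if (anyDuplicated(fam))
      stop("duplicate family id: ", fam[duplicated(fam)][1], call. = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- fam
    return(GeneFamilyCounts(m))
  }
  fams <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 1)
      stop("parse error at line ", i, ": no 'family:' prefix", call. = FALSE)
    fam <- trimws(substr(ln, 1, colon - 1))
    if (fam %in% names(fams))
      stop("duplicate family id: ", fam, " (line ", i, ")", call. = FALSE)
    members <- strsplit(trimws(substr(ln, colon + 1, nchar(ln))), "\\s+")[[1]]
    members <- members[nzchar(members)]
    sp <- sub("\\|.*$", "", members)
    if (any(!grepl("|", members, fixed = TRUE)))
      stop("parse error at line ", i, ": member without 'species|gene' form",
           call. = FALSE)
    fams[[fam]] <- table(sp)
  }
  species <- sort(unique(unlist(lapply(fams, names))))
  m <- matrix(0L, length(fams), length(species),
              dimnames = list(names(fams), species))
  for (fam in names(fams)) m[fam, names(fams[[fam]])] <- as.integer(fams[[fam]])
  GeneFamilyCounts(m)
}

#' Write a count matrix as TSV
#'
#' @param x A \linkS4class{GeneFamilyCounts}.
#' @param path output path; first column \code{family}, then one column per
#'   species.
#' @export
writeCounts <- function(x, path) {
  df <- data.frame(family = familyIds(x), geneCounts(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter to conserved gene families
#'
#' Retains families present (count > 0) in at least \code{minSpecies} species
#' AND present in the designated outgroup, the conservation filter applied
#' before F-index classification.
#'
#' @param x A \linkS4class{GeneFamilyCounts}.
#' @param minSpecies minimum number of species with a nonzero count.
#' @param outgroup species id whose families must have a homolog.
#' @return the filtered \linkS4class{GeneFamilyCounts}.
#' @export
filterConserved <- function(x, minSpecies, outgroup) {
  m <- geneCounts(x)
  if (!outgroup %in% colnames(m))
    stop("unknown outgroup id: ", outgroup, call. = FALSE)
  minSpecies <- assertCount(minSpecies, "minSpecies")
  if (minSpecies > ncol(m))
    stop("minSpecies exceeds the number of species", call. = FALSE)
  keep <- rowSums(m > 0) >= minSpecies & m[, outgroup] > 0
  GeneFamilyCounts(m[keep, , drop = FALSE])
}

#' F index of a species' share in a gene family
#'
#' F = (log2(a c/N + 1/2) + 1) / (log2(a + 1/2) + 1) with a = (S^2 - 2S)/2,
#' where c is the species' gene count in the family, N the family's total
#' gene count over all species and S the number of species represented in
#' the family. F = 0 iff c = 0, F = 1 iff c = N, and F = 1/2 exactly when
#' c/N = 1/S (the species holds an exactly average share).
#'
#' @param c_ij gene count of the species in the family (vectorised).
#' @param N_j total genes in the family.
#' @param S number of species in the family; must be >= 3 (the denominator
#'   degenerates at S = 2, where a = 0).
#' @return numeric F in [0, 1].
#' @export
fIndex <- function(c_ij, N_j, S) {
  if (any(S < 3)) stop("F index requires S >= 3", call. = FALSE)
  if (any(N_j < 1)) stop("N_j must be >= 1", call. = FALSE)
  if (any(c_ij < 0 | c_ij > N_j))
    stop("c_ij must satisfy 0 <= c_ij <= N_j", call. = FALSE)
  a <- (S^2 - 2 * S) / 2
  (log2(a * c_ij / N_j + 0.5) + 1) / (log2(a + 0.5) + 1)
}

FCATEGORIES <- c("Missing", "Less than average", "Around average (less)",
                 "Around average (greater)", "Greater than average")

#' Classify an F index into the five loss categories
#'
#' Boundaries: F = 0 Missing; 0 < F <= 0.45 Less than average;
#' 0.45 < F <= 0.5 Around average (less); 0.5 < F <= 0.55 Around average
#' (greater); F > 0.55 Greater than average. Comparisons are at full
#' precision (no rounding of F first).
#'
#' @param F numeric vector of F indices in [0, 1].
#' @return factor with the five category levels.
#' @export
classifyFIndex <- function(F) {
  if (any(!is.finite(F) | F < 0 | F > 1))
    stop("F must lie in [0, 1]", call. = FALSE)
  out <- character(length(F))
  out[F == 0] <- FCATEGORIES[1]
  out[F > 0 & F <= 0.45] <- FCATEGORIES[2]
  out[F > 0.45 & F <= 0.5] <- FCATEGORIES[3]
  out[F > 0.5 & F <= 0.55] <- FCATEGORIES[4]
  out[F > 0.55] <- FCATEGORIES[5]
  factor(out, levels = FCATEGORIES)
}

#' Per-cell F-index records for a count matrix
#'
#' Computes, for every family x species cell, the family totals N_j and S
#' (number of species with a nonzero count), a, the F index and its
#' category. For a missing species (c = 0) the family's S from the nonzero
#' species is used; F is 0 regardless. Families represented in fewer than 3
#' species are reported with \code{evaluable = FALSE} and NA F rather than
#' silently dropped.
#'
#' @param x A \linkS4class{GeneFamilyCounts}.
#' @return data.frame: family, species, c_ij, N_j, S, a, F, category,
#'   evaluable.
#' @export
fIndexTable <- function(x) {
  m <- geneCounts(x)
  Nj <- rowSums(m)
  S <- rowSums(m > 0)
  a <- (S^2 - 2 * S) / 2
  evaluable <- S >= 3
  out <- data.frame(
    family = rep(rownames(m), times = ncol(m)),
    species = rep(colnames(m), each = nrow(m)),
    c_ij = as.vector(m),
    N_j = rep(Nj, times = ncol(m)),
    S = rep(S, times = ncol(m)),
    a = rep(a, times = ncol(m)),
    evaluable = rep(evaluable, times = ncol(m)),
    stringsAsFactors = FALSE)
  out$F <- NA_real_
  ok <- out$evaluable
  out$F[ok] <- fIndex(out$c_ij[ok], out$N_j[ok], out$S[ok])
  out$category <- factor(NA_character_, levels = FCATEGORIES)
  out$category[ok] <- classifyFIndex(out$F[ok])
  out
}

#' Missing-family and category summaries
#'
#' Per species: the number of families with zero genes; per species pair:
#' the number of families missing in both; per species: the percentage of
#' evaluable families in each of the five F-index categories (each row sums
#' to 100).
#'
#' @param x A (typically conservation-filtered) \linkS4class{GeneFamilyCounts}.
#' @return list with \code{perSpeciesMissing} (named integer),
#'   \code{sharedMissing} (symmetric matrix) and \code{categoryPercent}
#'   (species x category percentage matrix).
#' @export
missingSummary <- function(x) {
  m <- geneCounts(x)
  z <- m == 0
  perSpecies <- colSums(z)
  shared <- crossprod(z)
  tab <- fIndexTable(x)
  tab <- tab[tab$evaluable, , drop = FALSE]
  counts <- table(tab$species, tab$category)
  pct <- 100 * counts / rowSums(counts)
  list(perSpeciesMissing = perSpecies,
       sharedMissing = shared,
       categoryPercent = as.matrix(pct)[colnames(m), , drop = FALSE])
}

#' Remove short open reading frames
#'
#' Drops coding sequences shorter than \code{minLen} base pairs (default 150),
#' the gene-model length filter applied before family clustering.
#'
#' @param cds named character vector or \code{DNAStringSet}.
#' @param minLen minimum length in bp to keep.
#' @return object of the same class, filtered.
#' @export
orfFilter <- function(cds, minLen = 150) {
  if (is(cds, "XStringSet")) return(cds[Biostrings::width(cds) >= minLen])
  cds[nchar(cds) >= minLen]
}
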