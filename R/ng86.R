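# Nei-Gojobori (1986) codon counting machinery.
#
# Conventions: mutations that create a stop codon count as nonsynonymous in
# site estimation; substitution pathways that pass through a stop codon are
# excluded from difference counting; a codon pair whose every pathway crosses
# a stop is excluded altogether.

NUCS <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

codonTable <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

senseCodons <- function() {
  gc <- codonTable()
  names(gc)[gc != "*"]
}

# Per-codon synonymous site count: over the 9 single-nucleotide mutations,
# the synonymous fraction at each position, summed over positions.
ngSynSites <- function(codon, gc = codonTable()) {
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nuc in setdiff(NUCS, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nuc
      if (gc[[mut]] != "*" && gc[[mut]] == aa) s <- s + 1 / 3
    }
  }
  s
}

# Average synonymous/nonsynonymous difference counts between two sense
# codons over all substitution orderings that avoid stop codons.
ngPairDiffs <- function(c1, c2, gc = codonTable()) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(pos)
  if (d == 0) return(list(sd = 0, nd = 0, valid = TRUE))
  perms <- switch(d,
    matrix(1L, 1, 1),
    matrix(c(1L, 2L, 2L, 1L), 2, 2, byrow = TRUE),
    matrix(c(1L,2L,3L, 1L,3L,2L, 2L,1L,3L, 2L,3L,1L, 3L,1L,2L, 3L,2L,1L),
           6, 3, byrow = TRUE))
  sdTot <- 0; ndTot <- 0; nValid <- 0L
  for (r in seq_len(nrow(perms))) {
    cur <- c1
    sd <- 0; nd <- 0; ok <- TRUE
    for (p in perms[r, ]) {
      nxt <- cur
      substr(nxt, pos[p], pos[p]) <- substr(c2, pos[p], pos[p])
      if (gc[[nxt]] == "*") { ok <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (ok) { sdTot <- sdTot + sd; ndTot <- ndTot + nd; nValid <- nValid + 1L }
  }
  if (nValid == 0L) return(list(sd = NA_real_, nd = NA_real_, valid = FALSE))
  list(sd = sdTot / nValid, nd = ndTot / nValid, valid = TRUE)
}

# Cache of the 61-codon site vector and 61 x 61 difference matrices.
.ng86cache <- new.env(parent = emptyenv())

ng86Tables <- function() {
  if (!is.null(.ng86cache$tables)) return(.ng86cache$tables)
  gc <- codonTable()
  sense <- senseCodons()
  n <- length(sense)
  sites <- vapply(sense, ngSynSites, numeric(1), gc = gc)
  sd <- matrix(NA_real_, n, n, dimnames = list(sense, sense))
  nd <- sd
  valid <- matrix(FALSE, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in i:n) {
      pd <- ngPairDiffs(sense[i], sense[j], gc)
      sd[i, j] <- sd[j, i] <- pd$sd
      nd[i, j] <- nd[j, i] <- pd$nd
      valid[i, j] <- valid[j, i] <- pd$valid
    }
  }
  .ng86cache$tables <- list(sense = sense, sites = sites, sd = sd, nd = nd,
                            valid = valid)
  .ng86cache$tables
}
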