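# Ground-truth generators for every input the pipeline consumes.

#' Gene-family loss scenario
#'
#' Parameters of the orthogroup count simulator: per-species retention
#' probabilities, an optional jointly-lost component for a designated pair
#' of (mycoheterotroph-like) species, and a positive-truncated Poisson
#' family-size model so present families always have at least one gene.
#'
#' @param nFamilies number of gene families to simulate.
#' @param speciesLabels character vector of species ids.
#' @param retentionProb per-species retention probability in [0, 1]
#'   (recycled; may be a named vector over speciesLabels).
#' @param sharedPair character(2): two distinct species jointly losing
#'   families, or NULL.
#' @param sharedLossProb probability that a family is lost jointly in the
#'   designated pair (union with the independent losses).
#' @param meanFamilySize expected per-species count given retention (> 1).
#' @param seed integer RNG seed.
#' @return a validated list of class "LossScenario".
#' @export
lossScenario <- function(nFamilies, speciesLabels,
                         retentionProb = 0.95, sharedPair = NULL,
                         sharedLossProb = 0, meanFamilySize = 3,
                         seed = 1729) {
  nFamilies <- assertCount(nFamilies, "nFamilies")
  assertProb(retentionProb, "retentionProb")
  assertProb(sharedLossProb, "sharedLossProb")
  if (meanFamilySize <= 1)
    stop("meanFamilySize must exceed 1 (positive-truncated Poisson mean)",
         call. = FALSE)
  if (is.null(names(retentionProb))) {
    retentionProb <- stats::setNames(rep_len(retentionProb,
                                             length(speciesLabels)),
                                     speciesLabels)
  } else if (!all(speciesLabels %in% names(retentionProb))) {
    stop("named retentionProb must cover all speciesLabels", call. = FALSE)
  }
  if (!is.null(sharedPair)) {
    if (length(sharedPair) != 2 || sharedPair[1] == sharedPair[2] ||
        !all(sharedPair %in% speciesLabels))
      stop("sharedPair must be two distinct species from speciesLabels",
           call. = FALSE)
  }
  structure(list(nFamilies = nFamilies, speciesLabels = speciesLabels,
                 retentionProb = retentionProb[speciesLabels],
                 sharedPair = sharedPair, sharedLossProb = sharedLossProb,
                 meanFamilySize = meanFamilySize, seed = as.integer(seed)),
            class = "LossScenario")
}

#' Simulate an orthogroup count matrix with known loss structure
#'
#' Per family and species the count is 0 with probability
#' 1 - retentionProb, otherwise drawn from a positive-truncated Poisson
#' whose truncated mean is meanFamilySize. Families are additionally lost
#' jointly in the designated pair with sharedLossProb (union with the
#' independent losses). Bit-reproducible from the scenario seed.
#'
#' @param scenario a \code{\link{lossScenario}}.
#' @return A \linkS4class{GeneFamilyCounts}.
#' @export
simulateCountMatrix <- function(scenario) {
  stopifnot(inherits(scenario, "LossScenario"))
  withSeed(scenario$seed, {
    nf <- scenario$nFamilies
    sp <- scenario$speciesLabels
    m <- matrix(0L, nf, length(sp),
                dimnames = list(sprintf("FAM%05d", seq_len(nf)), sp))
    present <- matrix(stats::runif(nf * length(sp)), nf, length(sp)) <
      rep(scenario$retentionProb, each = nf)
    if (!is.null(scenario$sharedPair) && scenario$sharedLossProb > 0) {
      joint <- stats::runif(nf) < scenario$sharedLossProb
      present[joint, match(scenario$sharedPair, sp)] <- FALSE
    }
    nPresent <- sum(present)
    if (nPresent > 0)
      m[present] <- rztpois(nPresent, scenario$meanFamilySize)
    GeneFamilyCounts(m)
  })
}

#' Four-taxon codon evolution scenario
#'
#' The fixed topology is (outgroup, (reference, (spA, spB))): five branches
#' named outgroup, reference, internal (ancestor of spA/spB), spA and spB,
#' each with an expected number of synonymous substitutions per synonymous
#' site (branch dS).
#'
#' @param branchDS named numeric over the five branch names, all >= 0.
#' @param nGenes number of genes to evolve.
#' @param codonsPerGene codons per gene (>= 30).
#' @param seed integer RNG seed.
#' @return a validated list of class "QuartetScenario".
#' @export
quartetScenario <- function(branchDS, nGenes = 100, codonsPerGene = 300,
                            seed = 1729) {
  branches <- c("outgroup", "reference", "internal", "spA", "spB")
  if (!all(branches %in% names(branchDS)))
    stop("branchDS must name all of: ", paste(branches, collapse = ", "),
         call. = FALSE)
  if (any(branchDS < 0)) stop("branch dS must be >= 0", call. = FALSE)
  nGenes <- assertCount(nGenes, "nGenes")
  codonsPerGene <- assertCount(codonsPerGene, "codonsPerGene", min = 30)
  structure(list(branchDS = branchDS[branches], nGenes = nGenes,
                 codonsPerGene = codonsPerGene, seed = as.integer(seed)),
            class = "QuartetScenario")
}

# Apply a Poisson(dS * synonymous sites) number of accepted synonymous
# substitutions to a codon vector. Proposals are random single-nucleotide
# changes; only synonymous, non-stop outcomes are accepted.
evolveSynonymous <- function(codons, dS, gc, sites) {
  if (dS == 0) return(codons)
  S <- sum(sites[codons])
  nEvents <- stats::rpois(1, dS * S)
  nc <- length(codons)
  applied <- 0L
  while (applied < nEvents) {
    i <- sample.int(nc, 1)
    pos <- sample.int(3, 1)
    old <- substr(codons[i], pos, pos)
    nuc <- sample(setdiff(NUCS, old), 1)
    mut <- codons[i]
    substr(mut, pos, pos) <- nuc
    if (gc[[mut]] != "*" && gc[[mut]] == gc[[codons[i]]]) {
      codons[i] <- mut
      applied <- applied + 1L
    }
  }
  codons
}

#' Simulate codon sequences on the four-taxon tree
#'
#' A random root coding sequence (sense codons only, no internal stops) is
#' evolved down the fixed (outgroup, (reference, (spA, spB))) topology by a
#' synonymous-only substitution process: random single-nucleotide proposals
#' are accepted only when synonymous and stop-free, with an expected
#' branch dS x (synonymous sites) accepted events per branch. Nonsynonymous
#' change is excluded by design so the true branch dS stays interpretable
#' downstream.
#'
#' @param scenario a \code{\link{quartetScenario}}.
#' @return list with \code{sequences} (list of four named character vectors:
#'   outgroup, reference, spA, spB; names are gene ids, shared across taxa)
#'   and \code{truth} (the branch dS table).
#' @export
simulateCodonQuartet <- function(scenario) {
  stopifnot(inherits(scenario, "QuartetScenario"))
  gc <- codonTable()
  sense <- senseCodons()
  sites <- vapply(sense, ngSynSites, numeric(1), gc = gc)
  ds <- scenario$branchDS
  withSeed(scenario$seed, {
    taxa <- c("outgroup", "reference", "spA", "spB")
    seqs <- stats::setNames(vector("list", 4), taxa)
    genes <- sprintf("g%04d", seq_len(scenario$nGenes))
    for (t in taxa) seqs[[t]] <- stats::setNames(character(scenario$nGenes),
                                                 genes)
    for (g in seq_len(scenario$nGenes)) {
      root <- sample(sense, scenario$codonsPerGene, replace = TRUE)
      og <- evolveSynonymous(root, ds["outgroup"], gc, sites)
      ref <- evolveSynonymous(root, ds["reference"], gc, sites)
      anc <- evolveSynonymous(root, ds["internal"], gc, sites)
      a <- evolveSynonymous(anc, ds["spA"], gc, sites)
      b <- evolveSynonymous(anc, ds["spB"], gc, sites)
      seqs$outgroup[g] <- paste(og, collapse = "")
      seqs$reference[g] <- paste(ref, collapse = "")
      seqs$spA[g] <- paste(a, collapse = "")
      seqs$spB[g] <- paste(b, collapse = "")
    }
    list(sequences = seqs,
         truth = data.frame(branch = names(ds), dS = unname(ds),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate diverged 5'/3' LTR pairs of known age
#'
#' Each element's two LTRs descend from a shared ancestral sequence and
#' independently accumulate Poisson(rate x age x length) substitutions
#' (random position, random different base, multiple hits allowed), so the
#' pairwise expectation is 2 r t per site before multiple-hit correction.
#'
#' @param n number of elements.
#' @param rate substitutions/site/year, > 0.
#' @param ages vector of element ages in years (recycled to n).
#' @param ltrLength LTR length in bp.
#' @param seed integer RNG seed.
#' @return list with \code{pairs} (named list of character(2), 5' then 3')
#'   and \code{truth} (data.frame element, age_yr).
#' @export
simulateLtrPairs <- function(n, rate, ages, ltrLength = 2000, seed = 1729) {
  n <- assertCount(n, "n")
  if (rate <= 0) stop("rate must be > 0", call. = FALSE)
  if (any(ages < 0)) stop("ages must be >= 0", call. = FALSE)
  ages <- rep_len(ages, n)
  withSeed(seed, {
    ids <- sprintf("LTR%04d", seq_len(n))
    pairs <- stats::setNames(vector("list", n), ids)
    mutate <- function(s, nHits) {
      if (nHits == 0) return(s)
      ch <- strsplit(s, "")[[1]]
      for (h in seq_len(nHits)) {
        i <- sample.int(length(ch), 1)
        ch[i] <- sample(setdiff(NUCS, ch[i]), 1)
      }
      paste(ch, collapse = "")
    }
    for (i in seq_len(n)) {
      anc <- paste(sample(NUCS, ltrLength, replace = TRUE), collapse = "")
      lambda <- rate * ages[i] * ltrLength
      pairs[[ids[i]]] <- c(mutate(anc, stats::rpois(1, lambda)),
                           mutate(anc, stats::rpois(1, lambda)))
    }
    list(pairs = pairs,
         truth = data.frame(element = ids, age_yr = ages,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate reads from a random genome of known size
#'
#' Reads of fixed length are sampled uniformly (random strand) from a
#' uniform-random genome, optionally with per-base substitution errors. The
#' expected k-mer peak depth is roughly
#' coverage x (readLength - k + 1) / readLength.
#'
#' @param genomeSize genome length in bp.
#' @param coverage mean fold coverage (> 0; coverage 0 returns no reads).
#' @param readLength read length in bp.
#' @param errorRate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @return list with \code{reads} (character vector) and \code{genome}
#'   (character(1)).
#' @export
simulateReads <- function(genomeSize, coverage, readLength = 100,
                          errorRate = 0, seed = 1729) {
  genomeSize <- assertCount(genomeSize, "genomeSize")
  if (coverage < 0) stop("coverage must be >= 0", call. = FALSE)
  assertProb(errorRate, "errorRate")
  withSeed(seed, {
    genome <- paste(sample(NUCS, genomeSize, replace = TRUE), collapse = "")
    nReads <- round(coverage * genomeSize / readLength)
    if (nReads == 0)
      return(list(reads = character(0), genome = genome))
    starts <- sample.int(genomeSize - readLength + 1, nReads, replace = TRUE)
    reads <- substring(genome, starts, starts + readLength - 1)
    flip <- stats::runif(nReads) < 0.5
    if (any(flip))
      reads[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[flip])))
    if (errorRate > 0) {
      nErr <- stats::rbinom(nReads, readLength, errorRate)
      for (i in which(nErr > 0)) {
        ch <- strsplit(reads[i], "")[[1]]
        pos <- sample.int(readLength, nErr[i])
        for (p in pos) ch[p] <- sample(setdiff(NUCS, ch[p]), 1)
        reads[i] <- paste(ch, collapse = "")
      }
    }
    names(reads) <- sprintf("read%07d", seq_len(nReads))
    list(reads = reads, genome = genome)
  })
}

#' Simulate a term-to-gene annotation with one (optionally) enriched term
#'
#' The designated first term draws each of its genes from \code{targetSet}
#' with probability \code{enrichedTermFraction} (otherwise uniformly from
#' the universe); all remaining terms draw uniformly. With
#' \code{enrichedTermFraction = 0} the map is a null (no-enrichment)
#' scenario.
#'
#' @param universe character vector of gene ids.
#' @param nTerms number of annotation terms.
#' @param enrichedTermFraction probability that a gene of the enriched term
#'   is drawn from \code{targetSet}.
#' @param targetSet character vector (subset of universe), e.g. the lost
#'   families a term should concentrate in.
#' @param meanTermSize expected genes per term (default 20).
#' @param seed integer RNG seed.
#' @return list with \code{termMap} (data.frame term, gene) and
#'   \code{enrichedTerm} (id of the designated term).
#' @export
simulateAnnotation <- function(universe, nTerms, enrichedTermFraction = 0,
                               targetSet = character(0), meanTermSize = 20,
                               seed = 1729) {
  nTerms <- assertCount(nTerms, "nTerms")
  assertProb(enrichedTermFraction, "enrichedTermFraction")
  if (!all(targetSet %in% universe))
    stop("targetSet must be a subset of the universe", call. = FALSE)
  withSeed(seed, {
    terms <- sprintf("T%03d", seq_len(nTerms))
    sizes <- pmax(1, stats::rpois(nTerms, meanTermSize))
    rows <- vector("list", nTerms)
    for (i in seq_len(nTerms)) {
      size <- min(sizes[i], length(universe))
      if (i == 1 && enrichedTermFraction > 0 && length(targetSet) > 0) {
        nFromTarget <- stats::rbinom(1, size, enrichedTermFraction)
        nFromTarget <- min(nFromTarget, length(targetSet))
        genes <- unique(c(sample(targetSet, nFromTarget),
                          sample(universe, size - nFromTarget)))
      } else {
        genes <- sample(universe, size)
      }
      rows[[i]] <- data.frame(term = terms[i], gene = genes,
                              stringsAsFactors = FALSE)
    }
    list(termMap = do.call(rbind, rows), enrichedTerm = terms[1])
  })
}
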