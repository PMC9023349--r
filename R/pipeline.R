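#' Percentage of a whole, rounded half-up to two decimals
#'
#' Printed-report style: 100 * part / whole with round-half-up (not
#' banker's rounding) to two decimal places.
#'
#' @param part,whole counts with 0 <= part <= whole, whole > 0.
#' @return numeric percentage.
#' @examples
#' summarizePercent(273, 488)  # 55.94
#' @export
summarizePercent <- function(part, whole) {
  if (any(whole <= 0)) stop("whole must be > 0", call. = FALSE)
  if (any(part < 0 | part > whole))
    stop("part must satisfy 0 <= part <= whole", call. = FALSE)
  roundHalfUp(100 * part / whole, 2)
}

writeManifest <- function(outDir, stage, params, seed, inputs = character(0)) {
  manifest <- list(
    stage = stage,
    package = "mycohet",
    version = as.character(utils::packageVersion("mycohet")),
    seed = seed,
    parameters = params,
    input_checksums = if (length(inputs))
      as.list(tools::md5sum(inputs)) else list(),
    defaults_applied = list(
      ks_filter_bounds = c(0.01, 5),
      kde = "gaussian, Silverman (nrd0) bandwidth, 512-point grid",
      min_kmer_multiplicity = 3,
      era_threshold_reading = "T < threshold (more recent than)",
      percent_rounding = "half-up, 2 decimals"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Run a pipeline stage end to end, writing TSV outputs and a manifest
#'
#' Thin driver over the package functions: executes one named stage on file
#' inputs, writes its outputs under \code{outDir} together with a
#' \code{manifest.json} recording all parameters, the seed, the package
#' version and input checksums. All randomness flows from \code{seed};
#' rerunning with the same inputs and seed reproduces the outputs
#' byte-identically.
#'
#' Stages and their required \code{params}:
#' \describe{
#'   \item{famloss}{\code{counts} (TSV/groups path), \code{minSpecies},
#'     \code{outgroup}. Writes f_index.tsv, category_percent.tsv,
#'     shared_missing.tsv.}
#'   \item{genomesize}{\code{reads} (FASTA/FASTQ path), optional \code{k},
#'     \code{minMult}. Writes kmer_histogram.tsv, genome_size.tsv.}
#'   \item{ltrdate}{\code{pairs} (FASTA path), \code{rate} or (\code{d},
#'     \code{tMa}), optional \code{thresholdMa}. Writes insertion_times.tsv,
#'     age_histogram.tsv.}
#'   \item{enrich}{\code{study} (one gene id per line), \code{map} (TSV
#'     term, gene), \code{universe} (one id per line). Writes
#'     enrichment.tsv.}
#'   \item{relrate}{\code{ksOA}, \code{ksOB}, \code{ksAB} (Ks TSVs with
#'     geneA, geneB, Ks), optional \code{nBoot}. Writes modes.tsv,
#'     decomposition.tsv.}
#' }
#'
#' @param stage one of "famloss", "genomesize", "ltrdate", "enrich",
#'   "relrate".
#' @param params named list of stage parameters (above).
#' @param outDir output directory (created if absent).
#' @param seed integer seed used for every stochastic step (default 1729,
#'   recorded in the manifest).
#' @return (invisibly) the list of written file paths.
#' @export
runPipeline <- function(stage = c("famloss", "genomesize", "ltrdate",
                                  "enrich", "relrate"),
                        params = list(), outDir, seed = 1729) {
  stage <- match.arg(stage)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  need <- function(nm) {
    if (is.null(params[[nm]]))
      stop("stage '", stage, "' requires parameter '", nm, "'", call. = FALSE)
    params[[nm]]
  }
  needFile <- function(nm) {
    p <- need(nm)
    if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    p
  }
  tsv <- function(df, name) {
    path <- file.path(outDir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  written <- character(0)
  inputs <- character(0)

  if (stage == "famloss") {
    counts <- needFile("counts")
    inputs <- counts
    x <- readGroups(counts)
    x <- filterConserved(x, need("minSpecies"), need("outgroup"))
    tab <- fIndexTable(x)
    ms <- missingSummary(x)
    written <- c(
      tsv(tab, "f_index.tsv"),
      tsv(data.frame(species = rownames(ms$categoryPercent),
                     ms$categoryPercent, check.names = FALSE),
          "category_percent.tsv"),
      tsv(data.frame(species = rownames(ms$sharedMissing),
                     ms$sharedMissing, check.names = FALSE),
          "shared_missing.tsv"))
  } else if (stage == "genomesize") {
    reads <- needFile("reads")
    inputs <- reads
    k <- if (is.null(params$k)) 17 else params$k
    minMult <- if (is.null(params$minMult)) 3 else params$minMult
    hist <- countKmers(reads, k)
    est <- estimateGenomeSize(hist, minMult = minMult, peak = params$peak)
    written <- c(
      writeKmerHistogram(hist, file.path(outDir, "kmer_histogram.tsv")),
      tsv(data.frame(k = k, min_multiplicity = minMult, peak = est$peak,
                     total_kmers_used = est$totalKmersUsed,
                     genome_size_bp = est$size),
          "genome_size.tsv"))
  } else if (stage == "ltrdate") {
    pairsPath <- needFile("pairs")
    inputs <- pairsPath
    rate <- if (!is.null(params$rate)) params$rate else
      substitutionRate(need("d"), need("tMa") * 1e6)
    times <- ltrInsertionTimes(readLtrPairs(pairsPath), rate)
    thr <- if (is.null(params$thresholdMa)) 0.2 else params$thresholdMa
    era <- eraFraction(times$T_Ma, thr)
    written <- c(
      tsv(times, "insertion_times.tsv"),
      tsv(era$histogram, "age_histogram.tsv"),
      tsv(data.frame(threshold_Ma = thr,
                     fraction_younger = era$fraction,
                     percent_younger = summarizePercent(
                       sum(times$T_Ma < thr, na.rm = TRUE),
                       sum(is.finite(times$T_Ma)))),
          "era_fraction.tsv"))
  } else if (stage == "enrich") {
    study <- readLines(needFile("study"))
    map <- utils::read.delim(needFile("map"), stringsAsFactors = FALSE)
    universe <- readLines(needFile("universe"))
    inputs <- c(params$study, params$map, params$universe)
    written <- tsv(hypergeomEnrich(study[nzchar(study)], map,
                                   universe[nzchar(universe)]),
                   "enrichment.tsv")
  } else if (stage == "relrate") {
    inputs <- c(needFile("ksOA"), needFile("ksOB"), needFile("ksAB"))
    nBoot <- if (is.null(params$nBoot)) 200 else params$nBoot
    dOA <- importKsTable(params$ksOA, c("outgroup", "A"))
    dOB <- importKsTable(params$ksOB, c("outgroup", "B"))
    dAB <- importKsTable(params$ksAB, c("A", "B"))
    modes <- lapply(list(OA = dOA, OB = dOB, AB = dAB), function(d)
      bootstrapMode(d, nBoot = nBoot, seed = seed))
    dec <- relativeRateBootstrap(dOA, dOB, dAB, nBoot = nBoot, seed = seed)
    modeRow <- function(nm) {
      m <- modes[[nm]]
      data.frame(pair = nm, n = length(ksValues(get(paste0("d", nm)))),
                 mode = m@mode, ci_low = m@ciLow, ci_high = m@ciHigh,
                 bandwidth = m@bandwidth)
    }
    bd <- branchDistances(dec)
    written <- c(
      tsv(do.call(rbind, lapply(c("OA", "OB", "AB"), modeRow)), "modes.tsv"),
      tsv(data.frame(branch = names(bd), distance = unname(bd),
                     ci_low = dec@ci[, 1], ci_high = dec@ci[, 2],
                     flags = paste(dec@flags, collapse = ";")),
          "decomposition.tsv"))
  }

  writeManifest(outDir, stage, params, seed, inputs)
  invisible(c(written, file.path(outDir, "manifest.json")))
}
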