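# End-to-end pipeline driver and whole-object VCF roundtrip.

#' Annotate mutations with trinucleotide context and 96-channel label
#'
#' @param dnms data.frame with chrom, pos, ref, alt.
#' @param reference reference sequence (or context index).
#' @return \code{dnms} with \code{context} and \code{channel} columns.
#' @export
annotateChannels <- function(dnms, reference) {
  idx <- if (is.list(reference) && !is.null(reference$code2ctx32))
    reference else .contextIndex(reference)
  if (nrow(dnms) == 0) {
    dnms$context <- character(0)
    dnms$channel <- character(0)
    return(dnms)
  }
  ctx <- .contextAtMulti(idx, dnms$chrom, dnms$pos)
  dnms$context <- unname(ctx)
  dnms$channel <- channelOf(ctx, dnms$ref, dnms$alt)
  dnms
}

#' Write-then-read roundtrip of trio VCF records
#'
#' @param records trio site records (see [writeTrioVcf()]).
#' @param path optional path (temporary file by default).
#' @return the records as re-read by [readTrioVcf()].
#' @export
roundtripVcf <- function(records, path = tempfile(fileext = ".vcf")) {
  writeTrioVcf(records, path)
  readTrioVcf(path)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes simulate, call + filter cascade, phasing, spectrum /
#' signature-exposure analysis and burden modelling in order, with one
#' global seed feeding per-stage substreams, and returns (and optionally
#' writes) a JSON-able summary.
#'
#' @param config named list (or path to a YAML file) with any of:
#'   \code{seed}; \code{n_control_trios}, \code{n_hyper_trios};
#'   \code{reference_length}, \code{mean_depth}, and the other
#'   [EvidenceConfig()] / [MutationProcessConfig()] fields (snake_case);
#'   \code{thresholds}, a named list of [FilterThresholds()] overrides;
#'   \code{out_dir}, output directory (no files written when \code{NULL});
#'   \code{repeats_bed}, \code{segdups_bed}, \code{popaf_tsv} to use
#'   external masks / AF table instead of the simulated ones.
#' @return named list: per-offspring DNM counts, filter trace, phasing
#'   summary, exposure fractions, rate estimate and burden coefficients.
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  gv <- function(key, default) if (!is.null(config[[key]]))
    config[[key]] else default
  seed <- gv("seed", 1)
  outDir <- gv("out_dir", NULL)
  for (key in c("repeats_bed", "segdups_bed", "popaf_tsv")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("input file not found: ", config[[key]])
  }

  pedCfg <- PedigreeConfig(nControlTrios = gv("n_control_trios", 10),
                           nHyperTrios = gv("n_hyper_trios", 0))
  prcCfg <- MutationProcessConfig(
    controlBurdenMean = gv("control_burden_mean", 10.5),
    maternalCpgExcessMean = gv("maternal_cpg_excess_mean", 30),
    maternalCpaExcessMean = gv("maternal_cpa_excess_mean", 15),
    paternalFraction = gv("paternal_fraction", 0.742))
  evCfg <- EvidenceConfig(
    referenceLength = gv("reference_length", 2e7),
    meanDepth = gv("mean_depth", 23.6),
    nominalCallableBases = gv("nominal_callable_bases", 1.32e9),
    informativeSiteDensity = gv("informative_site_density", 0.00151),
    fragmentLength = gv("fragment_length", 500))
  th <- do.call(FilterThresholds, as.list(gv("thresholds", list())))

  cohort <- simulateTrioCohort(pedCfg, prcCfg, evCfg, seed = seed)
  ped <- cohort@pedigree

  repeatMask <- if (!is.null(config$repeats_bed))
    readBedMask(config$repeats_bed) else cohort@repeatMask
  segdupMask <- if (!is.null(config$segdups_bed))
    readBedMask(config$segdups_bed) else cohort@segdupMask
  afTable <- if (!is.null(config$popaf_tsv))
    readPopulationAf(config$popaf_tsv) else cohort@popAf

  cand <- callCandidates(cohort@evidence)
  callset <- runCascade(cand, th, repeatMask, segdupMask, afTable)
  surv <- survivors(callset)
  counts <- table(factor(surv$offspring, levels = ped$child))

  phased <- phaseDnms(surv, cohort@readObs, cohort@infoSites)
  phaseSummary <- if (nrow(phased) > 0) summarizePhasing(phased) else NULL

  idx <- .contextIndex(cohort@reference)
  spec <- buildSpectrum(surv, idx)
  renorm <- renormalizeCatalog(syntheticSignatureCatalog(),
                               syntheticSourceFrequencies(),
                               cohort@contextFreqs)
  expo <- if (sum(spectrumCounts(spec)) > 0)
    fitExposures(spec, renorm) else NULL

  ctrl <- !ped$hypermutator
  rate <- if (any(ctrl))
    estimateRate(as.numeric(counts[ped$child[ctrl]]), ped$callable[ctrl])
  else NULL

  burden <- NULL
  if (nrow(ped) >= 8) {
    covar <- data.frame(sample = ped$child,
                        paternal_age = ped$paternal_age,
                        maternal_age = ped$maternal_age,
                        mbd4_genotype = ped$mother_mbd4,
                        callable = ped$callable,
                        hypermutator = ped$hypermutator,
                        stringsAsFactors = FALSE)
    annotated <- annotateChannels(surv, idx)
    ctab <- countsByClass(annotated, offspring = ped$child)
    terms <- c("paternal_age", "maternal_age", "callable")
    if (length(unique(covar$mbd4_genotype)) > 1) {
      if (any(covar$mbd4_genotype == "+/-")) terms <- c(terms, "mbd4_het")
      if (any(covar$mbd4_genotype == "-/-")) terms <- c(terms, "mbd4_hom")
    }
    burden <- fitBurdenModel(ctab, covar, model = "total", terms = terms)
  }

  summary <- list(
    seed = seed,
    n_trios = nrow(ped),
    dnm_counts = setNames(as.integer(counts), names(counts)),
    mean_dnm_count = mean(as.integer(counts)),
    filter_trace = as.list(stageRemovals(filterTrace(callset))),
    input_candidates = filterTrace(callset)@inputCount,
    surviving = filterTrace(callset)@survivingCount,
    phasing = if (!is.null(phaseSummary)) list(
      maternal = phaseSummary@nMaternal,
      paternal = phaseSummary@nPaternal,
      unphased = phaseSummary@nUnphased,
      phaseable_fraction = phaseSummary@phaseableFraction,
      alpha = alphaValue(phaseSummary)) else NULL,
    exposure_fractions = if (!is.null(expo))
      as.list(exposureFractions(expo)) else NULL,
    rate = if (!is.null(rate)) rateValue(rate) else NULL,
    burden_coefficients = if (!is.null(burden))
      as.list(burdenCoefficients(burden)[, "estimate"]) else NULL)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePedFile(ped, file.path(outDir, "pedigree.ped"))
    writeTruthManifest(cohort@truth, file.path(outDir, "truth.tsv"))
    writeFilterTrace(filterTrace(callset),
                     file.path(outDir, "filter_trace.tsv"))
    write.table(surv, file.path(outDir, "filtered_dnms.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(phased, file.path(outDir, "phasing.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    writeBedMask(repeatMask, file.path(outDir, "repeats.bed"))
    writeBedMask(segdupMask, file.path(outDir, "segdups.bed"))
    writePopulationAf(afTable, file.path(outDir, "popaf.tsv"))
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  summary
}
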