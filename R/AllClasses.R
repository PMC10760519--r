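# S4 class definitions and validity methods.

#' Pyrimidine-centred trinucleotide context frequencies
#'
#' Frequencies of the 32 pyrimidine-centred trinucleotide contexts of a
#' genome (purine-centred occurrences collapsed onto their reverse
#' complement). Used to renormalise signature catalogs between genomes of
#' different base composition and to place simulated mutations at
#' context-matched positions.
#'
#' @slot freq named numeric vector of length 32; sums to 1.
#' @slot skipped number of interior windows skipped because they contained
#'   non-ACGT characters.
#' @seealso [buildContextModel()], [renormalizeCatalog()]
#' @export
setClass("ContextFrequencies",
  representation(freq = "numeric", skipped = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@freq) != 32L)
      msg <- c(msg, "freq must have length 32")
    if (!identical(names(object@freq), contexts32()))
      msg <- c(msg, "freq names must be the 32 pyrimidine-centred contexts")
    if (any(object@freq < 0))
      msg <- c(msg, "frequencies must be nonnegative")
    if (abs(sum(object@freq) - 1) > 1e-6)
      msg <- c(msg, "frequencies must sum to 1")
    if (is.null(msg)) TRUE else msg
  })

#' Single-base-substitution signature catalog
#'
#' A 96 x S matrix of channel probabilities, one column per signature.
#' Columns sum to 1.
#'
#' @slot probs numeric matrix, rownames the 96 channel labels (e.g.
#'   \code{"A[C>T]G"}), colnames the signature labels.
#' @seealso [syntheticSignatureCatalog()], [renormalizeCatalog()],
#'   [fitExposures()]
#' @export
setClass("SignatureCatalog",
  representation(probs = "matrix"),
  validity = function(object) {
    msg <- NULL
    p <- object@probs
    if (nrow(p) != 96L || !identical(rownames(p), sbsChannels()))
      msg <- c(msg, "probs must have the 96 SBS channels as rownames")
    if (is.null(colnames(p)) || anyDuplicated(colnames(p)))
      msg <- c(msg, "signatures must have unique labels")
    if (any(p < 0))
      msg <- c(msg, "probabilities must be nonnegative")
    if (any(abs(colSums(p) - 1) > 1e-9))
      msg <- c(msg, "each signature column must sum to 1 (tol 1e-9)")
    if (is.null(msg)) TRUE else msg
  })

#' 96-channel mutation spectrum
#'
#' Counts of single-base substitutions over the 96 pyrimidine-centred
#' trinucleotide channels.
#'
#' @slot counts named numeric vector of length 96 (channel order as
#'   [sbsChannels()]).
#' @seealso [buildSpectrum()], [channelOf()]
#' @export
setClass("Spectrum96",
  representation(counts = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@counts) != 96L ||
        !identical(names(object@counts), sbsChannels()))
      msg <- c(msg, "counts must be named by the 96 SBS channels")
    if (any(object@counts < 0))
      msg <- c(msg, "counts must be nonnegative")
    if (is.null(msg)) TRUE else msg
  })

#' Signature exposure estimate
#'
#' Result of a nonnegative least-squares refit of a spectrum against a
#' signature catalog.
#'
#' @slot exposures named nonnegative mutation counts attributed per signature.
#' @slot fractions exposures normalised to sum 1.
#' @slot residualNorm Euclidean norm of the fit residual.
#' @seealso [fitExposures()]
#' @export
setClass("ExposureEstimate",
  representation(exposures = "numeric", fractions = "numeric",
                 residualNorm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@exposures < 0))
      msg <- c(msg, "exposures must be nonnegative")
    if (sum(object@exposures) > 0 &&
        abs(sum(object@fractions) - 1) > 1e-6)
      msg <- c(msg, "fractions must sum to 1 when total exposure > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Hard-filter thresholds for the DNM cascade
#'
#' Defaults encode the published cascade: de novo posterior > 0.5; read
#' depth within [4, 80] in all three samples; offspring variant allele
#' fraction (VAF) within [0.35, 0.70] on autosomes and female X, > 0.70 on
#' male X, Y excluded; alternate reads on both strands with >= 2 alt reads;
#' population allele frequency <= 0.01; parental evidence limited to <= 1
#' alt read and <= 10 percent VAF; binomial allele-balance test at
#' FDR-adjusted p < 0.05.
#'
#' @slot pDnMin minimum de novo posterior probability.
#' @slot depthMin,depthMax inclusive depth bounds applied to child and both
#'   parents.
#' @slot vafMin,vafMax inclusive child VAF bounds (autosomes, female X).
#' @slot maleXVafMin strict lower VAF bound for male X calls.
#' @slot minAltReads minimum alternate-supporting reads in the child.
#' @slot popfreqMax maximum population allele frequency (strictly greater
#'   removed).
#' @slot parentMaxAltReads maximum parental alt reads (strictly greater
#'   removed).
#' @slot parentMaxVaf maximum parental VAF (strictly greater removed).
#' @slot fdrAlpha significance level for the FDR-adjusted binomial test.
#' @export
setClass("FilterThresholds",
  representation(pDnMin = "numeric", depthMin = "numeric", depthMax = "numeric",
                 vafMin = "numeric", vafMax = "numeric",
                 maleXVafMin = "numeric", minAltReads = "numeric",
                 popfreqMax = "numeric", parentMaxAltReads = "numeric",
                 parentMaxVaf = "numeric", fdrAlpha = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!(object@vafMin >= 0 && object@vafMin < object@vafMax &&
          object@vafMax <= 1))
      msg <- c(msg, "need 0 <= vafMin < vafMax <= 1")
    if (object@depthMin >= object@depthMax)
      msg <- c(msg, "need depthMin < depthMax")
    if (is.null(msg)) TRUE else msg
  })

#' Per-stage audit trail of the filter cascade
#'
#' @slot stages ordered stage names.
#' @slot removed removals per stage (named, same order as stages).
#' @slot inputCount number of candidates entering the cascade.
#' @slot survivingCount number of candidates surviving every stage.
#' @seealso [runCascade()]
#' @export
setClass("FilterTrace",
  representation(stages = "character", removed = "integer",
                 inputCount = "integer", survivingCount = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@removed) != length(object@stages))
      msg <- c(msg, "one removal count per stage required")
    if (any(object@removed < 0))
      msg <- c(msg, "removed counts must be nonnegative")
    if (object@inputCount - sum(object@removed) != object@survivingCount)
      msg <- c(msg, "input - sum(removed) must equal surviving")
    if (is.null(msg)) TRUE else msg
  })

#' Filtered DNM callset with its audit trail
#'
#' @slot candidates all scored candidates with per-stage verdicts
#'   (column \code{first_fail}, \code{NA} for survivors).
#' @slot survivors candidates passing every stage.
#' @slot trace the [FilterTrace-class] of the run.
#' @slot thresholds the [FilterThresholds-class] used.
#' @export
setClass("DNMCallset",
  representation(candidates = "data.frame", survivors = "data.frame",
                 trace = "FilterTrace", thresholds = "FilterThresholds"))

#' Summary of read-backed parent-of-origin phasing
#'
#' @slot nMaternal,nPaternal,nUnphased assignment counts.
#' @slot phaseableFraction (maternal + paternal) / total.
#' @slot alpha paternal:maternal ratio; \code{NA} when no maternal calls.
#' @seealso [summarizePhasing()]
#' @export
setClass("PhasingSummary",
  representation(nMaternal = "integer", nPaternal = "integer",
                 nUnphased = "integer", phaseableFraction = "numeric",
                 alpha = "numeric"),
  validity = function(object) {
    if (object@nMaternal < 0 || object@nPaternal < 0 || object@nUnphased < 0)
      "counts must be nonnegative" else TRUE
  })

#' Callable-genome summary from depth quantisation
#'
#' Base counts in the four coverage categories NO_COVERAGE [0,1),
#' LOW_COVERAGE [1,4), CALLABLE [4,80) and HIGH_COVERAGE [80, Inf).
#'
#' @slot counts named numeric vector over the four categories.
#' @slot total track length (sum of category counts).
#' @seealso [quantizeCallable()]
#' @export
setClass("CallableSummary",
  representation(counts = "numeric", total = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(names(object@counts),
                   c("NO_COVERAGE", "LOW_COVERAGE", "CALLABLE",
                     "HIGH_COVERAGE")))
      msg <- c(msg, "counts must be named by the four coverage categories")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
    if (abs(sum(object@counts) - object@total) > 0.5)
      msg <- c(msg, "category counts must sum to the track length")
    if (is.null(msg)) TRUE else msg
  })

#' Callable-adjusted mutation rate estimate
#'
#' @slot perTrio per-trio rates (count / callable bases).
#' @slot rate cohort rate: mean of per-trio rates.
#' @slot pooledRate pooled alternative: sum(counts) / sum(callable).
#' @slot denominator denominator convention marker
#'   (\code{"haploid-callable"}).
#' @seealso [estimateRate()]
#' @export
setClass("RateEstimate",
  representation(perTrio = "numeric", rate = "numeric",
                 pooledRate = "numeric", denominator = "character"),
  validity = function(object) {
    if (any(object@perTrio < 0) || object@rate < 0)
      "rates must be nonnegative" else TRUE
  })

#' Poisson burden regression fit
#'
#' @slot model label of the count response (\code{"total"} or a mutation
#'   class).
#' @slot coefficients matrix with columns estimate, se, z, p.
#' @slot deviance residual deviance.
#' @slot nobs number of offspring modelled.
#' @slot converged IRLS convergence flag.
#' @seealso [fitBurdenModel()], [fitInteractionModel()]
#' @export
setClass("BurdenFit",
  representation(model = "character", coefficients = "matrix",
                 deviance = "numeric", nobs = "integer",
                 converged = "logical"))

#' Per-context enrichment test result
#'
#' @slot table per-context rate ratios, coefficients and p-values.
#' @slot cpaModel coefficient matrix of the CpA C>T model with MBD4 genotype
#'   and parental-age covariates (\code{NULL} when not fitted).
#' @seealso [contextEnrichmentTest()]
#' @export
setClass("EnrichmentResult",
  representation(table = "data.frame", cpaModel = "ANY"))

#' Candidate-gene screen result
#'
#' @slot retained retained variants or genes.
#' @slot removed per-filter removal counts.
#' @slot proband proband sample id (private-homozygote screen).
#' @slot mode which screen produced the result.
#' @export
setClass("ScreenResult",
  representation(retained = "data.frame", removed = "numeric",
                 proband = "character", mode = "character"))

#' Pedigree layout for the synthetic cohort
#'
#' @slot nControlTrios,nHyperTrios trio counts; hypermutator trios are
#'   exactly those whose dam is MBD4 -/-.
#' @slot paternalAgeRange,maternalAgeRange sampling ranges (years) for
#'   parental ages at conception.
#' @slot offspringSex \code{"random"} or a vector of \code{"M"}/\code{"F"}.
#' @slot hetDamFraction fraction of control dams carrying one MBD4 null
#'   allele (+/-).
#' @export
setClass("PedigreeConfig",
  representation(nControlTrios = "numeric", nHyperTrios = "numeric",
                 paternalAgeRange = "numeric", maternalAgeRange = "numeric",
                 offspringSex = "character", hetDamFraction = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@nControlTrios < 0 || object@nHyperTrios < 0)
      msg <- c(msg, "trio counts must be nonnegative")
    if (any(object@paternalAgeRange <= 0) || any(object@maternalAgeRange <= 0))
      msg <- c(msg, "ages must be positive")
    if (is.null(msg)) TRUE else msg
  })

#' Mutational process parameters of the synthetic cohort
#'
#' @slot controlBurdenMean expected DNMs per offspring at the cohort-mean
#'   parental ages (default 10.5).
#' @slot controlSignatureMix exposure weights over the catalog signatures
#'   for baseline mutations (default 0.2 SBS1-like / 0.8 SBS5-like).
#' @slot maternalCpgExcessMean expected extra maternal CpG C>T mutations in
#'   hypermutator offspring (default 30).
#' @slot maternalCpaExcessMean expected extra maternal CpA C>T mutations
#'   (default 15).
#' @slot paternalFraction probability a baseline DNM is paternal
#'   (default 0.742, i.e. alpha 2.87).
#' @slot paternalAgeSlope,maternalAgeSlope additional mutations per year of
#'   parental age, centred at the cohort mean ages (defaults 1.5 and 0.4).
#' @slot sharedMutationRate expected shared (mosaic-derived) mutations per
#'   sibling pair; 0 by default.
#' @export
setClass("MutationProcessConfig",
  representation(controlBurdenMean = "numeric",
                 controlSignatureMix = "numeric",
                 maternalCpgExcessMean = "numeric",
                 maternalCpaExcessMean = "numeric",
                 paternalFraction = "numeric",
                 paternalAgeSlope = "numeric", maternalAgeSlope = "numeric",
                 sharedMutationRate = "numeric"),
  validity = function(object) {
    msg <- NULL
    means <- c(object@controlBurdenMean, object@maternalCpgExcessMean,
               object@maternalCpaExcessMean, object@sharedMutationRate)
    if (any(means < 0)) msg <- c(msg, "all means must be >= 0")
    mix <- object@controlSignatureMix
    if (any(mix < 0) || abs(sum(mix) - 1) > 1e-6)
      msg <- c(msg, "signature mix must be nonnegative and sum to 1")
    if (object@paternalFraction < 0 || object@paternalFraction > 1)
      msg <- c(msg, "paternalFraction must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
  })

#' Read-evidence parameters of the synthetic cohort
#'
#' @slot referenceLength bases of synthetic reference (default 2e7).
#' @slot xFraction fraction of the reference assigned to a synthetic X
#'   chromosome (0 by default; see the methods vignette).
#' @slot nominalCallableBases genome-scale callable size carried through to
#'   rate computation (default 1.32e9).
#' @slot meanDepth target sequencing coverage (default 23.6).
#' @slot baseErrorRate per-read error probability (default 0.001).
#' @slot informativeSiteDensity informative heterozygous sites per base
#'   (default 0.00151, calibrated so ~53 percent of DNMs are phaseable with
#'   the default fragment length).
#' @slot fragmentLength read-pair linkage window in bp (default 500).
#' @slot artifactRates expected artifact sites per offspring for the seven
#'   artifact classes (all 0 by default).
#' @export
setClass("EvidenceConfig",
  representation(referenceLength = "numeric", xFraction = "numeric",
                 nominalCallableBases = "numeric", meanDepth = "numeric",
                 baseErrorRate = "numeric",
                 informativeSiteDensity = "numeric",
                 fragmentLength = "numeric", artifactRates = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@referenceLength < 1e5)
      msg <- c(msg, "referenceLength must be >= 1e5")
    if (object@meanDepth <= 4 || object@meanDepth >= 80)
      msg <- c(msg, "meanDepth must lie in (4, 80)")
    if (any(object@artifactRates < 0))
      msg <- c(msg, "artifact rates must be >= 0")
    if (!all(names(object@artifactRates) %in% artifactClasses()) ||
        length(object@artifactRates) != length(artifactClasses()))
      msg <- c(msg, "artifactRates must be named by the seven artifact classes")
    if (object@xFraction < 0 || object@xFraction > 0.5)
      msg <- c(msg, "xFraction must lie in [0, 0.5]")
    if (is.null(msg)) TRUE else msg
  })

#' True simulated mutations with provenance labels
#'
#' @slot dnms one row per simulated DNM: offspring, chromosome, position,
#'   ref, alt, forward-strand trinucleotide context, 96-channel label,
#'   parent of origin and process label (\code{baseline}, \code{cpg_excess},
#'   \code{cpa_excess} or an artifact class).
#' @slot pedigree the pedigree table the truth was generated for.
#' @export
setClass("TruthSet",
  representation(dnms = "data.frame", pedigree = "data.frame"))

#' Complete synthetic trio cohort
#'
#' Container returned by [simulateTrioCohort()]: site-level trio read
#' evidence, the generating truth, phased-read observations, informative
#' sites, region masks, a population allele-frequency table, per-sample
#' callable sizes and the reference sequence itself.
#'
#' @slot evidence per-site trio evidence (one row per candidate site).
#' @slot truth the [TruthSet-class].
#' @slot readObs phased-read observations (dnm_id, read_id, dnm_allele,
#'   info_pos, info_allele).
#' @slot infoSites informative heterozygous sites with trio genotypes.
#' @slot repeatMask,segdupMask region masks as \code{GRanges}.
#' @slot popAf population allele-frequency table.
#' @slot pedigree pedigree table with ages, MBD4 genotypes and callable
#'   sizes.
#' @slot reference the synthetic reference (\code{DNAStringSet}).
#' @slot contextFreqs [ContextFrequencies-class] of the reference.
#' @export
setClass("TrioCohort",
  representation(evidence = "data.frame", truth = "TruthSet",
                 readObs = "data.frame", infoSites = "data.frame",
                 repeatMask = "ANY", segdupMask = "ANY",
                 popAf = "data.frame", pedigree = "data.frame",
                 reference = "ANY", contextFreqs = "ContextFrequencies"))
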