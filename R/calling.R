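# Candidate DNM calling: de novo posterior probability and the ordered
# hard-filter cascade with its per-stage audit trail.

#' @rdname FilterThresholds-class
#' @param pDnMin,depthMin,depthMax,vafMin,vafMax,maleXVafMin,minAltReads,popfreqMax,parentMaxAltReads,parentMaxVaf,fdrAlpha
#'   see the class slots.
#' @export
FilterThresholds <- function(pDnMin = 0.5, depthMin = 4, depthMax = 80,
                             vafMin = 0.35, vafMax = 0.70,
                             maleXVafMin = 0.70, minAltReads = 2,
                             popfreqMax = 0.01, parentMaxAltReads = 1,
                             parentMaxVaf = 0.10, fdrAlpha = 0.05) {
  new("FilterThresholds", pDnMin = pDnMin, depthMin = depthMin,
      depthMax = depthMax, vafMin = vafMin, vafMax = vafMax,
      maleXVafMin = maleXVafMin, minAltReads = minAltReads,
      popfreqMax = popfreqMax, parentMaxAltReads = parentMaxAltReads,
      parentMaxVaf = parentMaxVaf, fdrAlpha = fdrAlpha)
}

# genotype machinery for the trio posterior: genotypes RR, RA, AA with
# per-read alt probabilities e, 1/2, 1-e
.GENOTYPES <- c("RR", "RA", "AA")
.gtAltProb <- function(errorRate) c(RR = errorRate, RA = 0.5,
                                    AA = 1 - errorRate)
.gtAltCount <- c(RR = 0L, RA = 1L, AA = 2L)

# Mendelian transmission probability P(child gt | mother gt, father gt)
.mendelTrans <- function(gm, gf, gc) {
  pAlt <- function(g) .gtAltCount[[g]] / 2
  pm <- pAlt(gm); pf <- pAlt(gf)
  switch(gc,
         RR = (1 - pm) * (1 - pf),
         RA = pm * (1 - pf) + (1 - pm) * pf,
         AA = pm * pf)
}

#' De novo posterior probability for trio site evidence
#'
#' Enumerates the 27 diploid genotype configurations of a trio with
#' binomial read likelihoods (per-allele error \code{errorRate}),
#' population genotype priors on the parents (alt allele frequency
#' \code{hetPrior}), Mendelian transmission probabilities, and a flat
#' \code{mutationPrior} on non-Mendelian configurations. Returns the
#' posterior probability that the child carries an allele absent from both
#' parental genotypes.
#'
#' @param evidence data.frame with columns \code{child_dp},
#'   \code{child_alt_ad}, \code{mother_dp}, \code{mother_alt_ad},
#'   \code{father_dp}, \code{father_alt_ad} (one row per site).
#' @param errorRate per-read error probability of the likelihood model
#'   (default 0.005).
#' @param mutationPrior prior weight of a non-Mendelian transmission. The
#'   default (1e-2) is deliberately permissive: trio callers admit
#'   thousands of candidates per individual past the posterior gate and
#'   leave removal to the explicit filter cascade, so sites with, say, a
#'   low-coverage or alt-carrying parent must reach the stage built to
#'   reject them. Supplying the biological per-base rate (~1e-8) instead
#'   yields a strict Bayesian gate that pre-empts the depth and parental
#'   stages.
#' @param hetPrior population alternate-allele frequency used for the
#'   parental genotype priors (default 1e-3).
#' @return numeric vector of posteriors in [0, 1].
#' @export
denovoPosterior <- function(evidence, errorRate = 0.005,
                            mutationPrior = 1e-2, hetPrior = 1e-3) {
  req <- c("child_dp", "child_alt_ad", "mother_dp", "mother_alt_ad",
           "father_dp", "father_alt_ad")
  stopifnot(all(req %in% names(evidence)))
  if (nrow(evidence) == 0) return(numeric(0))
  if (any(evidence$child_dp <= 0 | evidence$mother_dp <= 0 |
            evidence$father_dp <= 0))
    stop("zero read depth in a sample: site not callable")
  pa <- .gtAltProb(errorRate)
  th <- hetPrior
  gtPrior <- c(RR = (1 - th)^2, RA = 2 * th * (1 - th), AA = th^2)
  lik <- function(dp, alt) {
    sapply(.GENOTYPES, function(g) dbinom(alt, dp, pa[[g]]))
  }
  Lm <- lik(evidence$mother_dp, evidence$mother_alt_ad)
  Lf <- lik(evidence$father_dp, evidence$father_alt_ad)
  Lc <- lik(evidence$child_dp, evidence$child_alt_ad)
  if (is.null(dim(Lm))) {  # single site: sapply returned a vector
    Lm <- matrix(Lm, 1); Lf <- matrix(Lf, 1); Lc <- matrix(Lc, 1)
    colnames(Lm) <- colnames(Lf) <- colnames(Lc) <- .GENOTYPES
  }
  num <- den <- numeric(nrow(Lm))
  for (gm in .GENOTYPES) for (gf in .GENOTYPES) for (gc in .GENOTYPES) {
    tp <- .mendelTrans(gm, gf, gc)
    tp <- if (tp > 0) tp else mutationPrior
    w <- gtPrior[[gm]] * gtPrior[[gf]] * tp *
      Lm[, gm] * Lf[, gf] * Lc[, gc]
    # de novo: child carries an allele absent from both parents
    deNovo <- (.gtAltCount[[gc]] > 0 && .gtAltCount[[gm]] == 0 &&
                 .gtAltCount[[gf]] == 0) ||
      (.gtAltCount[[gc]] < 2 && .gtAltCount[[gm]] == 2 &&
         .gtAltCount[[gf]] == 2)
    den <- den + w
    if (deNovo) num <- num + w
  }
  as.numeric(num / den)
}

#' Score candidates with the de novo posterior and child VAF
#'
#' @param evidence site-level trio evidence (as from
#'   [simulateSiteEvidence()] or [readTrioVcf()]).
#' @param ... passed to [denovoPosterior()].
#' @return the evidence with columns \code{p_dn} and \code{vaf} appended.
#' @export
callCandidates <- function(evidence, ...) {
  evidence$p_dn <- denovoPosterior(evidence, ...)
  evidence$vaf <- evidence$child_alt_ad / evidence$child_dp
  evidence
}

.normChrom <- function(chrom) {
  x <- sub("^chr", "", tolower(chrom))
  ifelse(x == "x", "X", ifelse(x == "y", "Y", x))
}

#' Site-level hard filters
#'
#' Applies, in order, the depth, VAF/chromosome, strand and
#' parental-evidence rules and records the first failing stage per
#' candidate. Depth must lie within \code{[depthMin, depthMax]} in the
#' child and both parents. Child VAF must lie within
#' \code{[vafMin, vafMax]} on autosomes and the female X, and strictly
#' above \code{maleXVafMin} on the male X; Y-chromosome calls are
#' excluded. Alternate reads must appear on both strands with at least
#' \code{minAltReads} alternate reads. A candidate fails the parental
#' stage when either parent shows more than \code{parentMaxAltReads}
#' alternate reads or a VAF above \code{parentMaxVaf}.
#'
#' @param candidates scored candidate data.frame (see [callCandidates()]).
#' @param thresholds a [FilterThresholds-class].
#' @return character vector: \code{NA} for a pass, otherwise the first
#'   failing stage (\code{"depth"}, \code{"vaf"}, \code{"strand"},
#'   \code{"parental"}).
#' @export
evaluateSiteFilters <- function(candidates, thresholds = FilterThresholds()) {
  th <- thresholds
  chrom <- .normChrom(candidates$chrom)
  known <- grepl("^[0-9]+$", chrom) | chrom %in% c("X", "Y")
  if (any(!known))
    stop("unknown chromosome label(s): ",
         paste(unique(candidates$chrom[!known]), collapse = ", "))
  if (any(chrom == "X" & (is.na(candidates$child_sex) |
                            !candidates$child_sex %in% c("M", "F"))))
    stop("child sex is required for X-chromosome VAF rules")
  vaf <- candidates$child_alt_ad / candidates$child_dp
  inBand <- function(x, lo, hi) x >= lo & x <= hi
  failDepth <- !(inBand(candidates$child_dp, th@depthMin, th@depthMax) &
                   inBand(candidates$mother_dp, th@depthMin, th@depthMax) &
                   inBand(candidates$father_dp, th@depthMin, th@depthMax))
  maleX <- chrom == "X" & candidates$child_sex == "M"
  failVaf <- ifelse(chrom == "Y", TRUE,
                    ifelse(maleX, vaf <= th@maleXVafMin,
                           !inBand(vaf, th@vafMin, th@vafMax)))
  failStrand <- candidates$child_alt_ad < th@minAltReads |
    candidates$child_adf < 1 | candidates$child_adr < 1
  # hemizygous male X: all alt reads sit on one haplotype but both strands
  # are still required, as for autosomes
  mVaf <- candidates$mother_alt_ad / candidates$mother_dp
  fVaf <- candidates$father_alt_ad / candidates$father_dp
  failParent <- candidates$mother_alt_ad > th@parentMaxAltReads |
    candidates$father_alt_ad > th@parentMaxAltReads |
    mVaf > th@parentMaxVaf | fVaf > th@parentMaxVaf
  out <- rep(NA_character_, nrow(candidates))
  out[failParent] <- "parental"
  out[failStrand] <- "strand"
  out[failVaf] <- "vaf"
  out[failDepth] <- "depth"
  out
}

#' Remove candidates falling inside region masks
#'
#' Containment is tested on the single mutated base against 0-based
#' half-open BED intervals (the repeat mask is applied before the
#' segmental-duplication mask).
#'
#' @param candidates candidate data.frame with \code{chrom} and \code{pos}
#'   (1-based).
#' @param repeatMask,segdupMask \code{GRanges} masks (1-based, as returned
#'   by [readBedMask()]); \code{NULL} for no mask.
#' @return list with \code{survivors}, \code{removedRepeat},
#'   \code{removedSegdup} (counts) and \code{stage} (per-candidate mask
#'   verdict, \code{NA} = kept).
#' @export
regionMaskFilter <- function(candidates, repeatMask = NULL,
                             segdupMask = NULL) {
  n <- nrow(candidates)
  stage <- rep(NA_character_, n)
  if (n > 0) {
    gr <- GRanges(candidates$chrom, IRanges(candidates$pos, candidates$pos))
    hitSeg <- if (!is.null(segdupMask) && length(segdupMask) > 0)
      overlapsAny(gr, segdupMask) else rep(FALSE, n)
    hitRep <- if (!is.null(repeatMask) && length(repeatMask) > 0)
      overlapsAny(gr, repeatMask) else rep(FALSE, n)
    stage[hitSeg] <- "segdup_mask"
    stage[hitRep] <- "repeat_mask"   # repeats take precedence
  }
  list(survivors = candidates[is.na(stage), , drop = FALSE],
       removedRepeat = sum(stage == "repeat_mask", na.rm = TRUE),
       removedSegdup = sum(stage == "segdup_mask", na.rm = TRUE),
       stage = stage)
}

#' Remove candidates common in the population
#'
#' Candidates with allele frequency strictly above \code{popfreqMax} are
#' removed; candidates absent from the table are treated as novel and
#' kept.
#'
#' @param candidates candidate data.frame.
#' @param afTable data.frame with columns chrom, pos, ref, alt, af;
#'   \code{NULL} to rely on a \code{pop_af} column in the candidates.
#' @param popfreqMax removal threshold (default 0.01).
#' @return logical vector: TRUE = removed.
#' @export
popfreqFilter <- function(candidates, afTable = NULL, popfreqMax = 0.01) {
  af <- candidates$pop_af
  if (is.null(af)) af <- rep(NA_real_, nrow(candidates))
  if (!is.null(afTable) && nrow(afTable) > 0) {
    key <- paste(candidates$chrom, candidates$pos, candidates$ref,
                 candidates$alt)
    tkey <- paste(afTable$chrom, afTable$pos, afTable$ref, afTable$alt)
    hit <- match(key, tkey)
    af <- ifelse(!is.na(hit), afTable$af[hit], af)
  }
  if (any(!is.na(af) & (af < 0 | af > 1)))
    stop("allele frequency outside [0, 1]")
  !is.na(af) & af > popfreqMax
}

# exact two-sided binomial p-value at p = 0.5 (minimum-likelihood method,
# matching binom.test; symmetric at 0.5 so equal to the doubled tail)
.binomTwoSided <- function(alt, dp) {
  if (any(dp <= 0)) stop("zero depth in binomial allele-balance test")
  lo <- pmin(alt, dp - alt)
  pmin(1, 2 * pbinom(lo, dp, 0.5) -
         ifelse(2 * lo == dp, dbinom(lo, dp, 0.5), 0))
}

#' Binomial allele-balance test with FDR correction
#'
#' Two-sided exact binomial test of the child's alternate read count
#' against depth at success probability 0.5, Benjamini-Hochberg adjusted
#' within each offspring. Candidates with adjusted p below \code{fdrAlpha}
#' are removed.
#'
#' @param candidates candidate data.frame with \code{child_alt_ad},
#'   \code{child_dp} and an \code{offspring} grouping column.
#' @param fdrAlpha significance level (default 0.05).
#' @return list with \code{p}, \code{padj} and \code{removed} (logical).
#' @export
binomialFdrFilter <- function(candidates, fdrAlpha = 0.05) {
  n <- nrow(candidates)
  if (n == 0)
    return(list(p = numeric(0), padj = numeric(0), removed = logical(0)))
  p <- .binomTwoSided(candidates$child_alt_ad, candidates$child_dp)
  grp <- if ("offspring" %in% names(candidates))
    candidates$offspring else rep("all", n)
  padj <- p
  for (g in unique(grp)) {
    sel <- grp == g
    padj[sel] <- p.adjust(p[sel], method = "BH")
  }
  list(p = p, padj = padj, removed = padj < fdrAlpha)
}

#' Run the full DNM filter cascade
#'
#' Applies, in order: de novo posterior selection (\code{p_dn > pDnMin});
#' depth; VAF / chromosome rules; strand support; repeat mask; segmental
#' duplication mask; population allele frequency; parental evidence; and
#' the binomial allele-balance test with per-offspring FDR correction.
#' Each candidate is attributed to the first stage that removes it.
#'
#' @param candidates scored candidates (see [callCandidates()]).
#' @param thresholds a [FilterThresholds-class].
#' @param repeatMask,segdupMask \code{GRanges} region masks (optional).
#' @param afTable population allele-frequency table (optional).
#' @return a [DNMCallset-class] holding survivors and the
#'   [FilterTrace-class].
#' @export
runCascade <- function(candidates, thresholds = FilterThresholds(),
                       repeatMask = NULL, segdupMask = NULL,
                       afTable = NULL) {
  stages <- c("p_dn", "depth", "vaf", "strand", "repeat_mask",
              "segdup_mask", "popfreq", "parental", "binomial_fdr")
  n <- nrow(candidates)
  fail <- rep(NA_character_, n)
  if (n > 0) {
    if (is.null(candidates$p_dn))
      stop("candidates must carry a p_dn column; run callCandidates first")
    siteStage <- evaluateSiteFilters(candidates, thresholds)
    maskRes <- regionMaskFilter(candidates, repeatMask, segdupMask)
    popHit <- popfreqFilter(candidates, afTable, thresholds@popfreqMax)
    # attribute each candidate to the earliest failing stage:
    # depth/vaf/strand precede the masks; parental comes after popfreq
    fail[siteStage %in% c("depth", "vaf", "strand")] <-
      siteStage[siteStage %in% c("depth", "vaf", "strand")]
    fail[is.na(fail) & maskRes$stage %in% "repeat_mask"] <- "repeat_mask"
    fail[is.na(fail) & maskRes$stage %in% "segdup_mask"] <- "segdup_mask"
    fail[is.na(fail) & popHit] <- "popfreq"
    fail[is.na(fail) & siteStage %in% "parental"] <- "parental"
    # the posterior gate is the first stage of all
    fail[candidates$p_dn <= thresholds@pDnMin] <- "p_dn"
    # binomial FDR runs on the candidates surviving everything above
    alive <- is.na(fail)
    if (any(alive)) {
      bres <- binomialFdrFilter(candidates[alive, , drop = FALSE],
                                thresholds@fdrAlpha)
      idx <- which(alive)[bres$removed]
      fail[idx] <- "binomial_fdr"
      candidates$binomial_p <- NA_real_
      candidates$fdr_adjusted_p <- NA_real_
      candidates$binomial_p[alive] <- bres$p
      candidates$fdr_adjusted_p[alive] <- bres$padj
    } else {
      candidates$binomial_p <- NA_real_
      candidates$fdr_adjusted_p <- NA_real_
    }
  }
  candidates$first_fail <- fail
  removed <- vapply(stages, function(s) sum(fail == s, na.rm = TRUE),
                    integer(1))
  trace <- new("FilterTrace", stages = stages, removed = removed,
               inputCount = as.integer(n),
               survivingCount = as.integer(sum(is.na(fail))))
  new("DNMCallset", candidates = candidates,
      survivors = candidates[is.na(fail), , drop = FALSE],
      trace = trace, thresholds = thresholds)
}

#' @describeIn runCascade accessor for the surviving candidates.
#' @param x a \code{DNMCallset}.
#' @export
survivors <- function(x) {
  stopifnot(is(x, "DNMCallset"))
  x@survivors
}

#' @describeIn runCascade accessor for the filter trace.
#' @export
filterTrace <- function(x) {
  stopifnot(is(x, "DNMCallset"))
  x@trace
}

#' @describeIn runCascade per-stage removal counts of a trace (named).
#' @param trace a \code{FilterTrace}.
#' @export
stageRemovals <- function(trace) {
  stopifnot(is(trace, "FilterTrace"))
  setNames(trace@removed, trace@stages)
}
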