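# Synthetic trio cohort generator: pedigrees, true DNMs under control and
# hypermutator mutational processes, and site-level trio read evidence
# including the artifact classes the filter cascade is designed to remove.

# deterministic substream seed derivation (kept below 2^31)
.substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 10007 + k * 7919) %% 2147483629)
}

#' @rdname PedigreeConfig-class
#' @param nControlTrios,nHyperTrios,paternalAgeRange,maternalAgeRange,offspringSex,hetDamFraction
#'   see the class slots.
#' @export
PedigreeConfig <- function(nControlTrios = 1, nHyperTrios = 0,
                           paternalAgeRange = c(5, 15),
                           maternalAgeRange = c(4, 12),
                           offspringSex = "random",
                           hetDamFraction = 0.02) {
  new("PedigreeConfig", nControlTrios = nControlTrios,
      nHyperTrios = nHyperTrios, paternalAgeRange = paternalAgeRange,
      maternalAgeRange = maternalAgeRange, offspringSex = offspringSex,
      hetDamFraction = hetDamFraction)
}

#' @rdname MutationProcessConfig-class
#' @param controlBurdenMean,controlSignatureMix,maternalCpgExcessMean,maternalCpaExcessMean,paternalFraction,paternalAgeSlope,maternalAgeSlope,sharedMutationRate
#'   see the class slots.
#' @export
MutationProcessConfig <- function(controlBurdenMean = 10.5,
                                  controlSignatureMix =
                                    c(SBS1like = 0.2, SBS5like = 0.8),
                                  maternalCpgExcessMean = 30,
                                  maternalCpaExcessMean = 15,
                                  paternalFraction = 0.742,
                                  paternalAgeSlope = 1.5,
                                  maternalAgeSlope = 0.4,
                                  sharedMutationRate = 0) {
  new("MutationProcessConfig", controlBurdenMean = controlBurdenMean,
      controlSignatureMix = controlSignatureMix,
      maternalCpgExcessMean = maternalCpgExcessMean,
      maternalCpaExcessMean = maternalCpaExcessMean,
      paternalFraction = paternalFraction,
      paternalAgeSlope = paternalAgeSlope,
      maternalAgeSlope = maternalAgeSlope,
      sharedMutationRate = sharedMutationRate)
}

#' @rdname EvidenceConfig-class
#' @param referenceLength,xFraction,nominalCallableBases,meanDepth,baseErrorRate,informativeSiteDensity,fragmentLength,artifactRates
#'   see the class slots.
#' @export
EvidenceConfig <- function(referenceLength = 2e7, xFraction = 0,
                           nominalCallableBases = 1.32e9,
                           meanDepth = 23.6, baseErrorRate = 0.001,
                           informativeSiteDensity = 0.00151,
                           fragmentLength = 500,
                           artifactRates = setNames(numeric(7),
                                                    artifactClasses())) {
  if (fragmentLength < 1) stop("fragmentLength must be >= 1")
  full <- setNames(numeric(7), artifactClasses())
  full[names(artifactRates)] <- artifactRates
  new("EvidenceConfig", referenceLength = referenceLength,
      xFraction = xFraction, nominalCallableBases = nominalCallableBases,
      meanDepth = meanDepth, baseErrorRate = baseErrorRate,
      informativeSiteDensity = informativeSiteDensity,
      fragmentLength = fragmentLength, artifactRates = full)
}

#' Simulate a random reference genome
#'
#' Generates an i.i.d. base sequence at the requested GC content, split
#' into an autosome \code{chr1} and, when \code{xFraction > 0}, a synthetic
#' X chromosome \code{chrX}.
#'
#' @param length total reference length in bases.
#' @param xFraction fraction of the length assigned to \code{chrX}.
#' @param gc GC content (default 0.42, primate-like).
#' @param seed integer seed.
#' @return a \code{DNAStringSet}.
#' @export
simulateReference <- function(length = 2e7, xFraction = 0, gc = 0.42,
                              seed = 1) {
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- utf8ToInt("ACGT")
  lens <- c(chr1 = round(length * (1 - xFraction)))
  if (xFraction > 0) lens <- c(lens, chrX = round(length * xFraction))
  seqs <- vapply(lens, function(n) {
    intToUtf8(sample(codes, n, replace = TRUE, prob = probs))
  }, character(1))
  DNAStringSet(seqs)
}

#' Build a pedigree table from a pedigree configuration
#'
#' Control trios have unrelated parents; all hypermutator trios share a
#' single MBD4 -/- dam mated to different sires, mirroring the structure of
#' a hypermutator half-sibship. Parental ages are drawn uniformly from the
#' configured ranges; per-sample callable sizes are drawn around the
#' nominal callable genome (sd 2.5 percent).
#'
#' @param config a [PedigreeConfig-class].
#' @param seed integer seed.
#' @param nominalCallableBases callable-genome scale for the per-sample
#'   callable sizes.
#' @return data.frame with one row per trio.
#' @export
buildPedigree <- function(config, seed = 1, nominalCallableBases = 1.32e9) {
  set.seed(seed)
  nC <- config@nControlTrios
  nH <- config@nHyperTrios
  n <- nC + nH
  if (n == 0) stop("pedigree must contain at least one trio")
  hyper <- c(rep(FALSE, nC), rep(TRUE, nH))
  trio <- sprintf("T%04d", seq_len(n))
  sex <- if (identical(config@offspringSex, "random"))
    sample(c("M", "F"), n, replace = TRUE)
  else rep_len(config@offspringSex, n)
  motherMbd4 <- ifelse(hyper, "-/-",
    ifelse(runif(n) < config@hetDamFraction, "+/-", "+/+"))
  mother <- ifelse(hyper, "DAM_H",
                   sprintf("DAM%04d", seq_len(n)))
  data.frame(
    trio = trio,
    child = sprintf("CH%04d", seq_len(n)),
    mother = mother,
    father = sprintf("SIRE%04d", seq_len(n)),
    child_sex = sex,
    paternal_age = round(runif(n, config@paternalAgeRange[1],
                               config@paternalAgeRange[2]), 1),
    maternal_age = round(runif(n, config@maternalAgeRange[1],
                               config@maternalAgeRange[2]), 1),
    mother_mbd4 = motherMbd4,
    father_mbd4 = "+/+",
    hypermutator = hyper,
    callable = round(pmax(rnorm(n, nominalCallableBases,
                                0.025 * nominalCallableBases),
                          0.5 * nominalCallableBases)),
    stringsAsFactors = FALSE)
}

# place n mutations at positions matching the requested channels;
# channels: vector of 96-channel labels, one per mutation
.placeMutations <- function(index, channels) {
  n <- length(channels)
  if (n == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      context = character(0), channel = character(0),
                      stringsAsFactors = FALSE))
  ctx <- .channelContext(channels)
  altPyr <- substr(channels, 5, 5)
  ctxLevels <- contexts32()
  out <- data.frame(chrom = rep(NA_character_, n), pos = NA_integer_,
                    ref = NA_character_, alt = NA_character_,
                    context = NA_character_, channel = channels,
                    stringsAsFactors = FALSE)
  for (cx in unique(ctx)) {
    rows <- which(ctx == cx)
    pools <- .contextPositions(index, match(cx, ctxLevels))
    sizes <- vapply(pools, length, integer(1))
    if (sum(sizes) == 0)
      stop("context ", cx, " absent from the reference")
    chromPick <- sample(names(pools), length(rows), replace = TRUE,
                        prob = sizes / sum(sizes))
    for (ch_ in unique(chromPick)) {
      rr <- rows[chromPick == ch_]
      pos <- pools[[ch_]][sample.int(length(pools[[ch_]]), length(rr),
                                     replace = TRUE)]
      fwd <- .contextAt(index, ch_, pos)
      ctr <- substr(fwd, 2, 2)
      isPyr <- ctr %in% c("C", "T")
      out$chrom[rr] <- ch_
      out$pos[rr] <- pos
      out$context[rr] <- fwd
      out$ref[rr] <- ctr
      out$alt[rr] <- ifelse(isPyr, altPyr[rr],
                            unname(.COMPLEMENT[altPyr[rr]]))
    }
  }
  out
}

#' Simulate true de novo mutations for a pedigree
#'
#' Per-offspring baseline counts are Poisson with mean
#' \code{controlBurdenMean} plus linear parental-age effects centred at the
#' realised cohort mean ages (so the configured burden is the cohort mean).
#' Baseline channels are drawn from the control signature mixture
#' renormalised to the reference's trinucleotide frequencies, and placed
#' uniformly among context-matching reference positions. Hypermutator
#' offspring additionally receive Poisson-distributed maternal CpG C>T and
#' CpA C>T excess mutations. Baseline parent of origin is Bernoulli with
#' the configured paternal fraction; excess mutations are always maternal.
#'
#' @param pedigree a pedigree data.frame from [buildPedigree()] or a
#'   [PedigreeConfig-class] (built internally with the same seed).
#' @param process a [MutationProcessConfig-class].
#' @param reference reference sequence (or a prebuilt context index).
#' @param seed integer seed.
#' @param catalog signature catalog defining the control mixture channels
#'   (default the packaged synthetic catalog).
#' @return a [TruthSet-class].
#' @export
simulateTruthDnms <- function(pedigree, process, reference, seed = 1,
                              catalog = syntheticSignatureCatalog()) {
  if (is(pedigree, "PedigreeConfig"))
    pedigree <- buildPedigree(pedigree, seed = .substream(seed, 1))
  index <- if (is.list(reference) && !is.null(reference$code2ctx32))
    reference else .contextIndex(reference)
  set.seed(.substream(seed, 2))
  fTarget <- buildContextModel(DNAStringSet(index$seqs))
  renorm <- renormalizeCatalog(catalog, syntheticSourceFrequencies(),
                               fTarget)
  mix <- process@controlSignatureMix
  probs <- signatureProbs(renorm)[, names(mix), drop = FALSE] %*% mix
  chLevels <- sbsChannels()

  patC <- mean(pedigree$paternal_age)
  matC <- mean(pedigree$maternal_age)
  lam <- pmax(process@controlBurdenMean +
                process@paternalAgeSlope * (pedigree$paternal_age - patC) +
                process@maternalAgeSlope * (pedigree$maternal_age - matC),
              0)
  nBase <- rpois(nrow(pedigree), lam)
  nCpg <- ifelse(pedigree$hypermutator,
                 rpois(nrow(pedigree), process@maternalCpgExcessMean), 0L)
  nCpa <- ifelse(pedigree$hypermutator,
                 rpois(nrow(pedigree), process@maternalCpaExcessMean), 0L)

  pieces <- vector("list", nrow(pedigree))
  for (i in seq_len(nrow(pedigree))) {
    chans <- character(0)
    proc <- character(0)
    if (nBase[i] > 0) {
      chans <- c(chans, sample(chLevels, nBase[i], replace = TRUE,
                               prob = as.numeric(probs)))
      proc <- c(proc, rep("baseline", nBase[i]))
    }
    if (nCpg[i] > 0) {
      chans <- c(chans, sample(cpgCtChannels(), nCpg[i], replace = TRUE,
                               prob = contextFreq(fTarget)[
                                 .channelContext(cpgCtChannels())]))
      proc <- c(proc, rep("cpg_excess", nCpg[i]))
    }
    if (nCpa[i] > 0) {
      chans <- c(chans, sample(cpaCtChannels(), nCpa[i], replace = TRUE,
                               prob = contextFreq(fTarget)[
                                 .channelContext(cpaCtChannels())]))
      proc <- c(proc, rep("cpa_excess", nCpa[i]))
    }
    if (length(chans) == 0) next
    placed <- .placeMutations(index, chans)
    placed$process <- proc
    placed$parent <- ifelse(proc == "baseline",
                            ifelse(runif(length(proc)) <
                                     process@paternalFraction,
                                   "paternal", "maternal"),
                            "maternal")
    # male X is inherited only from the dam
    placed$parent[placed$chrom == "chrX" &
                    pedigree$child_sex[i] == "M"] <- "maternal"
    placed$offspring <- pedigree$child[i]
    placed$trio <- pedigree$trio[i]
    placed$sex <- pedigree$child_sex[i]
    # resample duplicate positions within an offspring
    dup <- duplicated(paste(placed$chrom, placed$pos))
    while (any(dup)) {
      redo <- .placeMutations(index, placed$channel[dup])
      placed[dup, names(redo)] <- redo
      dup <- duplicated(paste(placed$chrom, placed$pos))
    }
    pieces[[i]] <- placed
  }
  dnms <- do.call(rbind, pieces)
  if (is.null(dnms))
    dnms <- data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       context = character(0), channel = character(0),
                       process = character(0), parent = character(0),
                       offspring = character(0), trio = character(0),
                       sex = character(0), stringsAsFactors = FALSE)
  # optional mosaic-derived sharing: copy mutations between maternal sibs
  if (process@sharedMutationRate > 0 && !is.null(dnms) && nrow(dnms) > 0) {
    extra <- list()
    for (i in seq_len(nrow(pedigree))) {
      sibs <- pedigree$child[pedigree$mother == pedigree$mother[i] &
                               pedigree$child != pedigree$child[i]]
      pool <- dnms[dnms$offspring %in% sibs, , drop = FALSE]
      if (nrow(pool) == 0) next
      k <- min(rpois(1, process@sharedMutationRate), nrow(pool))
      if (k == 0) next
      cp <- pool[sample.int(nrow(pool), k), , drop = FALSE]
      cp$offspring <- pedigree$child[i]
      cp$trio <- pedigree$trio[i]
      cp$sex <- pedigree$child_sex[i]
      cp$parent <- "maternal"
      cp$process <- "shared"
      extra[[length(extra) + 1L]] <- cp
    }
    if (length(extra)) dnms <- rbind(dnms, do.call(rbind, extra))
  }
  if (nrow(dnms) > 0) {
    dnms$dnm_id <- sprintf("%s_%s_%d", dnms$offspring, dnms$chrom, dnms$pos)
    rownames(dnms) <- NULL
  } else dnms$dnm_id <- character(0)
  new("TruthSet", dnms = dnms, pedigree = pedigree)
}

#' @describeIn simulateTruthDnms accessor for the truth table.
#' @param x a \code{TruthSet}.
#' @export
truthDnms <- function(x) {
  stopifnot(is(x, "TruthSet"))
  x@dnms
}

# truncated binomial draw with alt/size constrained to [lo, hi] (fractions)
.rbinomBand <- function(size, p, lo, hi) {
  vapply(size, function(n) {
    ks <- max(ceiling(lo * n), 2):floor(hi * n)
    if (length(ks) == 0 || ks[1] > n) ks <- max(2, round(p * n))
    w <- dbinom(ks, n, p)
    if (sum(w) == 0) w <- rep(1, length(ks))
    ks[sample.int(length(ks), 1, prob = w)]
  }, numeric(1))
}

# one clean heterozygous child evidence row (conditioned to pass the depth,
# VAF and strand stages when condition = TRUE)
.childEvidence <- function(n, meanDepth, condition = FALSE) {
  dp <- pmax(rpois(n, meanDepth), 1)
  if (condition) {
    dp <- pmin(pmax(dp, 6), 80)
    alt <- .rbinomBand(dp, 0.5, 0.35, 0.70)
    adf <- vapply(alt, function(a) {
      ks <- 1:(a - 1)
      ks[sample.int(length(ks), 1, prob = dbinom(ks, a, 0.5))]
    }, numeric(1))
  } else {
    alt <- rbinom(n, dp, 0.5)
    adf <- rbinom(n, alt, 0.5)
  }
  data.frame(dp = dp, alt = alt, adf = adf, adr = alt - adf)
}

#' Simulate site-level trio read evidence for a truth set
#'
#' For every true DNM the child receives Poisson read depth around the
#' configured mean with binomially sampled alternate reads (probability 0.5
#' on autosomes, near 1 on male X where depth is halved), a binomial strand
#' split, and parental alternate reads arising from the base error rate
#' only. Artifact sites are injected per artifact class, each constructed
#' to violate exactly the cascade stage it targets while passing all
#' earlier stages. Read observations linking DNM alleles to nearby
#' informative heterozygous sites are generated within the fragment
#' length.
#'
#' @param truth a [TruthSet-class].
#' @param config an [EvidenceConfig-class].
#' @param reference the reference used to build the truth (or its context
#'   index).
#' @param seed integer seed.
#' @return list with elements \code{evidence}, \code{readObs},
#'   \code{infoSites}, \code{repeatMask}, \code{segdupMask}, \code{popAf}.
#' @export
simulateSiteEvidence <- function(truth, config, reference, seed = 1) {
  if (config@fragmentLength < 1) stop("fragmentLength must be >= 1")
  index <- if (is.list(reference) && !is.null(reference$code2ctx32))
    reference else .contextIndex(reference)
  ped <- truth@pedigree
  dnms <- truth@dnms
  if (nrow(dnms) > 0) {
    inRef <- dnms$chrom %in% names(index$seqs) & dnms$pos >= 1 &
      dnms$pos <= index$lens[dnms$chrom]
    if (!all(inRef)) stop("truth positions outside the reference")
  }
  set.seed(.substream(seed, 3))
  md <- config@meanDepth
  err <- config@baseErrorRate

  evid <- list(); reads <- list(); infos <- list()
  repeatIv <- list(); popRows <- list()
  readCounter <- 0L

  # ---- true DNMs -----------------------------------------------------------
  if (nrow(dnms) > 0) {
    n <- nrow(dnms)
    maleX <- dnms$chrom == "chrX" & dnms$sex == "M"
    cdp <- pmax(rpois(n, ifelse(maleX, md / 2, md)), 1)
    calt <- ifelse(maleX, rbinom(n, cdp, 1 - err), rbinom(n, cdp, 0.5))
    cadf <- rbinom(n, calt, 0.5)
    onX <- dnms$chrom == "chrX"
    mdp <- pmax(rpois(n, md), 1)
    fdp <- pmax(rpois(n, ifelse(onX, md / 2, md)), 1)
    ev <- data.frame(
      dnm_id = dnms$dnm_id, trio = dnms$trio, offspring = dnms$offspring,
      chrom = dnms$chrom, pos = dnms$pos, ref = dnms$ref, alt = dnms$alt,
      child_sex = dnms$sex,
      child_dp = cdp, child_ref_ad = cdp - calt, child_alt_ad = calt,
      child_adf = cadf, child_adr = calt - cadf,
      mother_dp = mdp, mother_ref_ad = NA, mother_alt_ad = rbinom(n, mdp, err),
      father_dp = fdp, father_ref_ad = NA, father_alt_ad = rbinom(n, fdp, err),
      pop_af = NA_real_, is_true = TRUE, class = dnms$process,
      true_parent = dnms$parent, stringsAsFactors = FALSE)
    ev$mother_ref_ad <- ev$mother_dp - ev$mother_alt_ad
    ev$father_ref_ad <- ev$father_dp - ev$father_alt_ad
    ev$mother_adf <- rbinom(n, ev$mother_alt_ad, 0.5)
    ev$mother_adr <- ev$mother_alt_ad - ev$mother_adf
    ev$father_adf <- rbinom(n, ev$father_alt_ad, 0.5)
    ev$father_adr <- ev$father_alt_ad - ev$father_adf
    evid[[length(evid) + 1L]] <- ev

    # ---- read-backed linkage to informative sites -------------------------
    lnk <- config@informativeSiteDensity * config@fragmentLength
    nInfo <- rpois(n, lnk)
    nInfo[onX] <- 0L  # informative-site model is autosomal
    if (sum(nInfo) > 0) {
      src <- rep(seq_len(n), nInfo)          # DNM row per info site
      tot <- length(src)
      off <- round(runif(tot, -config@fragmentLength / 2,
                         config@fragmentLength / 2))
      off[off == 0] <- 1L
      lens <- index$lens
      ipos <- pmin(pmax(dnms$pos[src] + off, 2), lens[dnms$chrom[src]] - 1)
      ipos <- ifelse(ipos == dnms$pos[src], ipos + 1L, ipos)
      # distinct informative sites of one trio must not share a position
      # (the allele-to-parent map is keyed by position)
      key <- paste(dnms$trio[src], ipos)
      while (anyDuplicated(key)) {
        d <- which(duplicated(key))
        ipos[d] <- pmin(pmax(ipos[d] + sample(1:97, length(d),
                                              replace = TRUE), 2),
                        lens[dnms$chrom[src][d]] - 1)
        key <- paste(dnms$trio[src], ipos)
      }
      momInf <- runif(tot) < 0.5
      # allele carried by the haplotype bearing the DNM
      hapAllele <- ifelse(momInf,
                          ifelse(dnms$parent[src] == "maternal", "1", "0"),
                          ifelse(dnms$parent[src] == "paternal", "1", "0"))
      infos[[1L]] <- data.frame(
        trio = dnms$trio[src], chrom = dnms$chrom[src], pos = ipos,
        mother_gt = ifelse(momInf, "0/1", "0/0"),
        father_gt = ifelse(momInf, "0/0", "0/1"),
        child_gt = "0/1", stringsAsFactors = FALSE)
      nSupp <- sample(2:4, tot, replace = TRUE)
      # supporting reads carry the DNM alt and the linked haplotype allele;
      # one reference-haplotype read per site carries the other allele
      expand <- rep(seq_len(tot), nSupp + 1L)
      isAlt <- sequence(nSupp + 1L) <= rep(nSupp, nSupp + 1L)
      reads[[1L]] <- data.frame(
        dnm_id = dnms$dnm_id[src][expand],
        read_id = sprintf("read%07d", seq_along(expand)),
        dnm_allele = ifelse(isAlt, "alt", "ref"),
        info_pos = ipos[expand],
        info_allele = ifelse(isAlt, hapAllele[expand],
                             ifelse(hapAllele[expand] == "1", "0", "1")),
        stringsAsFactors = FALSE)
    }
  }

  # ---- artifact sites ------------------------------------------------------
  rates <- config@artifactRates
  usedPos <- if (nrow(dnms) > 0)
    paste(dnms$chrom, dnms$pos) else character(0)
  autos <- setdiff(names(index$seqs), "chrX")
  sampleSite <- function() {
    ch_ <- if (length(autos) == 1) autos else
      sample(autos, 1, prob = index$lens[autos])
    len <- index$lens[[ch_]]
    repeat {
      p <- sample(2:(len - 1), 1)
      if (!paste(ch_, p) %in% usedPos) break
    }
    usedPos <<- c(usedPos, paste(ch_, p))
    fwd <- .contextAt(index, ch_, p)
    ref <- substr(fwd, 2, 2)
    alt <- sample(setdiff(.BASES, ref), 1)
    list(chrom = ch_, pos = p, ref = ref, alt = alt)
  }
  for (i in seq_len(nrow(ped))) {
    for (cls in artifactClasses()) {
      k <- rpois(1, rates[[cls]])
      if (k == 0) next
      for (j in seq_len(k)) {
        st <- sampleSite()
        ch_ <- .childEvidence(1, md, condition = TRUE)
        row <- data.frame(
          dnm_id = sprintf("%s_%s_%d", ped$child[i], st$chrom, st$pos),
          trio = ped$trio[i], offspring = ped$child[i],
          chrom = st$chrom, pos = st$pos, ref = st$ref, alt = st$alt,
          child_sex = ped$child_sex[i],
          child_dp = ch_$dp, child_ref_ad = ch_$dp - ch_$alt,
          child_alt_ad = ch_$alt, child_adf = ch_$adf, child_adr = ch_$adr,
          mother_dp = pmax(rpois(1, md), 4), mother_ref_ad = NA,
          mother_alt_ad = 0L,
          father_dp = pmax(rpois(1, md), 4), father_ref_ad = NA,
          father_alt_ad = 0L,
          pop_af = NA_real_, is_true = FALSE, class = cls,
          true_parent = NA_character_, stringsAsFactors = FALSE)
        if (cls == "inherited_undercalled_in_parent") {
          # a truly inherited allele sampled at the low tail in one parent:
          # two alt reads at solid depth (below that, the posterior gate
          # already classifies the site as inherited)
          who <- sample(c("mother", "father"), 1)
          row[[paste0(who, "_dp")]] <- max(rpois(1, md), 16)
          row[[paste0(who, "_alt_ad")]] <- 2L
        } else if (cls == "strand_biased_error") {
          row$child_adf <- row$child_alt_ad
          row$child_adr <- 0L
        } else if (cls == "low_depth_site") {
          who <- sample(c("mother", "father"), 1)
          row[[paste0(who, "_dp")]] <- sample(1:3, 1)
        } else if (cls == "common_population_variant") {
          af <- round(runif(1, 0.02, 0.30), 4)
          row$pop_af <- af
          popRows[[length(popRows) + 1L]] <- data.frame(
            chrom = st$chrom, pos = st$pos, ref = st$ref, alt = st$alt,
            af = af, stringsAsFactors = FALSE)
        } else if (cls == "repeat_region_site") {
          repeatIv[[length(repeatIv) + 1L]] <- data.frame(
            chrom = st$chrom, start = max(st$pos - 1 - 25, 0),
            end = st$pos + 25, stringsAsFactors = FALSE)
        } else if (cls == "mosaic_parent_signal") {
          who <- sample(c("mother", "father"), 1)
          row[[paste0(who, "_dp")]] <- sample(5:9, 1)
          row[[paste0(who, "_alt_ad")]] <- 1L
        } else if (cls == "allele_biased_site") {
          f <- runif(1, 0.75, 0.85)
          altN <- max(round(f * row$child_dp), floor(0.70 * row$child_dp) + 1)
          altN <- min(altN, row$child_dp)
          row$child_alt_ad <- altN
          row$child_ref_ad <- row$child_dp - altN
          row$child_adf <- rbinom(1, altN - 2, 0.5) + 1L
          row$child_adr <- altN - row$child_adf
        }
        row$mother_ref_ad <- row$mother_dp - row$mother_alt_ad
        row$father_ref_ad <- row$father_dp - row$father_alt_ad
        row$mother_adf <- rbinom(1, row$mother_alt_ad, 0.5)
        row$mother_adr <- row$mother_alt_ad - row$mother_adf
        row$father_adf <- rbinom(1, row$father_alt_ad, 0.5)
        row$father_adr <- row$father_alt_ad - row$father_adf
        evid[[length(evid) + 1L]] <- row
      }
    }
  }

  evidence <- if (length(evid)) do.call(rbind, evid) else
    .emptyEvidence()
  rownames(evidence) <- NULL

  # ---- masks and population AF table (decoys plus artifact entries) -------
  decoy <- function(k, width) {
    ch_ <- sample(autos, k, replace = TRUE)
    st <- vapply(ch_, function(cc)
      sample.int(index$lens[[cc]] - width - 2, 1), numeric(1))
    df <- data.frame(chrom = ch_, start = st, end = st + width,
                     stringsAsFactors = FALSE)
    # decoys must not swallow candidate sites
    keep <- !vapply(seq_len(k), function(r) {
      any(evidence$chrom == df$chrom[r] & evidence$pos - 1 >= df$start[r] &
            evidence$pos - 1 < df$end[r])
    }, logical(1))
    df[keep, , drop = FALSE]
  }
  repDf <- rbind(do.call(rbind, repeatIv), decoy(20, 200))
  segDf <- decoy(20, 500)
  toGr <- function(df) {
    if (is.null(df) || nrow(df) == 0)
      return(GRanges())
    GRanges(df$chrom, IRanges(start = df$start + 1, end = df$end))
  }
  popDf <- do.call(rbind, popRows)
  decoyAf <- decoy(50, 1)
  if (nrow(decoyAf) > 0) {
    daf <- data.frame(chrom = decoyAf$chrom, pos = decoyAf$start + 1,
                      ref = "N", alt = "N",
                      af = round(runif(nrow(decoyAf), 0, 0.3), 4),
                      stringsAsFactors = FALSE)
    daf$ref <- substr(.contextAtMulti(index, daf$chrom, daf$pos), 2, 2)
    daf$alt <- vapply(daf$ref, function(b)
      sample(setdiff(.BASES, b), 1), character(1))
    popDf <- rbind(popDf, daf)
  }
  if (is.null(popDf))
    popDf <- data.frame(chrom = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        af = numeric(0), stringsAsFactors = FALSE)

  list(evidence = evidence,
       readObs = if (length(reads)) do.call(rbind, reads) else
         data.frame(dnm_id = character(0), read_id = character(0),
                    dnm_allele = character(0), info_pos = integer(0),
                    info_allele = character(0), stringsAsFactors = FALSE),
       infoSites = if (length(infos)) do.call(rbind, infos) else
         data.frame(trio = character(0), chrom = character(0),
                    pos = integer(0), mother_gt = character(0),
                    father_gt = character(0), child_gt = character(0),
                    stringsAsFactors = FALSE),
       repeatMask = toGr(repDf), segdupMask = toGr(segDf), popAf = popDf)
}

.emptyEvidence <- function() {
  data.frame(dnm_id = character(0), trio = character(0),
             offspring = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             child_sex = character(0), child_dp = integer(0),
             child_ref_ad = integer(0), child_alt_ad = integer(0),
             child_adf = integer(0), child_adr = integer(0),
             mother_dp = integer(0), mother_ref_ad = integer(0),
             mother_alt_ad = integer(0), father_dp = integer(0),
             father_ref_ad = integer(0), father_alt_ad = integer(0),
             pop_af = numeric(0), is_true = logical(0),
             class = character(0), true_parent = character(0),
             mother_adf = integer(0), mother_adr = integer(0),
             father_adf = integer(0), father_adr = integer(0),
             stringsAsFactors = FALSE)
}

#' Simulate a complete trio cohort
#'
#' Convenience driver tying the generator together: builds the reference,
#' the pedigree, the truth set and the site-level evidence in one call with
#' a single seed.
#'
#' @param pedigreeConfig a [PedigreeConfig-class].
#' @param processConfig a [MutationProcessConfig-class].
#' @param evidenceConfig an [EvidenceConfig-class].
#' @param seed integer seed driving every stage.
#' @param reference optional pre-built reference (\code{DNAStringSet});
#'   generated from \code{evidenceConfig} when missing.
#' @return a [TrioCohort-class].
#' @export
simulateTrioCohort <- function(pedigreeConfig = PedigreeConfig(),
                               processConfig = MutationProcessConfig(),
                               evidenceConfig = EvidenceConfig(),
                               seed = 1, reference = NULL) {
  if (is.null(reference))
    reference <- simulateReference(evidenceConfig@referenceLength,
                                   xFraction = evidenceConfig@xFraction,
                                   seed = .substream(seed, 11))
  index <- .contextIndex(reference)
  ped <- buildPedigree(pedigreeConfig, seed = .substream(seed, 12),
                       nominalCallableBases =
                         evidenceConfig@nominalCallableBases)
  truth <- simulateTruthDnms(ped, processConfig, index,
                             seed = .substream(seed, 13))
  sim <- simulateSiteEvidence(truth, evidenceConfig, index,
                              seed = .substream(seed, 14))
  new("TrioCohort", evidence = sim$evidence, truth = truth,
      readObs = sim$readObs, infoSites = sim$infoSites,
      repeatMask = sim$repeatMask, segdupMask = sim$segdupMask,
      popAf = sim$popAf, pedigree = ped, reference = reference,
      contextFreqs = buildContextModel(reference))
}

#' Simulate a per-sample depth track
#'
#' BedGraph-style constant-depth bins with Poisson depth around the mean.
#'
#' @param length track length in bases.
#' @param binSize bin width.
#' @param meanDepth mean coverage.
#' @param seed integer seed.
#' @param chrom chromosome label.
#' @return data.frame with columns chrom, start (0-based), end, depth.
#' @export
simulateDepthTrack <- function(length = 1e6, binSize = 1000,
                               meanDepth = 23.6, seed = 1, chrom = "chr1") {
  set.seed(seed)
  starts <- seq(0, length - 1, by = binSize)
  ends <- pmin(starts + binSize, length)
  data.frame(chrom = chrom, start = starts, end = ends,
             depth = rpois(length(starts), meanDepth),
             stringsAsFactors = FALSE)
}
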