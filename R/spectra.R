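# Mutation spectra over the 96 trinucleotide channels and per-context
# enrichment tests.

#' Build a 96-channel spectrum from a set of single-base mutations
#'
#' Looks up the trinucleotide context of every mutation in the reference,
#' collapses purine-centred mutations onto their reverse complement and
#' tallies the 96 channels. Errors if any stated reference base disagrees
#' with the reference sequence.
#'
#' @param dnms data.frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt}.
#' @param reference a \code{DNAStringSet}, \code{DNAString} or named
#'   character vector of chromosome sequences.
#' @return a [Spectrum96-class]; its total equals \code{nrow(dnms)}.
#' @export
buildSpectrum <- function(dnms, reference) {
  ch <- sbsChannels()
  if (nrow(dnms) == 0)
    return(new("Spectrum96", counts = setNames(numeric(96), ch)))
  idx <- if (is.list(reference) && !is.null(reference$code2ctx32))
    reference else .contextIndex(reference)
  bad <- !dnms$chrom %in% names(idx$seqs)
  if (any(bad))
    stop("unknown chromosome(s): ", paste(unique(dnms$chrom[bad]),
                                          collapse = ", "))
  ctx <- .contextAtMulti(idx, dnms$chrom, dnms$pos)
  refBase <- substr(ctx, 2, 2)
  mismatch <- is.na(ctx) | refBase != toupper(dnms$ref)
  if (any(mismatch))
    stop("reference mismatch at: ",
         paste(paste0(dnms$chrom[mismatch], ":", dnms$pos[mismatch]),
               collapse = ", "))
  lab <- channelOf(ctx, dnms$ref, dnms$alt)
  counts <- setNames(as.numeric(table(factor(lab, levels = ch))), ch)
  new("Spectrum96", counts = counts)
}

#' @describeIn buildSpectrum accessor for the channel counts.
#' @param x a \code{Spectrum96}.
#' @export
spectrumCounts <- function(x) {
  stopifnot(is(x, "Spectrum96"))
  x@counts
}

#' Channel subsets of a spectrum
#'
#' \code{cpgCtChannels}/\code{cpaCtChannels} return the four C>T channels
#' with a 3' G (CpG) or 3' A (CpA). \code{substitutionClassCounts} collapses
#' a spectrum to the six substitution classes.
#'
#' @return character vector of channel labels, or a named numeric of class
#'   totals.
#' @export
cpgCtChannels <- function() {
  ch <- sbsChannels()
  ch[.channelSub(ch) == "C>T" & substr(ch, 7, 7) == "G"]
}

#' @rdname cpgCtChannels
#' @export
cpaCtChannels <- function() {
  ch <- sbsChannels()
  ch[.channelSub(ch) == "C>T" & substr(ch, 7, 7) == "A"]
}

#' @rdname cpgCtChannels
#' @param spectrum a [Spectrum96-class].
#' @export
substitutionClassCounts <- function(spectrum) {
  counts <- spectrumCounts(spectrum)
  sub <- .channelSub(names(counts))
  tapply(counts, factor(sub, levels = c("C>A", "C>G", "C>T",
                                        "T>A", "T>C", "T>G")), sum)
}

#' Mutation-class label of single mutations
#'
#' Maps each mutation to the class vocabulary used by the burden models:
#' the six substitution classes in purine-free notation (\code{"A>C"} for
#' T>G etc.), plus derived subsets \code{"CpG C>T"}, \code{"CpG C>A"} and
#' \code{"non-CpG C>T"} available through [countsByClass()].
#'
#' @param channel 96-channel labels (as from [channelOf()]).
#' @return character vector of base substitution classes.
#' @export
mutationClassOf <- function(channel) {
  sub <- .channelSub(channel)
  map <- c("C>A" = "C>A", "C>G" = "C>G", "C>T" = "C>T",
           "T>A" = "A>T", "T>C" = "A>G", "T>G" = "A>C")
  unname(map[sub])
}

#' Per-offspring mutation counts by class
#'
#' Builds the counts table consumed by [fitBurdenModel()]: one row per
#' offspring and class, covering the total, the six substitution classes,
#' and the CpG / CpA / non-CpG C>T subsets.
#'
#' @param dnms data.frame with columns \code{offspring} and \code{channel}
#'   (96-channel label per mutation).
#' @param offspring optional vector of offspring ids to include (zero rows
#'   are kept for offspring without mutations).
#' @return data.frame with columns \code{sample}, \code{class},
#'   \code{count}.
#' @export
countsByClass <- function(dnms, offspring = NULL) {
  if (is.null(offspring)) offspring <- unique(dnms$offspring)
  ch <- dnms$channel
  base <- mutationClassOf(ch)
  three <- substr(ch, 7, 7)
  cls <- list(
    total = rep(TRUE, length(ch)),
    `A>C` = base == "A>C", `A>T` = base == "A>T", `A>G` = base == "A>G",
    `C>A` = base == "C>A", `C>G` = base == "C>G", `C>T` = base == "C>T",
    `CpG C>T` = base == "C>T" & three == "G",
    `CpG C>A` = base == "C>A" & three == "G",
    `non-CpG C>T` = base == "C>T" & three != "G",
    `CpA C>T` = base == "C>T" & three == "A")
  out <- do.call(rbind, lapply(names(cls), function(k) {
    tab <- table(factor(dnms$offspring[cls[[k]]], levels = offspring))
    data.frame(sample = offspring, class = k,
               count = as.integer(tab[offspring]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-context enrichment test by Poisson regression
#'
#' For each trinucleotide context, fits a log-linear Poisson model of
#' per-offspring mutation counts on a hypermutator-vs-control indicator
#' and reports the rate ratio with its Wald p-value. When per-offspring
#' covariates are supplied, additionally fits the CpA C>T model with MBD4
#' genotype (-/- and +/-) and parental ages as covariates.
#'
#' @param counts long data.frame with columns \code{offspring},
#'   \code{group} (\code{"hypermutator"} or \code{"control"}),
#'   \code{context} (trinucleotide) and \code{count}.
#' @param offsets optional named vector of per-offspring exposure offsets
#'   (e.g. callable bases); entered as \code{log(offset)}.
#' @param covariates optional data.frame with columns \code{offspring},
#'   \code{mbd4_genotype} (\code{"+/+"}, \code{"+/-"}, \code{"-/-"}),
#'   \code{paternal_age}, \code{maternal_age}; triggers the CpA model.
#' @param padjust multiple-testing adjustment across contexts
#'   (default Bonferroni).
#' @return an [EnrichmentResult-class]. Contexts with zero counts in both
#'   groups get an undefined rate ratio and a \code{degenerate} flag; a
#'   zero count in exactly one group raises a \code{finite-sample} flag.
#' @export
contextEnrichmentTest <- function(counts, offsets = NULL, covariates = NULL,
                                  padjust = "bonferroni") {
  stopifnot(all(c("offspring", "group", "context", "count") %in%
                  names(counts)))
  counts$group <- factor(counts$group, levels = c("control", "hypermutator"))
  ctxs <- unique(counts$context)
  rows <- lapply(ctxs, function(cx) {
    d <- counts[counts$context == cx, ]
    byG <- tapply(d$count, d$group, sum)
    if (all(byG == 0, na.rm = TRUE))
      return(data.frame(context = cx, rate_ratio = NA_real_,
                        coefficient = NA_real_, p_value = NA_real_,
                        flag = "degenerate", stringsAsFactors = FALSE))
    off <- if (is.null(offsets)) NULL else log(offsets[d$offspring])
    fit <- glm(count ~ group, family = poisson(), data = d, offset = off)
    co <- summary(fit)$coefficients
    flag <- if (any(byG == 0, na.rm = TRUE)) "finite-sample" else ""
    data.frame(context = cx,
               rate_ratio = exp(co["grouphypermutator", "Estimate"]),
               coefficient = co["grouphypermutator", "Estimate"],
               p_value = co["grouphypermutator", "Pr(>|z|)"],
               flag = flag, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- p.adjust(tab$p_value, method = padjust)
  cpa <- NULL
  if (!is.null(covariates)) {
    cpaCtx <- c("ACA", "CCA", "GCA", "TCA")
    d <- counts[counts$context %in% cpaCtx, ]
    agg <- tapply(d$count, d$offspring, sum)
    cv <- covariates[match(names(agg), covariates$offspring), ]
    cv$cpa <- as.integer(agg)
    cv$mbd4_hom <- as.integer(cv$mbd4_genotype == "-/-")
    cv$mbd4_het <- as.integer(cv$mbd4_genotype == "+/-")
    fit <- glm(cpa ~ mbd4_hom + mbd4_het + paternal_age + maternal_age,
               family = poisson(), data = cv)
    cpa <- summary(fit)$coefficients
  }
  new("EnrichmentResult", table = tab, cpaModel = cpa)
}

#' @describeIn contextEnrichmentTest accessor for the per-context table.
#' @param x an \code{EnrichmentResult}.
#' @export
enrichmentTable <- function(x) {
  stopifnot(is(x, "EnrichmentResult"))
  x@table
}
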