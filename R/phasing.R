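# Read-backed parent-of-origin phasing of filtered DNMs.

#' Classify a heterozygous site as informative for transmission
#'
#' A site is informative when the parental origin of each child allele is
#' uniquely determined by the trio genotypes: the child is heterozygous and
#' exactly one assignment of its two alleles to the parents is Mendelian-
#' consistent. Mendelian-inconsistent trios are uninformative (with a
#' warning rather than an error: they are expected at low rate in noisy
#' data).
#'
#' @param motherGt,fatherGt,childGt diploid genotypes as \code{"a/b"}
#'   strings over allele codes (e.g. \code{"0/1"}).
#' @return named character vector mapping each child allele to
#'   \code{"maternal"} / \code{"paternal"}, or \code{NULL} when
#'   uninformative.
#' @examples
#' classifyInformativeSite("0/1", "0/0", "0/1")  # c(`1`="maternal", `0`="paternal")
#' classifyInformativeSite("0/1", "0/1", "0/1")  # NULL
#' @export
classifyInformativeSite <- function(motherGt, fatherGt, childGt) {
  gt <- function(g) strsplit(g, "[/|]")[[1]]
  mo <- gt(motherGt); fa <- gt(fatherGt); ch <- gt(childGt)
  if (length(ch) != 2 || length(mo) != 2 || length(fa) != 2)
    stop("genotypes must be diploid")
  opt1 <- ch[1] %in% mo && ch[2] %in% fa      # allele1 maternal
  opt2 <- ch[2] %in% mo && ch[1] %in% fa      # allele2 maternal
  if (!opt1 && !opt2) {
    warning("Mendelian-inconsistent trio genotypes; site uninformative")
    return(NULL)
  }
  if (ch[1] == ch[2]) return(NULL)            # homozygous child: no phase
  if (opt1 && opt2) return(NULL)              # ambiguous
  if (opt1) c(setNames("maternal", ch[1]), setNames("paternal", ch[2]))
  else      c(setNames("maternal", ch[2]), setNames("paternal", ch[1]))
}

#' Phase a single DNM from its read observations
#'
#' Every read carrying the DNM alternate allele votes for the parent
#' implied by the allele it carries at its linked informative site.
#' Unanimous votes give the assignment; any conflict, or the absence of
#' votes, yields \code{"unphased"}.
#'
#' @param dnmId DNM identifier.
#' @param readObs data.frame of read observations for this DNM
#'   (columns \code{dnm_allele}, \code{info_pos}, \code{info_allele}).
#' @param infoMaps named list: per informative-site position (character),
#'   the allele-to-parent map from [classifyInformativeSite()].
#' @return one-row data.frame: dnm_id, assignment, supporting, conflicting.
#' @export
phaseCandidate <- function(dnmId, readObs, infoMaps) {
  votes <- character(0)
  if (nrow(readObs) > 0) {
    altReads <- readObs[readObs$dnm_allele == "alt", , drop = FALSE]
    for (i in seq_len(nrow(altReads))) {
      m <- infoMaps[[as.character(altReads$info_pos[i])]]
      if (is.null(m)) next
      al <- as.character(altReads$info_allele[i])
      if (al %in% names(m)) votes <- c(votes, m[[al]])
    }
  }
  tab <- table(votes)
  if (length(tab) == 1 && sum(tab) >= 1) {
    data.frame(dnm_id = dnmId, assignment = names(tab),
               supporting = as.integer(tab), conflicting = 0L,
               stringsAsFactors = FALSE)
  } else {
    data.frame(dnm_id = dnmId, assignment = "unphased",
               supporting = if (length(tab)) max(tab) else 0L,
               conflicting = if (length(tab)) as.integer(sum(tab) - max(tab))
               else 0L, stringsAsFactors = FALSE)
  }
}

#' Phase a set of DNMs against trio informative sites
#'
#' @param dnms data.frame of filtered DNMs with columns \code{dnm_id} and
#'   \code{trio}.
#' @param readObs read observations (dnm_id, read_id, dnm_allele,
#'   info_pos, info_allele).
#' @param infoSites informative-site table (trio, pos, mother_gt,
#'   father_gt, child_gt).
#' @return data.frame of [phaseCandidate()] rows, one per DNM.
#' @export
phaseDnms <- function(dnms, readObs, infoSites) {
  out <- vector("list", nrow(dnms))
  mapsByTrio <- list()
  for (tr in unique(dnms$trio)) {
    si <- infoSites[infoSites$trio == tr, , drop = FALSE]
    maps <- list()
    for (i in seq_len(nrow(si))) {
      m <- withCallingHandlers(
        classifyInformativeSite(si$mother_gt[i], si$father_gt[i],
                                si$child_gt[i]),
        warning = function(w) invokeRestart("muffleWarning"))
      if (!is.null(m)) maps[[as.character(si$pos[i])]] <- m
    }
    mapsByTrio[[tr]] <- maps
  }
  obsByDnm <- split(readObs, readObs$dnm_id)
  for (i in seq_len(nrow(dnms))) {
    ro <- obsByDnm[[dnms$dnm_id[i]]]
    if (is.null(ro)) ro <- readObs[0, , drop = FALSE]
    out[[i]] <- phaseCandidate(dnms$dnm_id[i], ro,
                               mapsByTrio[[dnms$trio[i]]])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(dnm_id = character(0), assignment = character(0),
                      supporting = integer(0), conflicting = integer(0),
                      stringsAsFactors = FALSE)
  res
}

#' Summarise phasing results
#'
#' @param phasedCalls data.frame from [phaseDnms()] (or any frame with an
#'   \code{assignment} column).
#' @return a [PhasingSummary-class] with counts, the phaseable fraction
#'   and alpha (paternal:maternal; \code{NA} when no maternal calls).
#' @examples
#' calls <- data.frame(assignment = rep(c("paternal", "maternal"), c(74, 26)))
#' alphaValue(summarizePhasing(calls))  # 2.846
#' @export
summarizePhasing <- function(phasedCalls) {
  if (nrow(phasedCalls) < 1) stop("at least one call required")
  a <- phasedCalls$assignment
  nm <- sum(a == "maternal")
  np <- sum(a == "paternal")
  nu <- sum(a == "unphased")
  new("PhasingSummary", nMaternal = as.integer(nm),
      nPaternal = as.integer(np), nUnphased = as.integer(nu),
      phaseableFraction = (nm + np) / nrow(phasedCalls),
      alpha = if (nm > 0) np / nm else NA_real_)
}

#' @describeIn summarizePhasing accessor for alpha (paternal:maternal).
#' @param x a \code{PhasingSummary}.
#' @export
alphaValue <- function(x) {
  stopifnot(is(x, "PhasingSummary"))
  x@alpha
}

#' @describeIn summarizePhasing accessor for the assignment counts.
#' @export
phasedCounts <- function(x) {
  stopifnot(is(x, "PhasingSummary"))
  c(maternal = x@nMaternal, paternal = x@nPaternal,
    unphased = x@nUnphased)
}
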