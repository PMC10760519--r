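# Signature catalogs: a packaged synthetic two-signature catalog,
# cross-genome renormalisation, and nonnegative exposure refitting.

# context of a channel label: "A[C>T]G" -> "ACG"
.channelContext <- function(channel) {
  paste0(substr(channel, 1, 1), substr(channel, 3, 3),
         substr(channel, 7, 7))
}

# substitution of a channel label: "A[C>T]G" -> "C>T"
.channelSub <- function(channel) substr(channel, 3, 5)

#' Synthetic two-signature SBS catalog
#'
#' A deterministic stand-in catalog with the qualitative structure of the
#' two germline signatures: \code{SBS1like} concentrates 95 percent of its
#' mass on the four CpG C>T channels (spontaneous methyl-cytosine
#' deamination), the remainder spread evenly; \code{SBS5like} is a
#' flat, clock-like signature with a mild T>C elevation. A real catalog in
#' the same 96-row layout can be supplied by file instead
#' ([readSignatureCatalog()]).
#'
#' @return a [SignatureCatalog-class] with signatures \code{SBS1like} and
#'   \code{SBS5like}.
#' @export
syntheticSignatureCatalog <- function() {
  ch <- sbsChannels()
  cpgCt <- .channelSub(ch) == "C>T" & substr(ch, 7, 7) == "G"
  s1 <- numeric(96)
  s1[cpgCt] <- 0.95 * c(0.30, 0.25, 0.25, 0.20)
  s1[!cpgCt] <- 0.05 / sum(!cpgCt)
  s5 <- rep(1, 96)
  s5[.channelSub(ch) == "T>C"] <- 2
  s5 <- s5 / sum(s5)
  probs <- cbind(SBS1like = s1, SBS5like = s5)
  rownames(probs) <- ch
  new("SignatureCatalog", probs = probs)
}

#' Synthetic human-like source context frequencies
#'
#' Deterministic stand-in for the trinucleotide composition of the genome a
#' catalog was derived on: 40.9 percent GC with the strong CpG depletion
#' characteristic of vertebrate genomes (CpG-containing contexts down-
#' weighted fivefold).
#'
#' @return a [ContextFrequencies-class] object.
#' @export
syntheticSourceFrequencies <- function() {
  ctx <- contexts32()
  gc <- 0.409
  pBase <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  splitb <- strsplit(ctx, "", fixed = TRUE)
  w <- vapply(splitb, function(s) prod(pBase[s]), numeric(1))
  hasCpG <- vapply(splitb, function(s) {
    any(s[-length(s)] == "C" & s[-1] == "G")
  }, logical(1))
  # collapsed contexts also cover reverse-complement occurrences
  hasCpG <- hasCpG | grepl("CG", .revcomp(ctx))
  w[hasCpG] <- w[hasCpG] / 5
  freq <- setNames(w / sum(w), ctx)
  new("ContextFrequencies", freq = freq, skipped = 0)
}

#' @describeIn syntheticSignatureCatalog accessor for the 96 x S probability
#'   matrix.
#' @param x a \code{SignatureCatalog}.
#' @export
signatureProbs <- function(x) {
  stopifnot(is(x, "SignatureCatalog"))
  x@probs
}

#' Read / write a signature catalog TSV
#'
#' The TSV has a \code{channel} column with the 96 labels (any row order)
#' and one numeric column per signature.
#'
#' @param path file path.
#' @return \code{readSignatureCatalog}: a [SignatureCatalog-class].
#' @export
readSignatureCatalog <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"channel" %in% names(df))
    stop("catalog TSV must have a 'channel' column")
  rn <- df$channel
  mat <- as.matrix(df[setdiff(names(df), "channel")])
  rownames(mat) <- rn
  if (!setequal(rn, sbsChannels()))
    stop("catalog must cover exactly the 96 SBS channels")
  mat <- mat[sbsChannels(), , drop = FALSE]
  mat <- sweep(mat, 2, colSums(mat), "/")
  new("SignatureCatalog", probs = mat)
}

#' @rdname readSignatureCatalog
#' @param catalog a [SignatureCatalog-class].
#' @export
writeSignatureCatalog <- function(catalog, path) {
  p <- signatureProbs(catalog)
  df <- data.frame(channel = rownames(p), p, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Renormalise a signature catalog to another genome's base composition
#'
#' Signature probabilities are defined relative to the trinucleotide
#' frequencies of the genome they were extracted from. To apply a catalog
#' to a genome with different composition, each channel weight is
#' multiplied by the ratio of target to source frequency of its context,
#' and each signature column is rescaled to sum 1.
#'
#' @param catalog a [SignatureCatalog-class].
#' @param fSource,fTarget [ContextFrequencies-class] of the catalog's
#'   source genome and of the target genome.
#' @return the renormalised [SignatureCatalog-class].
#' @examples
#' cat0 <- syntheticSignatureCatalog()
#' fs <- syntheticSourceFrequencies()
#' identical(signatureProbs(renormalizeCatalog(cat0, fs, fs)),
#'           signatureProbs(cat0))
#' @export
renormalizeCatalog <- function(catalog, fSource, fTarget) {
  p <- signatureProbs(catalog)
  fs <- contextFreq(fSource)
  ft <- contextFreq(fTarget)
  ctx <- .channelContext(rownames(p))
  if (any(fs[ctx] == 0 & rowSums(p) > 0))
    stop("zero source frequency for a context with nonzero catalog weight")
  ratio <- ft[ctx] / fs[ctx]
  out <- p * ratio
  out <- sweep(out, 2, colSums(out), "/")
  new("SignatureCatalog", probs = out)
}

#' Refit signature exposures by nonnegative least squares
#'
#' Attribution of an observed 96-channel spectrum to a fixed set of
#' signatures: solves \code{min || C e - s ||} subject to \code{e >= 0}
#' where \code{C} holds the selected catalog columns and \code{s} the
#' spectrum counts. This constrained refit replaces de novo signature
#' extraction, which is not reproducible at small cohort sizes.
#'
#' @param spectrum a [Spectrum96-class].
#' @param catalog a [SignatureCatalog-class] (renormalised to the genome the
#'   spectrum was observed on).
#' @param signatures signature labels to fit; defaults to all columns.
#' @return an [ExposureEstimate-class].
#' @export
fitExposures <- function(spectrum, catalog, signatures = NULL) {
  s <- spectrumCounts(spectrum)
  if (sum(s) == 0)
    stop("spectrum has no mutations; cannot fit exposures")
  p <- signatureProbs(catalog)
  if (is.null(signatures)) signatures <- colnames(p)
  if (length(signatures) == 0)
    stop("signature subset must be nonempty")
  missing <- setdiff(signatures, colnames(p))
  if (length(missing) > 0)
    stop("unknown signature(s): ", paste(missing, collapse = ", "))
  A <- p[, signatures, drop = FALSE]
  fit <- pracma::lsqnonneg(A, as.numeric(s))
  expo <- setNames(pmax(fit$x, 0), signatures)
  frac <- if (sum(expo) > 0) expo / sum(expo) else expo
  new("ExposureEstimate", exposures = expo, fractions = frac,
      residualNorm = sqrt(sum((A %*% expo - s)^2)))
}

#' @describeIn fitExposures accessor for the exposure fractions.
#' @param x an \code{ExposureEstimate}.
#' @export
exposureFractions <- function(x) {
  stopifnot(is(x, "ExposureEstimate"))
  x@fractions
}

#' @describeIn fitExposures accessor for the absolute exposures.
#' @export
exposures <- function(x) {
  stopifnot(is(x, "ExposureEstimate"))
  x@exposures
}
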