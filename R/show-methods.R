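# show() methods for the user-facing classes.

setMethod("show", "ContextFrequencies", function(object) {
  cat("ContextFrequencies over 32 pyrimidine-centred contexts\n")
  top <- sort(object@freq, decreasing = TRUE)[1:5]
  cat("  top contexts:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = " "), "\n")
  if (object@skipped > 0)
    cat("  skipped windows:", object@skipped, "\n")
})

setMethod("show", "SignatureCatalog", function(object) {
  cat("SignatureCatalog:", ncol(object@probs), "signature(s):",
      paste(colnames(object@probs), collapse = ", "), "\n")
})

setMethod("show", "Spectrum96", function(object) {
  tot <- sum(object@counts)
  cat("Spectrum96 with", tot, "mutations\n")
  if (tot > 0) {
    cls <- substitutionClassCounts(new("Spectrum96",
                                       counts = object@counts))
    cat("  ", paste(sprintf("%s:%d", names(cls), as.integer(cls)),
                    collapse = "  "), "\n", sep = "")
  }
})

setMethod("show", "ExposureEstimate", function(object) {
  cat("ExposureEstimate\n")
  for (s in names(object@exposures))
    cat(sprintf("  %s: %.1f (%.1f%%)\n", s, object@exposures[s],
                100 * object@fractions[s]))
  cat(sprintf("  residual norm: %.2f\n", object@residualNorm))
})

setMethod("show", "FilterTrace", function(object) {
  cat("FilterTrace:", object@inputCount, "candidates ->",
      object@survivingCount, "survivors\n")
  rem <- setNames(object@removed, object@stages)
  for (s in object@stages)
    cat(sprintf("  %-13s -%d\n", s, rem[[s]]))
})

setMethod("show", "DNMCallset", function(object) {
  cat("DNMCallset:", nrow(object@survivors), "of",
      nrow(object@candidates), "candidates pass all filters\n")
})

setMethod("show", "PhasingSummary", function(object) {
  cat(sprintf(
    "PhasingSummary: %d paternal, %d maternal, %d unphased (%.1f%% phased)\n",
    object@nPaternal, object@nMaternal, object@nUnphased,
    100 * object@phaseableFraction))
  cat("  alpha (paternal:maternal):",
      if (is.na(object@alpha)) "undefined (no maternal calls)" else
        sprintf("%.2f", object@alpha), "\n")
})

setMethod("show", "RateEstimate", function(object) {
  cat(sprintf(
    "RateEstimate: %.3g per bp per generation (%s denominator, %d trios)\n",
    object@rate, object@denominator, length(object@perTrio)))
})

setMethod("show", "BurdenFit", function(object) {
  cat("BurdenFit [", object@model, "], n =", object@nobs, "\n")
  print(round(object@coefficients, 4))
})

setMethod("show", "CallableSummary", function(object) {
  cat("CallableSummary over", object@total, "bases\n")
  for (k in names(object@counts))
    cat(sprintf("  %-13s %g\n", k, object@counts[[k]]))
})

setMethod("show", "TruthSet", function(object) {
  cat("TruthSet:", nrow(object@dnms), "simulated DNMs in",
      nrow(object@pedigree), "trio(s)\n")
})

setMethod("show", "TrioCohort", function(object) {
  cat("TrioCohort:", nrow(object@pedigree), "trio(s),",
      nrow(object@evidence), "candidate site(s),",
      nrow(object@truth@dnms), "true DNM(s)\n")
})

setMethod("show", "ScreenResult", function(object) {
  cat("ScreenResult [", object@mode, "]:", nrow(object@retained),
      "candidate(s) retained\n")
})
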