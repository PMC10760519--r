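# Callable-genome summaries, mutation rate estimation and Poisson burden
# regression.

#' Quantise a depth track into coverage categories
#'
#' Bins depths into NO_COVERAGE [0,1), LOW_COVERAGE [1,4), CALLABLE [4,80)
#' and HIGH_COVERAGE [80, Inf) - the half-open bins of the quantize string
#' \code{0:1:4:80:}.
#'
#' @param depths nonnegative integer depths: either a plain vector (one
#'   entry per base) or a BedGraph-style data.frame with columns
#'   \code{start}, \code{end}, \code{depth} (each bin weighted by its
#'   width).
#' @return a [CallableSummary-class].
#' @examples
#' callableCounts(quantizeCallable(c(0, 2, 10, 100)))  # one base each
#' @export
quantizeCallable <- function(depths) {
  if (is.data.frame(depths)) {
    w <- depths$end - depths$start
    d <- depths$depth
  } else {
    w <- rep(1, length(depths))
    d <- depths
  }
  if (any(d < 0)) stop("negative depth in track")
  cat <- cut(d, breaks = c(-Inf, 1, 4, 80, Inf), right = FALSE,
             labels = c("NO_COVERAGE", "LOW_COVERAGE", "CALLABLE",
                        "HIGH_COVERAGE"))
  counts <- tapply(w, cat, sum, default = 0)
  counts <- setNames(as.numeric(counts), levels(cat))
  new("CallableSummary", counts = counts, total = sum(w))
}

#' @describeIn quantizeCallable accessor for the category counts.
#' @param x a \code{CallableSummary}.
#' @export
callableCounts <- function(x) {
  stopifnot(is(x, "CallableSummary"))
  x@counts
}

#' Callable-adjusted per-generation mutation rate
#'
#' Per-trio rate = DNM count / callable bases (haploid-denominator
#' convention, under which a 10.5-mutation mean over a 1.32 Gb callable
#' genome gives 0.8e-8 per bp per generation); the cohort rate is the mean
#' of per-trio rates. The pooled alternative (sum of counts over sum of
#' callable bases) is reported alongside.
#'
#' @param counts per-trio filtered DNM counts.
#' @param callable per-trio callable base counts (recycled if length 1).
#' @return a [RateEstimate-class].
#' @examples
#' rateValue(estimateRate(10.5, 1.32e9))  # 7.95e-09
#' @export
estimateRate <- function(counts, callable) {
  callable <- rep_len(callable, length(counts))
  if (any(callable <= 0)) stop("callable sizes must be positive")
  if (any(counts < 0)) stop("counts must be nonnegative")
  perTrio <- counts / callable
  new("RateEstimate", perTrio = perTrio, rate = mean(perTrio),
      pooledRate = sum(counts) / sum(callable),
      denominator = "haploid-callable")
}

#' @describeIn estimateRate accessor for the cohort rate.
#' @param x a \code{RateEstimate}.
#' @export
rateValue <- function(x) {
  stopifnot(is(x, "RateEstimate"))
  x@rate
}

# assemble the model frame shared by the burden fits
.burdenFrame <- function(counts, covariates, model) {
  if (is.data.frame(counts)) {
    sel <- counts[counts$class == model, , drop = FALSE]
    if (nrow(sel) == 0)
      stop("no counts for model class '", model, "'")
    y <- sel$count[match(covariates$sample, sel$sample)]
  } else {
    y <- counts
  }
  if (anyNA(y)) stop("counts missing for some samples")
  if (any(y < 0) || any(y != round(y)))
    stop("counts must be nonnegative integers")
  df <- data.frame(
    count = y,
    paternal_age = covariates$paternal_age,
    maternal_age = covariates$maternal_age,
    mbd4_het = as.integer(covariates$mbd4_genotype == "+/-"),
    mbd4_hom = as.integer(covariates$mbd4_genotype == "-/-"),
    callable = as.numeric(covariates$callable))
  if ("hypermutator" %in% names(covariates))
    df$hypermutator <- as.integer(covariates$hypermutator)
  df
}

.checkIdentifiable <- function(df, terms) {
  for (t in terms) {
    v <- df[[t]]
    if (length(unique(v)) < 2)
      stop("covariate '", t, "' is constant: model not identifiable")
  }
}

.asBurdenFit <- function(fit, model, n) {
  co <- summary(fit)$coefficients
  colnames(co) <- c("estimate", "se", "z", "p")
  new("BurdenFit", model = model, coefficients = co,
      deviance = fit$deviance, nobs = as.integer(n),
      converged = fit$converged)
}

#' Poisson regression of mutation burden
#'
#' Fits \code{count ~ paternal_age + maternal_age + mbd4_het + mbd4_hom +
#' callable} by Poisson GLM with log link (iteratively reweighted least
#' squares). Callable bases enter as a covariate, not an offset. The count
#' response is the total burden or one of the labelled mutation classes.
#'
#' @param counts either a counts table from [countsByClass()] (columns
#'   sample, class, count) or a plain count vector aligned with the
#'   covariate rows.
#' @param covariates data.frame with columns \code{sample},
#'   \code{paternal_age}, \code{maternal_age}, \code{mbd4_genotype}
#'   (\code{"+/+"}, \code{"+/-"}, \code{"-/-"}), \code{callable}.
#' @param model count response label (default \code{"total"}).
#' @param terms model terms to include; defaults to all five. Constant
#'   terms raise an identifiability error naming the term.
#' @return a [BurdenFit-class].
#' @export
fitBurdenModel <- function(counts, covariates, model = "total",
                           terms = c("paternal_age", "maternal_age",
                                     "mbd4_het", "mbd4_hom", "callable")) {
  df <- .burdenFrame(counts, covariates, model)
  if (nrow(df) <= length(terms) + 1)
    stop("need more observations than model parameters")
  .checkIdentifiable(df, terms)
  fo <- stats::as.formula(paste("count ~", paste(terms, collapse = " + ")))
  fit <- glm(fo, family = poisson(), data = df)
  if (!fit$converged) stop("IRLS did not converge")
  .asBurdenFit(fit, model, nrow(df))
}

#' Burden model with a hypermutator-by-age interaction
#'
#' Adds a \code{hypermutator:maternal_age} interaction to the burden model
#' to test whether excess mutations accumulate with the dam's age.
#'
#' @inheritParams fitBurdenModel
#' @param covariates as in [fitBurdenModel()], plus a logical
#'   \code{hypermutator} column; both groups must be present.
#' @return a [BurdenFit-class] including the interaction coefficient.
#' @export
fitInteractionModel <- function(counts, covariates, model = "total") {
  df <- .burdenFrame(counts, covariates, model)
  if (!"hypermutator" %in% names(df))
    stop("covariates must include a hypermutator column")
  if (length(unique(df$hypermutator)) < 2)
    stop("both hypermutator and control offspring required")
  .checkIdentifiable(df, c("paternal_age", "maternal_age"))
  fit <- glm(count ~ paternal_age + maternal_age + hypermutator +
               hypermutator:maternal_age, family = poisson(), data = df)
  if (!fit$converged) stop("IRLS did not converge")
  out <- .asBurdenFit(fit, paste0(model, "+interaction"), nrow(df))
  rownames(out@coefficients) <- sub("^(maternal_age:hypermutator)$",
                                    "hypermutator:maternal_age",
                                    rownames(out@coefficients))
  out
}

#' @describeIn fitBurdenModel accessor for the coefficient matrix.
#' @param x a \code{BurdenFit}.
#' @export
burdenCoefficients <- function(x) {
  stopifnot(is(x, "BurdenFit"))
  x@coefficients
}
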