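test_that("denovoPosterior matches the 27-configuration enumeration oracle", {
  cases <- list(
    c(30, 15, 30, 0, 30, 0),    # clean de novo
    c(24, 12, 16, 0, 40, 0),    # uneven parental depth
    c(30, 15, 30, 15, 30, 0),   # inherited from the mother
    c(24, 12, 24, 2, 24, 0),    # undercalled parental alt
    c(30, 0, 30, 0, 30, 0),     # hom-ref child
    c(10, 8, 24, 0, 24, 0))     # high-VAF low-depth child
  for (cs in cases) {
    ev <- data.frame(child_dp = cs[1], child_alt_ad = cs[2],
                     mother_dp = cs[3], mother_alt_ad = cs[4],
                     father_dp = cs[5], father_alt_ad = cs[6])
    expect_equal(denovoPosterior(ev),
                 oraclePosterior(cs[1], cs[2], cs[3], cs[4], cs[5], cs[6]),
                 tolerance = 1e-12)
  }
})

test_that("posterior gate semantics hold at both prior scales", {
  clean <- data.frame(child_dp = 30, child_alt_ad = 15, mother_dp = 30,
                      mother_alt_ad = 0, father_dp = 30, father_alt_ad = 0)
  expect_gt(denovoPosterior(clean), 0.99)
  expect_gt(denovoPosterior(clean, mutationPrior = 1e-8), 0.99)
  homRef <- transform(clean, child_alt_ad = 0)
  expect_lt(denovoPosterior(homRef), 0.5)
  inherited <- transform(clean, mother_alt_ad = 15)
  expect_lt(denovoPosterior(inherited), 1e-6)
  expect_error(denovoPosterior(transform(clean, mother_dp = 0)),
               "not callable")
})

test_that("site filters apply the published thresholds in order", {
  th <- FilterThresholds()
  # offspring depth below 4 fails the depth stage
  expect_equal(evaluateSiteFilters(cleanCandidate(dp = 3, alt_ad = 2,
                                                  adf = 1), th), "depth")
  # parent depth out of [4, 80] also fails depth
  expect_equal(evaluateSiteFilters(cleanCandidate(mo_dp = 81), th), "depth")
  # autosomal VAF 0.30 at depth 40 fails the VAF stage
  expect_equal(evaluateSiteFilters(cleanCandidate(alt_ad = 12, adf = 6),
                                   th), "vaf")
  # VAF bounds are inclusive
  expect_true(is.na(evaluateSiteFilters(cleanCandidate(dp = 40,
                                                       alt_ad = 14,
                                                       adf = 7), th)))
  expect_true(is.na(evaluateSiteFilters(cleanCandidate(dp = 40,
                                                       alt_ad = 28,
                                                       adf = 14), th)))
  # male X requires VAF > 0.70; 0.95 passes the VAF stage
  mx <- cleanCandidate(chrom = "chrX", sex = "M", dp = 20, alt_ad = 19,
                       adf = 10)
  expect_true(is.na(evaluateSiteFilters(mx, th)))
  # female X keeps the autosomal band
  fx <- cleanCandidate(chrom = "chrX", sex = "F", dp = 20, alt_ad = 19,
                       adf = 10)
  expect_equal(evaluateSiteFilters(fx, th), "vaf")
  # Y-chromosome calls are excluded
  expect_equal(evaluateSiteFilters(cleanCandidate(chrom = "chrY",
                                                  sex = "M"), th), "vaf")
  # three alt reads all on the forward strand fail the strand stage
  expect_equal(evaluateSiteFilters(cleanCandidate(dp = 8, alt_ad = 3,
                                                  adf = 3), th), "strand")
  # fewer than two alt reads fail the strand stage (VAF bound widened so
  # the strand rule is what fires)
  thWide <- FilterThresholds(vafMin = 0.2)
  expect_equal(evaluateSiteFilters(cleanCandidate(dp = 4, alt_ad = 1,
                                                  adf = 1), thWide),
               "strand")
  # father with two alt reads fails the parental stage
  expect_equal(evaluateSiteFilters(cleanCandidate(fa_alt = 2), th),
               "parental")
  # parent VAF above 10 percent fails parental even with one alt read
  expect_equal(evaluateSiteFilters(cleanCandidate(mo_dp = 8, mo_alt = 1),
                                   th), "parental")
  # clean de novo passes everything
  expect_true(is.na(evaluateSiteFilters(cleanCandidate(), th)))
})

test_that("site filters demand known chromosomes and sex on X", {
  expect_error(evaluateSiteFilters(cleanCandidate(chrom = "weird")),
               "chromosome")
  expect_error(evaluateSiteFilters(cleanCandidate(chrom = "chrX",
                                                  sex = NA)), "sex")
})

test_that("region masks use 0-based half-open semantics", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", bed)
  mask <- readBedMask(bed)
  inMask <- cleanCandidate(pos = 150)
  atEnd <- cleanCandidate(pos = 201)   # first base after the interval
  atStart <- cleanCandidate(pos = 101) # first base inside (0-based 100)
  res <- regionMaskFilter(rbind(inMask, atEnd, atStart), mask, NULL)
  expect_equal(res$stage, c("repeat_mask", NA, "repeat_mask"))
  expect_equal(res$removedRepeat, 2L)
  # empty masks are the identity
  res2 <- regionMaskFilter(rbind(inMask, atEnd), NULL, NULL)
  expect_equal(nrow(res2$survivors), 2L)
  # malformed BED lines error with their line number
  writeLines(c("chr1\t100\t200", "chr1\t500"), bed)
  expect_error(readBedMask(bed), "line 2")
  writeLines(c("chr1\t300\t200"), bed)
  expect_error(readBedMask(bed), "line 1")
})

test_that("population-frequency filter removes strictly above the cutoff", {
  af <- data.frame(chrom = "chr1", pos = c(5000, 6000, 7000), ref = "C",
                   alt = "T", af = c(0.02, 0.01, 0.5))
  cands <- rbind(cleanCandidate(pos = 5000), cleanCandidate(pos = 6000),
                 cleanCandidate(pos = 8000))
  removed <- popfreqFilter(cands, af, 0.01)
  expect_equal(removed, c(TRUE, FALSE, FALSE))  # 0.02 out, 0.01 kept,
                                                # absent treated as novel
  expect_error(popfreqFilter(cands, transform(af, af = c(2, 0, 0)), 0.01),
               "\\[0, 1\\]")
})

test_that("binomial allele-balance test is exact, two-sided, per offspring", {
  # exactly balanced: p = 1, kept
  bal <- cleanCandidate(dp = 40, alt_ad = 20, adf = 10)
  res <- binomialFdrFilter(bal)
  expect_equal(res$p, 1)
  expect_false(res$removed)
  # 5 alt of 40: doubled tail sum = 2 * sum C(40, 0..5) / 2^40
  skew <- cleanCandidate(dp = 40, alt_ad = 5, adf = 2)
  expected <- 2 * sum(choose(40, 0:5)) / 2^40
  res2 <- binomialFdrFilter(skew)
  expect_equal(res2$p, expected, tolerance = 1e-12)
  expect_true(res2$removed)
  # agreement with stats::binom.test across depths
  for (cs in list(c(40, 5), c(23, 8), c(17, 12), c(60, 25))) {
    got <- binomialFdrFilter(cleanCandidate(dp = cs[1], alt_ad = cs[2],
                                            adf = 1))$p
    expect_equal(got, binom.test(cs[2], cs[1], 0.5)$p.value,
                 tolerance = 1e-12)
  }
  # all balanced candidates survive jointly
  many <- do.call(rbind, lapply(1:20, function(i)
    cleanCandidate(pos = 1000 + i, dp = 40, alt_ad = 20, adf = 10)))
  expect_false(any(binomialFdrFilter(many)$removed))
  expect_error(binomialFdrFilter(cleanCandidate(dp = 0, alt_ad = 0)),
               "depth")
})

test_that("cascade bookkeeping is exact and monotone", {
  rates <- setNames(rep(3, 7), artifactClasses())
  co <- smallCohort(seed = 13, nControl = 12, refLen = 1e6, rates = rates)
  cand <- callCandidates(co@evidence)
  cs <- runCascade(cand, FilterThresholds(), co@repeatMask, co@segdupMask,
                   co@popAf)
  tr <- filterTrace(cs)
  expect_equal(tr@inputCount - sum(tr@removed), tr@survivingCount)
  expect_true(all(tr@removed >= 0))
  expect_equal(nrow(survivors(cs)), tr@survivingCount)
  # per-stage surviving counts are nonincreasing by construction
  expect_true(all(diff(tr@inputCount - cumsum(tr@removed)) <= 0))
  # empty input gives an empty trace
  empty <- runCascade(callCandidates(co@evidence[0, ]))
  expect_equal(filterTrace(empty)@inputCount, 0L)
  expect_equal(sum(filterTrace(empty)@removed), 0L)
})

test_that("the final set equals independent predicate intersection", {
  rates <- setNames(rep(3, 7), artifactClasses())
  co <- smallCohort(seed = 13, nControl = 12, refLen = 1e6, rates = rates)
  cand <- callCandidates(co@evidence)
  th <- FilterThresholds()
  cs <- runCascade(cand, th, co@repeatMask, co@segdupMask, co@popAf)
  # oracle: apply every predicate independently and intersect
  okGate <- cand$p_dn > th@pDnMin
  okSite <- is.na(evaluateSiteFilters(cand, th))
  okMask <- is.na(regionMaskFilter(cand, co@repeatMask, co@segdupMask)$stage)
  okPop <- !popfreqFilter(cand, co@popAf, th@popfreqMax)
  pre <- okGate & okSite & okMask & okPop
  okBinom <- rep(TRUE, nrow(cand))
  okBinom[pre] <- !binomialFdrFilter(cand[pre, ], th@fdrAlpha)$removed
  expect_setequal(survivors(cs)$dnm_id, cand$dnm_id[pre & okBinom])
})

test_that("each artifact class is removed at its targeted stage", {
  rates <- setNames(rep(2, 7), artifactClasses())
  co <- smallCohort(seed = 31, nControl = 60, refLen = 2e6, rates = rates)
  cand <- callCandidates(co@evidence)
  cs <- runCascade(cand, FilterThresholds(), co@repeatMask, co@segdupMask,
                   co@popAf)
  cc <- cs@candidates
  for (cls in artifactClasses()) {
    sel <- cc$class == cls
    expect_gt(sum(sel), 20)
    atTarget <- mean(cc$first_fail[sel] == artifactTargets[[cls]],
                     na.rm = FALSE)
    expect_gte(atTarget, 0.95)
  }
})

test_that("cascade sensitivity matches the read-sampling arithmetic", {
  # at 40x, at least 95 percent of true het DNMs survive the cascade
  co40 <- smallCohort(seed = 77, nControl = 60, refLen = 1e6,
                      meanDepth = 40)
  cand <- callCandidates(co40@evidence)
  cs <- runCascade(cand, FilterThresholds(), co40@repeatMask,
                   co40@segdupMask, co40@popAf)
  expect_gte(nrow(survivors(cs)) / nrow(cand), 0.95)

  # at 23.6x, survival equals the closed-form binomial prediction:
  # E over depth ~ Pois(23.6) of P(VAF in [0.35, 0.70], both strands hit)
  co <- smallCohort(seed = 78, nControl = 120, refLen = 1e6)
  cand2 <- callCandidates(co@evidence)
  cs2 <- runCascade(cand2, FilterThresholds(), co@repeatMask,
                    co@segdupMask, co@popAf)
  predicted <- {
    dps <- 4:80; wd <- dpois(dps, 23.6)
    sum(vapply(dps, function(n) {
      a <- 2:n
      ok <- a / n >= 0.35 & a / n <= 0.70
      sum(dbinom(a, n, 0.5) * ok * (1 - 2 * 0.5^a))
    }, numeric(1)) * wd)
  }
  observed <- nrow(survivors(cs2)) / nrow(cand2)
  expect_lt(abs(observed - predicted), 0.03)
})
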