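test_that("buildSpectrum tallies channels against a hand-built fixture", {
  # reference laid out so each mutation's context is known by construction
  ref <- c(chr1 = "AACGTTGCAAACGGA")
  #         123456789012345
  dnms <- data.frame(
    chrom = "chr1",
    pos = c(3, 4, 8, 11, 12),
    ref = c("C", "G", "C", "A", "C"),
    alt = c("T", "A", "A", "G", "T"))
  # hand tally: ACG C>T -> A[C>T]G ; CGT G>A -> A[C>T]G (revcomp) ;
  # GCA C>A -> G[C>A]A ; AAC A>G -> G[T>C]T (revcomp) ; ACG C>T -> A[C>T]G
  sp <- buildSpectrum(dnms, ref)
  counts <- spectrumCounts(sp)
  expect_equal(sum(counts), 5)
  expect_equal(unname(counts["A[C>T]G"]), 3)
  expect_equal(unname(counts["G[C>A]A"]), 1)
  expect_equal(unname(counts["G[T>C]T"]), 1)
  # empty input gives the zero spectrum
  expect_equal(sum(spectrumCounts(buildSpectrum(dnms[0, ], ref))), 0)
  # a single CpG C>T lands in the CpG subset
  one <- buildSpectrum(dnms[1, ], ref)
  expect_equal(sum(spectrumCounts(one)[cpgCtChannels()]), 1)
  # reference mismatch errors with the offending site
  bad <- transform(dnms, ref = c("T", "G", "C", "A", "C"))
  expect_error(buildSpectrum(bad, ref), "chr1:3")
})

test_that("substitution-class collapse is strand symmetric", {
  ref <- c(chr1 = "AACGTTGCAAACGGA")
  dnms <- data.frame(chrom = "chr1", pos = c(3, 4), ref = c("C", "G"),
                     alt = c("T", "A"))
  cls <- substitutionClassCounts(buildSpectrum(dnms, ref))
  expect_equal(unname(cls["C>T"]), 2)
  expect_equal(mutationClassOf(c("A[T>G]A", "A[T>A]C", "T[T>C]G")),
               c("A>C", "A>T", "A>G"))
})

test_that("catalog renormalisation rescales by context-frequency ratios", {
  cat0 <- syntheticSignatureCatalog()
  fs <- syntheticSourceFrequencies()
  # identical source and target frequencies: identity
  expect_equal(signatureProbs(renormalizeCatalog(cat0, fs, fs)),
               signatureProbs(cat0), tolerance = 1e-12)
  # a signature concentrated in one context is unchanged
  p <- matrix(0, 96, 1, dimnames = list(sbsChannels(), "S"))
  p["A[C>T]G", 1] <- 1
  single <- new("SignatureCatalog", probs = p)
  ft <- contextFreq(fs)
  ft <- ft / sum(ft)
  target <- new("ContextFrequencies",
                freq = rev(ft) |> setNames(names(ft)), skipped = 0)
  expect_equal(signatureProbs(renormalizeCatalog(single, fs, target)),
               signatureProbs(single), tolerance = 1e-12)
  # two-context toy: doubling one context's frequency gives 2/3 vs 1/3
  p2 <- matrix(0, 96, 1, dimnames = list(sbsChannels(), "S"))
  p2["A[C>A]A", 1] <- 0.5   # context ACA
  p2["A[C>A]C", 1] <- 0.5   # context ACC
  toy <- new("SignatureCatalog", probs = p2)
  fsrc <- setNames(rep(1 / 32, 32), contexts32())
  ftgt <- fsrc
  ftgt["ACA"] <- 2 / 32
  ftgt <- ftgt / sum(ftgt)
  fS <- new("ContextFrequencies", freq = fsrc, skipped = 0)
  fT <- new("ContextFrequencies", freq = ftgt, skipped = 0)
  out <- signatureProbs(renormalizeCatalog(toy, fS, fT))
  expect_equal(unname(out["A[C>A]A", 1]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(out["A[C>A]C", 1]), 1 / 3, tolerance = 1e-12)
  # renormalisation is invertible to 1e-9
  back <- renormalizeCatalog(renormalizeCatalog(cat0, fS, fT), fT, fS)
  expect_lt(max(abs(signatureProbs(back) - signatureProbs(cat0))), 1e-9)
})

test_that("exposure refitting recovers known mixtures", {
  cat0 <- syntheticSignatureCatalog()
  p <- signatureProbs(cat0)
  # a pure catalog column scaled by 500 is attributed entirely
  sp <- new("Spectrum96", counts = setNames(p[, "SBS1like"] * 500,
                                            sbsChannels()))
  est <- fitExposures(sp, cat0)
  expect_equal(unname(exposureFractions(est)["SBS1like"]), 1,
               tolerance = 1e-9)
  # multinomial draws from a 0.2/0.8 mixture recover the fractions
  set.seed(11)
  mix <- 0.2 * p[, "SBS1like"] + 0.8 * p[, "SBS5like"]
  draw <- as.numeric(rmultinom(1, 1e4, mix))
  est2 <- fitExposures(new("Spectrum96",
                           counts = setNames(draw, sbsChannels())), cat0)
  expect_lt(abs(exposureFractions(est2)["SBS1like"] - 0.2), 0.03)
  expect_true(all(exposures(est2) >= 0))
  # mean absolute recovery error below 0.05 over 20 seeds at 2000 draws
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    w <- runif(1, 0.1, 0.9)
    m <- w * p[, "SBS1like"] + (1 - w) * p[, "SBS5like"]
    d <- as.numeric(rmultinom(1, 2000, m))
    f <- exposureFractions(fitExposures(
      new("Spectrum96", counts = setNames(d, sbsChannels())), cat0))
    abs(f["SBS1like"] - w)
  }, numeric(1))
  expect_lt(mean(errs), 0.05)
  # all-zero spectrum is rejected
  expect_error(fitExposures(new("Spectrum96",
                                counts = setNames(numeric(96),
                                                  sbsChannels())), cat0),
               "no mutations")
})

test_that("NNLS agrees with a constrained grid-search oracle", {
  cat0 <- syntheticSignatureCatalog()
  p <- signatureProbs(cat0)
  set.seed(3)
  y <- as.numeric(rmultinom(1, 3000, 0.35 * p[, 1] + 0.65 * p[, 2]))
  est <- fitExposures(new("Spectrum96", counts = setNames(y, sbsChannels())),
                      cat0)
  # oracle: total exposure t and split w scanned on a fine grid
  obj <- function(w, t) sum((t * (w * p[, 1] + (1 - w) * p[, 2]) - y)^2)
  ws <- seq(0, 1, by = 0.001)
  best <- ws[which.min(vapply(ws, obj, numeric(1), t = sum(y)))]
  expect_lt(abs(exposureFractions(est)["SBS1like"] - best), 0.01)
})

test_that("per-context Poisson enrichment behaves across regimes", {
  mkCounts <- function(h, c_, ctx = "ACA") {
    rbind(data.frame(offspring = paste0("H", seq_along(h)),
                     group = "hypermutator", context = ctx, count = h),
          data.frame(offspring = paste0("C", seq_along(c_)),
                     group = "control", context = ctx, count = c_))
  }
  # identical groups: rate ratio 1, p near 1
  eq <- contextEnrichmentTest(mkCounts(rep(3, 20), rep(3, 20)))
  tab <- enrichmentTable(eq)
  expect_equal(tab$rate_ratio, 1, tolerance = 1e-8)
  expect_gt(tab$p_value, 0.9)
  # simulated fivefold enrichment at n = 50 per group: ratio within [4, 6]
  set.seed(21)
  enr <- contextEnrichmentTest(mkCounts(rpois(50, 10), rpois(50, 2)))
  expect_gt(enrichmentTable(enr)$rate_ratio, 4)
  expect_lt(enrichmentTable(enr)$rate_ratio, 6)
  expect_lt(enrichmentTable(enr)$p_value, 1e-6)
  # zero counts in one group raise the finite-sample flag
  z <- contextEnrichmentTest(mkCounts(rep(2, 10), rep(0, 10)))
  expect_equal(enrichmentTable(z)$flag, "finite-sample")
  # zero counts in both groups are degenerate with undefined ratio
  zz <- contextEnrichmentTest(mkCounts(rep(0, 10), rep(0, 10)))
  expect_equal(enrichmentTable(zz)$flag, "degenerate")
  expect_true(is.na(enrichmentTable(zz)$rate_ratio))
})

test_that("CpA C>T model attributes the excess to the MBD4 -/- dam", {
  co <- simulateTrioCohort(
    PedigreeConfig(nControlTrios = 40, nHyperTrios = 10),
    MutationProcessConfig(), EvidenceConfig(referenceLength = 1e6),
    seed = 33)
  tr <- truthDnms(co@truth)
  ped <- co@pedigree
  cpa <- tr$channel %in% cpaCtChannels()
  counts <- do.call(rbind, lapply(ped$child, function(ch_) {
    data.frame(offspring = ch_,
               group = if (ped$hypermutator[ped$child == ch_])
                 "hypermutator" else "control",
               context = "CCA",
               count = sum(cpa & tr$offspring == ch_))
  }))
  covar <- data.frame(offspring = ped$child,
                      mbd4_genotype = ped$mother_mbd4,
                      paternal_age = ped$paternal_age,
                      maternal_age = ped$maternal_age)
  res <- contextEnrichmentTest(counts, covariates = covar)
  cm <- res@cpaModel
  expect_gt(cm["mbd4_hom", "Estimate"], 1)
  expect_lt(cm["mbd4_hom", "Pr(>|z|)"], 1e-6)
})

test_that("C>T is the only substitution class with a hypermutator excess", {
  co <- simulateTrioCohort(
    PedigreeConfig(nControlTrios = 40, nHyperTrios = 15),
    MutationProcessConfig(), EvidenceConfig(referenceLength = 1e6),
    seed = 44)
  tr <- truthDnms(co@truth)
  ped <- co@pedigree
  hyper <- ped$child[ped$hypermutator]
  classes <- c("C>A", "C>G", "C>T", "A>T", "A>G", "A>C")
  pvals <- vapply(classes, function(cl) {
    cnt <- vapply(ped$child, function(ch_)
      sum(tr$offspring == ch_ & mutationClassOf(tr$channel) == cl),
      numeric(1))
    d <- data.frame(count = cnt, hyper = ped$child %in% hyper)
    summary(glm(count ~ hyper, poisson(), d))$coefficients[2, 4]
  }, numeric(1))
  expect_lt(pvals["C>T"], 1e-10)
  expect_true(all(pvals[setdiff(classes, "C>T")] > 0.01))
})
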