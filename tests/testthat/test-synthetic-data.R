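test_that("identical seeds and configs give identical cohorts", {
  co1 <- smallCohort(seed = 5, nControl = 8, refLen = 2e5, fresh = TRUE)
  co2 <- smallCohort(seed = 5, nControl = 8, refLen = 2e5, fresh = TRUE)
  expect_identical(as.character(co1@reference), as.character(co2@reference))
  expect_identical(truthDnms(co1@truth), truthDnms(co2@truth))
  expect_identical(co1@evidence, co2@evidence)
  expect_identical(co1@readObs, co2@readObs)
  co3 <- smallCohort(seed = 6, nControl = 8, refLen = 2e5, fresh = TRUE)
  expect_false(identical(truthDnms(co1@truth), truthDnms(co3@truth)))
})

test_that("per-offspring burden matches the configured mean", {
  ref <- simulateReference(2e5, seed = 3)
  ped <- buildPedigree(PedigreeConfig(nControlTrios = 600), seed = 3)
  truth <- simulateTruthDnms(ped, MutationProcessConfig(), ref, seed = 4)
  counts <- table(factor(truthDnms(truth)$offspring, levels = ped$child))
  m <- mean(counts)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - 10.5), 3 * se + 1e-9)
  # age effects: offspring of older sires carry more mutations
  fit <- coef(lm(as.numeric(counts) ~ ped$paternal_age))
  expect_gt(fit[2], 0.5)
})

test_that("all-zero process means give an empty truth set", {
  ref <- simulateReference(2e5, seed = 3)
  cfg <- MutationProcessConfig(controlBurdenMean = 0,
                               maternalCpgExcessMean = 0,
                               maternalCpaExcessMean = 0,
                               paternalAgeSlope = 0, maternalAgeSlope = 0)
  truth <- simulateTruthDnms(PedigreeConfig(nControlTrios = 5), cfg, ref,
                             seed = 2)
  expect_equal(nrow(truthDnms(truth)), 0L)
})

test_that("hypermutator offspring concentrate CpG C>T counts in 25-39", {
  ref <- simulateReference(5e5, seed = 8)
  ped <- buildPedigree(PedigreeConfig(nControlTrios = 0, nHyperTrios = 60),
                       seed = 8)
  truth <- simulateTruthDnms(ped, MutationProcessConfig(), ref, seed = 9)
  tr <- truthDnms(truth)
  cpg <- tapply(tr$process == "cpg_excess", tr$offspring, sum)
  expect_gte(mean(cpg >= 25 & cpg <= 39), 0.6)
  expect_true(median(cpg) >= 25 && median(cpg) <= 39)
  # excess mutations are maternal and context-faithful
  ex <- tr[tr$process != "baseline", ]
  expect_true(all(ex$parent == "maternal"))
  expect_true(all(ex$channel[ex$process == "cpg_excess"] %in%
                    cpgCtChannels()))
  expect_true(all(ex$channel[ex$process == "cpa_excess"] %in%
                    cpaCtChannels()))
})

test_that("truth contexts agree with the reference sequence", {
  co <- smallCohort(seed = 5, nControl = 8, refLen = 2e5)
  tr <- truthDnms(co@truth)
  seqs <- as.character(co@reference)
  ctx <- substring(seqs[tr$chrom], tr$pos - 1, tr$pos + 1)
  expect_equal(unname(ctx), tr$context)
  expect_equal(substr(tr$context, 2, 2), tr$ref)
})

test_that("artifact-free evidence is clean and balanced", {
  co <- smallCohort(seed = 42, nControl = 40, refLen = 1e6)
  ev <- co@evidence
  # parental alt reads arise from the error rate only
  expect_lt(mean(ev$mother_alt_ad), 0.1)
  expect_lt(mean(ev$father_alt_ad), 0.1)
  # child alt fraction averages 0.5
  expect_lt(abs(mean(ev$child_alt_ad / ev$child_dp) - 0.5), 0.02)
  # read-count bookkeeping invariants
  expect_true(all(ev$child_ref_ad + ev$child_alt_ad == ev$child_dp))
  expect_true(all(ev$child_adf + ev$child_adr == ev$child_alt_ad))
  # truth manifest counts equal evidence counts per offspring
  tr <- truthDnms(co@truth)
  expect_equal(table(ev$offspring[ev$is_true]), table(tr$offspring))
})

test_that("artifact classes violate their targeted evidence pattern", {
  rates <- setNames(rep(3, 7), artifactClasses())
  co <- smallCohort(seed = 13, nControl = 12, refLen = 1e6, rates = rates)
  ev <- co@evidence
  und <- ev[ev$class == "inherited_undercalled_in_parent", ]
  expect_true(all(pmax(und$mother_alt_ad, und$father_alt_ad) >= 2))
  sb <- ev[ev$class == "strand_biased_error", ]
  expect_true(all(sb$child_adr == 0 | sb$child_adf == 0))
  ld <- ev[ev$class == "low_depth_site", ]
  expect_true(all(pmin(ld$mother_dp, ld$father_dp) < 4))
  pv <- ev[ev$class == "common_population_variant", ]
  expect_true(all(pv$pop_af > 0.01))
  expect_true(all(paste(pv$chrom, pv$pos) %in%
                    paste(co@popAf$chrom, co@popAf$pos)))
  ab <- ev[ev$class == "allele_biased_site", ]
  vaf <- ab$child_alt_ad / ab$child_dp
  expect_true(all(vaf > 0.70 | vaf < 0.35))
  # repeat-class sites fall inside the emitted repeat mask
  rp <- ev[ev$class == "repeat_region_site", ]
  gr <- GenomicRanges::GRanges(rp$chrom, IRanges::IRanges(rp$pos, rp$pos))
  expect_true(all(IRanges::overlapsAny(gr, co@repeatMask)))
})

test_that("phaseable fraction sits at the calibrated 45-60 percent", {
  co <- smallCohort(seed = 42, nControl = 40, refLen = 1e6)
  tr <- truthDnms(co@truth)
  ph <- phaseDnms(tr, co@readObs, co@infoSites)
  frac <- mean(ph$assignment != "unphased")
  expect_gte(frac, 0.45)
  expect_lte(frac, 0.60)
})

test_that("male X sites are hemizygous with maternal origin", {
  co <- simulateTrioCohort(
    PedigreeConfig(nControlTrios = 30, offspringSex = "M"),
    MutationProcessConfig(),
    EvidenceConfig(referenceLength = 1e6, xFraction = 0.3), seed = 21)
  ev <- co@evidence
  x <- ev[ev$chrom == "chrX", ]
  expect_gt(nrow(x), 5)
  # hemizygous: essentially every read carries the alt (rare error reads)
  expect_gt(mean(x$child_alt_ad / x$child_dp), 0.97)
  expect_gt(mean(x$child_alt_ad / x$child_dp > 0.9), 0.95)
  expect_true(all(co@truth@dnms$parent[co@truth@dnms$chrom == "chrX"] ==
                    "maternal"))
  # halved coverage on the male X
  expect_lt(mean(x$child_dp), 0.7 * mean(ev$child_dp[ev$chrom != "chrX"]))
})

test_that("invalid evidence configurations are rejected", {
  expect_error(EvidenceConfig(fragmentLength = 0), "fragmentLength")
  expect_error(EvidenceConfig(referenceLength = 1e4), "referenceLength")
  expect_error(EvidenceConfig(meanDepth = 100), "meanDepth")
  expect_error(MutationProcessConfig(controlBurdenMean = -1), "means")
  expect_error(MutationProcessConfig(
    controlSignatureMix = c(SBS1like = 0.5, SBS5like = 0.2)), "sum to 1")
})

test_that("shared-mutation rate duplicates mutations between maternal sibs", {
  ref <- simulateReference(2e5, seed = 3)
  ped <- buildPedigree(PedigreeConfig(nControlTrios = 0, nHyperTrios = 10),
                       seed = 3)
  truth <- simulateTruthDnms(ped, MutationProcessConfig(sharedMutationRate = 2),
                             ref, seed = 5)
  tr <- truthDnms(truth)
  shared <- tr[tr$process == "shared", ]
  expect_gt(nrow(shared), 0)
  # a shared mutation also exists in a sibling at the same position
  key <- paste(tr$chrom, tr$pos)
  expect_true(all(table(key[key %in% paste(shared$chrom, shared$pos)]) >= 2))
})
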