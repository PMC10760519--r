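# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

# one clean heterozygous de novo candidate row
cleanCandidate <- function(chrom = "chr1", pos = 5000, ref = "C", alt = "T",
                           sex = "F", dp = 40, alt_ad = 20, adf = 10,
                           mo_dp = 40, mo_alt = 0, fa_dp = 40, fa_alt = 0,
                           pop_af = NA_real_, offspring = "CH1") {
  data.frame(
    dnm_id = paste0(offspring, "_", chrom, "_", pos), trio = "T1",
    offspring = offspring, chrom = chrom, pos = pos, ref = ref, alt = alt,
    child_sex = sex, child_dp = dp, child_ref_ad = dp - alt_ad,
    child_alt_ad = alt_ad, child_adf = adf, child_adr = alt_ad - adf,
    mother_dp = mo_dp, mother_ref_ad = mo_dp - mo_alt,
    mother_alt_ad = mo_alt, mother_adf = 0L, mother_adr = mo_alt,
    father_dp = fa_dp, father_ref_ad = fa_dp - fa_alt,
    father_alt_ad = fa_alt, father_adf = 0L, father_adr = fa_alt,
    pop_af = pop_af, is_true = TRUE, class = "baseline",
    true_parent = NA_character_, stringsAsFactors = FALSE)
}

# independent 27-configuration posterior oracle, written out longhand
oraclePosterior <- function(cdp, calt, mdp, malt, fdp, falt,
                            e = 0.005, mu = 1e-2, theta = 1e-3) {
  gts <- list(RR = 0, RA = 1, AA = 2)
  pErr <- c(RR = e, RA = 0.5, AA = 1 - e)
  prior <- c(RR = (1 - theta)^2, RA = 2 * theta * (1 - theta),
             AA = theta^2)
  trans <- function(m, f, c) {
    pm <- gts[[m]] / 2; pf <- gts[[f]] / 2
    p <- switch(c, RR = (1 - pm) * (1 - pf),
                RA = pm * (1 - pf) + (1 - pm) * pf, AA = pm * pf)
    if (p > 0) p else mu
  }
  num <- den <- 0
  for (m in names(gts)) for (f in names(gts)) for (c in names(gts)) {
    w <- prior[[m]] * prior[[f]] * trans(m, f, c) *
      dbinom(malt, mdp, pErr[[m]]) * dbinom(falt, fdp, pErr[[f]]) *
      dbinom(calt, cdp, pErr[[c]])
    dn <- (gts[[c]] > 0 && gts[[m]] == 0 && gts[[f]] == 0) ||
      (gts[[c]] < 2 && gts[[m]] == 2 && gts[[f]] == 2)
    den <- den + w
    if (dn) num <- num + w
  }
  num / den
}

# small shared cohort, built once per test file that sources it
smallCohort <- local({
  cache <- NULL
  function(seed = 42, nControl = 40, nHyper = 0, refLen = 1e6,
           rates = setNames(numeric(7), artifactClasses()),
           meanDepth = 23.6, density = 0.00151, fresh = FALSE) {
    key <- paste(seed, nControl, nHyper, refLen, meanDepth, density,
                 paste(rates, collapse = ","))
    if (!fresh && !is.null(cache) && identical(cache$key, key))
      return(cache$cohort)
    co <- simulateTrioCohort(
      PedigreeConfig(nControlTrios = nControl, nHyperTrios = nHyper),
      MutationProcessConfig(),
      EvidenceConfig(referenceLength = refLen, artifactRates = rates,
                     meanDepth = meanDepth,
                     informativeSiteDensity = density),
      seed = seed)
    cache <<- list(key = key, cohort = co)
    co
  }
})

artifactTargets <- c(
  inherited_undercalled_in_parent = "parental",
  strand_biased_error = "strand",
  low_depth_site = "depth",
  common_population_variant = "popfreq",
  repeat_region_site = "repeat_mask",
  mosaic_parent_signal = "parental",
  allele_biased_site = "vaf")
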