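---
title: "Trio de novo mutation analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio de novo mutation analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrioDNM)
```

TrioDNM detects and characterises germline de novo single-base mutations
(DNMs) from trio sequencing evidence: a child and its two parents, each
with per-site read depths, allele depths and strand counts. The package
was built around the analysis of a rhesus macaque pedigree in which a dam
homozygous for an *MBD4* loss-of-function allele transmitted a large
maternal excess of C>T mutations at CpG and CpA dinucleotides to her
offspring, but every component is generic trio-sequencing methodology:
candidate calling, hard filtering, read-backed parent-of-origin phasing,
96-channel mutation spectra with signature refitting, and Poisson burden
regression.

This vignette explains the models, the tunable parameters and the design
decisions. The README shows a worked example; `scripts/acceptance.R`
reruns the headline computations.

## The candidate caller

A site is scored with the posterior probability that the child carries an
allele absent from both parental genotypes. The model enumerates the
`3 x 3 x 3 = 27` diploid genotype configurations (RR, RA, AA per trio
member) with

* binomial read likelihoods: alternate-read probability `e` for RR, `0.5`
  for RA, `1 - e` for AA, with per-read error `e = 0.005` by default;
* population genotype priors on the parents from an alternate allele
  frequency `hetPrior = 1e-3` (the order of per-site heterozygosity in
  macaque);
* Mendelian transmission probabilities, with `mutationPrior` as the
  weight of every non-Mendelian configuration.

Candidates with posterior `> 0.5` enter the filter cascade.

**Why the default `mutationPrior` is 1e-2, not the biological per-base
mutation rate.** The posterior gate and the hard filters divide labour:
the gate asks "is there any de novo interpretation of these reads at
all?" and the filters remove specific, interpretable failure modes with
an audit trail. Under a strict prior of 1e-8, a parent sequenced at depth
`d` explains the child's allele as an inherited heterozygote with weight
about `1e-3 * 2^-d`, which exceeds 1e-8 whenever `d < ~18`; at 23.6x
average coverage about a fifth of true DNMs would then be silently
discarded by the gate, and sites with a low-coverage or alt-carrying
parent would never reach the depth and parental-evidence filters that
exist to count and remove them. Trio callers in production behave
permissively in exactly this way, admitting thousands of candidates per
individual past the probability gate. The default is therefore a
permissive screening prior; passing `mutationPrior = 1e-8` restores the
strict Bayesian reading when a single calibrated posterior is wanted
instead of a filter audit trail.

## The filter cascade

`runCascade()` applies, in order: posterior gate; read depth in `[4, 80]`
for child and both parents; child variant allele fraction (VAF) in
`[0.35, 0.70]` on autosomes and the female X, strictly `> 0.70` on the
male X, Y excluded; alternate reads on both strands with at least two
alternate reads; repeat mask; segmental-duplication mask; population
allele frequency `<= 0.01`; parental evidence (fail when either parent
has more than one alternate read or VAF `> 0.10`); and a two-sided exact
binomial test of allele balance at `p = 0.5`, Benjamini-Hochberg adjusted
within each offspring, removing adjusted `p < 0.05`.

Numerical conventions: VAF bounds are inclusive (the male-X bound is
strict); the parental VAF rule is strict; VCF coordinates are 1-based,
BED masks 0-based half-open, and mask containment is tested on the single
mutated base. The binomial p-value is the minimum-likelihood two-sided
value, which at `p = 0.5` equals the doubled tail. Each candidate is
attributed to the *first* failing stage, so per-stage removal counts sum
with survivors to the input count. The surviving *set* is invariant under
stage reordering whenever the binomial stage is unaffected, because the
other predicates are site-local and independent; per-stage counts of
course change with the order.

The FDR correction is applied within each offspring rather than
cohort-wide: removals at this stage are expected to be "between zero and
a few" per sample, which is the behaviour of a per-sample correction.

## What the cascade costs in sensitivity

With heterozygous alternate reads distributed `Binomial(depth, 0.5)`, the
inclusive `[0.35, 0.70]` VAF window passes

```{r vaf-survival}
survival <- function(md) {
  dps <- 4:80
  sum(dpois(dps, md) * vapply(dps, function(n) {
    a <- 2:n
    ok <- a / n >= 0.35 & a / n <= 0.70
    sum(dbinom(a, n, 0.5) * ok * (1 - 2 * 0.5^a))
  }, numeric(1)))
}
round(c(`20x` = survival(20), `23.6x` = survival(23.6),
        `32x` = survival(32), `40x` = survival(40)), 3)
```

of true het DNMs. This is a property of exact binomial arithmetic, not of
any implementation choice: at 23.6x roughly 10 percent of genuinely
heterozygous de novo sites fall outside the VAF window and are removed,
and 95 percent survival is reached only around 32x. Consequently an
end-to-end simulation whose *true* burden averages 10.5 DNMs per
offspring yields a *filtered* mean near `10.5 * 0.895 = 9.4` at default
coverage. The test suite asserts the 95 percent survival bound at 40x and
checks that observed survival at 23.6x matches the closed form above.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study
conditions every downstream module is validated against.

* **Burden.** Each offspring draws `Poisson(lambda)` baseline mutations
  with `lambda = 10.5 + 1.5 * (paternal age - mean) + 0.4 *
  (maternal age - mean)`. Ages are drawn uniformly from 5-15 (sires) and
  4-12 (dams) years; slopes are the literature's 1.5-2 per paternal year
  and 0.3-0.5 per maternal year. Age effects are centred at the realised
  cohort means so the configured burden *is* the cohort mean. Burden is
  parameterised per offspring, not per base: mutations are placed on a
  20 Mb synthetic reference while a nominal callable genome of 1.32 Gb is
  carried through to rate computation, giving desk-scale runtimes with
  genome-scale statistics.
* **Spectra.** Baseline channels are drawn from the 0.2 / 0.8 mixture of
  the packaged SBS1-like and SBS5-like signatures, renormalised to the
  synthetic reference's trinucleotide frequencies, and placed uniformly
  among context-matching positions. Hypermutator offspring (exactly the
  offspring of an MBD4 -/- dam; all hypermutator trios share one dam)
  additionally receive `Poisson(30)` CpG C>T and `Poisson(15)` CpA C>T
  maternal mutations. These defaults reproduce the observed structure: a
  four- to sixfold burden increase, CpG C>T counts concentrated in the
  25-39 range, and a CpA C>T share of roughly 28 percent of hypermutator
  calls.
* **Parent of origin.** Baseline mutations are paternal with probability
  0.742 (alpha 2.87); excess mutations are always maternal.
* **Evidence.** Child depth is `Poisson(23.6)` with `Binomial(depth,
  0.5)` alternate reads and a binomial strand split; parental alternate
  reads arise only from the base error rate (0.001, one Q30 error per
  thousand bases). On a male X the depth halves and the alternate
  fraction is `1 - error` (hemizygous).
* **Phaseability.** Informative heterozygous sites occur at density
  0.00151 per bp within a 500 bp fragment window (paired-end library
  scale), so the phaseable fraction is `1 - exp(-0.00151 * 500) = 0.53`,
  matching the 50-53 percent phased in real data. Supporting reads carry
  the DNM alternate allele together with the parentally-resolved allele
  of the linked site.
* **Artifacts.** Seven artifact classes are generated on demand, each
  constructed to *pass* every cascade stage before its target and to
  *fail* exactly the targeted stage: an inherited allele undercalled in a
  parent (two parental alt reads at solid depth) and a parental mosaic
  signal (one alt read at depth 5-9, VAF just above 10 percent) for the
  parental stage; one-sided strand support for the strand stage; a
  low-coverage parent (depth 1-3) for the depth stage; a common
  population variant (AF 0.02-0.30) for the frequency stage; a
  repeat-embedded site for the repeat mask; and an allele-biased site
  (alt fraction 0.75-0.85, as from a clonal CNV or mapping bias) for the
  VAF stage. Low-side allele bias is not used because reads at VAF ~0.3
  of modest depth are better explained as errors and are correctly
  removed by the posterior gate instead.

**The default genome is autosomal.** With an X chromosome in the default
mix, forced-maternal male-X mutations would shift the realised
parent-of-origin split away from the configured 0.742 and distort the
phasing calibration, which are the stated study conditions. X simulation
(`xFraction > 0`) exists to exercise the male-X VAF rule, halved male-X
coverage and maternal-only origin, and is covered by tests.

**What the generator does not emulate.** Alignment and mapping errors,
base-quality structure, indels, multi-allelic sites, relatedness between
control parents, and linkage disequilibrium at informative sites. Passing
tests therefore demonstrate the pipeline's statistical behaviour under an
idealised read model, not robustness to raw sequencing data.

## Phasing

An informative site is a heterozygous child site where exactly one
assignment of the child's alleles to the parents is Mendelian-consistent;
`classifyInformativeSite()` returns the allele-to-parent map and treats
Mendelian-inconsistent trios as uninformative with a warning (they occur
at low rate in noisy data and should not abort a run). Each read carrying
the DNM alternate allele votes for the parent implied by its linked
informative allele; unanimity is required, any conflict or the absence of
votes yields `unphased`. This conservative conflict rule costs a little
phaseability but makes a wrong assignment impossible without read errors,
which is why truth-concordance on artifact-free simulations is exactly
100 percent. The summary statistic alpha is the paternal:maternal count
ratio, reported as `NA` when no maternal calls exist.

## Spectra and signatures

Spectra live on the standard 96 channels: pyrimidine-centred
trinucleotide contexts, purine-centred mutations collapsed by reverse
complement. Catalog renormalisation between genomes multiplies each
channel weight by the target-to-source frequency ratio of its context and
rescales each signature to sum 1; it is exactly invertible. The packaged
catalog is a synthetic, deterministic stand-in - SBS1-like with 95
percent of mass on CpG C>T, SBS5-like flat with a mild T>C tilt - with
qualitative, not numerical, fidelity to the COSMIC signatures; a real
catalog can be read from TSV. Exposures are estimated by nonnegative
least squares against a fixed catalog (`pracma::lsqnonneg`) rather than
de novo NMF extraction: at a handful of samples NMF is not reproducible,
and the quantity of interest is an attribution between two known germline
signatures. Per-context enrichment is tested by Poisson regression of
per-offspring counts on a hypermutator indicator, Bonferroni-adjusted
across contexts (conservative, configurable); the CpA C>T model adds MBD4
genotype and parental ages as covariates.

## Burden models and the mutation rate

Callable bases are counted from depth tracks with the half-open bins
`[0,1)`, `[1,4)`, `[4,80)`, `[80, Inf)`. The per-generation mutation rate
divides each trio's filtered DNM count by its callable bases and averages
over trios. The haploid-callable denominator is used because the
published per-offspring count, callable size and rate are mutually
consistent only under that convention; the pooled alternative
(`sum(counts) / sum(callable)`) is reported alongside, and the
`RateEstimate` object carries a denominator marker.

Burden regression is a Poisson GLM with log link (IRLS via `stats::glm`)
of counts on paternal age, maternal age, MBD4 heterozygote and homozygote
indicators (the dam's genotype), and callable bases. Callable bases enter
as a covariate rather than an offset, since the modelling question is
whether coverage *explains* burden, not to normalise by it. Constant
covariates raise an identifiability error naming the term. The same model
is fit per mutation class, and an interaction variant adds
`hypermutator x maternal age` to ask whether the excess accumulates with
the dam's age.

## Reproducibility and problem sizes

One global seed drives every stage through fixed substreams, and
identical seeds give byte-identical outputs. The simulations used by the
tests and the acceptance script are sized for a desk machine: a 20 Mb
reference with 200 control and 50 hypermutator trios for the end-to-end
checks (about half a minute in total), smaller references for unit-level
properties. Statistical assertions use bands of three standard errors of
the quantity under test, or the rounding precision of a published value
where one is being reproduced.

## Known limitations

* The caller is single-site and biallelic; indels, multi-nucleotide
  variants and joint calling across overlapping pedigrees are out of
  scope.
* The permissive posterior default trades calibrated posteriors for
  filter-stage attribution (see above).
* The packaged signature catalog is synthetic; numerical exposure values
  against real COSMIC signatures require supplying the real table.
* Phasing consumes pre-extracted read observations; BAM parsing is not
  included.
* At default coverage the VAF window removes about 10 percent of true
  heterozygous DNMs (exact arithmetic above); observed filtered burdens
  underestimate true burdens accordingly, exactly as in real pipelines.
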