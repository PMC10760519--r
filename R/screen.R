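# Candidate causal-genotype screens: private homozygotes in the proband
# and genes with biallelic damaging variants in any parent.

# genotype helpers on "a/b" strings
.isHomAlt <- function(gt) !is.na(gt) & gt %in% c("1/1", "1|1")
.isHet <- function(gt) !is.na(gt) & gt %in% c("0/1", "1/0", "0|1", "1|0")

#' Screen for rare homozygous variants private to a proband
#'
#' Keeps variants that are homozygous-alternate in the proband, have
#' population allele frequency below \code{afMax}, and are not
#' homozygous-alternate in any of the other listed parents.
#'
#' @param variants data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{gene}, \code{impact}, \code{af}, plus
#'   one genotype column per sample (named by sample id).
#' @param proband proband sample id (its genotype column must exist).
#' @param otherParents sample ids of the other parents in the cohort.
#' @param afMax allele-frequency cutoff (strictly below retained;
#'   default 0.01).
#' @return a [ScreenResult-class] with the retained variants and
#'   per-filter removal counts.
#' @export
privateHomozygoteScreen <- function(variants, proband, otherParents,
                                    afMax = 0.01) {
  if (!proband %in% names(variants))
    stop("missing proband genotype column: ", proband)
  if (any(!is.na(variants$af) & (variants$af < 0 | variants$af > 1)))
    stop("allele frequency outside [0, 1]")
  n0 <- nrow(variants)
  keep <- .isHomAlt(variants[[proband]])
  nHom <- sum(keep)
  keep2 <- keep & !is.na(variants$af) & variants$af < afMax
  nRare <- sum(keep2)
  othersHom <- rep(FALSE, n0)
  for (p in intersect(otherParents, names(variants)))
    othersHom <- othersHom | .isHomAlt(variants[[p]])
  keep3 <- keep2 & !othersHom
  removed <- c(not_homozygous = n0 - nHom,
               common = nHom - nRare,
               homozygous_elsewhere = nRare - sum(keep3))
  new("ScreenResult", retained = variants[keep3, , drop = FALSE],
      removed = as.numeric(removed) |> setNames(names(removed)),
      proband = proband, mode = "private_homozygote")
}

#' Screen genes for biallelic damaging variants in any parent
#'
#' Restricts to high- and moderate-impact variants in the candidate gene
#' list and reports genes in which some parent is homozygous-alternate for
#' one such variant, or carries two or more heterozygous such variants
#' (compound-heterozygous candidates; phase unknown, flagged).
#'
#' @param variants annotated variant data.frame (see
#'   [privateHomozygoteScreen()]).
#' @param candidateGenes character vector of gene symbols to interrogate.
#' @param parents sample ids of the dams and sires to screen.
#' @return a [ScreenResult-class]; \code{retained} has one row per
#'   (gene, parent) candidate with a \code{mechanism} column
#'   (\code{"homozygous"} or \code{"compound_het"}).
#' @export
biallelicDamagingScreen <- function(variants, candidateGenes, parents) {
  if (length(candidateGenes) == 0) stop("gene list must be nonempty")
  dmg <- variants[variants$impact %in% c("high", "moderate") &
                    variants$gene %in% candidateGenes, , drop = FALSE]
  hits <- list()
  for (g in unique(dmg$gene)) {
    vg <- dmg[dmg$gene == g, , drop = FALSE]
    for (p in intersect(parents, names(vg))) {
      gts <- vg[[p]]
      if (any(.isHomAlt(gts))) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene = g, parent = p, mechanism = "homozygous",
          n_variants = sum(.isHomAlt(gts)), stringsAsFactors = FALSE)
      } else if (sum(.isHet(gts)) >= 2) {
        hits[[length(hits) + 1L]] <- data.frame(
          gene = g, parent = p, mechanism = "compound_het",
          n_variants = sum(.isHet(gts)), stringsAsFactors = FALSE)
      }
    }
  }
  retained <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene = character(0), parent = character(0),
               mechanism = character(0), n_variants = integer(0),
               stringsAsFactors = FALSE)
  new("ScreenResult", retained = retained,
      removed = c(non_damaging_or_off_list = nrow(variants) - nrow(dmg)),
      proband = NA_character_, mode = "biallelic_damaging")
}

#' @describeIn privateHomozygoteScreen accessor for the retained rows.
#' @param x a \code{ScreenResult}.
#' @export
screenRetained <- function(x) {
  stopifnot(is(x, "ScreenResult"))
  x@retained
}
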