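# File formats: trio VCF (GT:DP:AD:ADF:ADR), BED masks, PED pedigrees,
# allele-frequency and depth-track TSVs, truth manifests.
#
# Coordinate conventions: VCF and internal positions are 1-based; BED is
# 0-based half-open; containment is tested on the single mutated base.

#' Write trio site records as a multi-sample VCF
#'
#' One file per trio with samples ordered child, mother, father and FORMAT
#' \code{GT:DP:AD:ADF:ADR} (AD / ADF / ADR are ref,alt pairs; the
#' reference strand split is not tracked by the pipeline and is written as
#' an even split). The population allele frequency, when present, is
#' written as \code{POPAF} INFO field.
#'
#' @param records evidence data.frame rows of a single trio (see
#'   [simulateSiteEvidence()]); optional columns \code{child_gt},
#'   \code{mother_gt}, \code{father_gt} override the default genotypes
#'   (child 0/1, parents 0/0).
#' @param path output path.
#' @param sampleNames length-3 character vector (child, mother, father).
#' @return the path, invisibly.
#' @export
writeTrioVcf <- function(records, path,
                         sampleNames = c("CHILD", "MOTHER", "FATHER")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=TrioDNM",
    "##INFO=<ID=POPAF,Number=1,Type=Float,Description=\"Population alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=ADF,Number=R,Type=Integer,Description=\"Allelic depths, forward strand\">",
    "##FORMAT=<ID=ADR,Number=R,Type=Integer,Description=\"Allelic depths, reverse strand\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(sampleNames, collapse = "\t"))), con)
  if (nrow(records) == 0) return(invisible(path))
  fmt <- function(prefix, gtDefault) {
    gtCol <- paste0(prefix, "_gt")
    gt <- if (gtCol %in% names(records)) records[[gtCol]] else
      rep(gtDefault, nrow(records))
    dp <- records[[paste0(prefix, "_dp")]]
    refAd <- records[[paste0(prefix, "_ref_ad")]]
    altAd <- records[[paste0(prefix, "_alt_ad")]]
    adf <- records[[paste0(prefix, "_adf")]]
    adr <- records[[paste0(prefix, "_adr")]]
    refF <- ceiling(refAd / 2)
    paste0(gt, ":", dp, ":", refAd, ",", altAd, ":",
           refF, ",", adf, ":", refAd - refF, ",", adr)
  }
  info <- ifelse(is.na(records$pop_af), ".",
                 sprintf("POPAF=%g", records$pop_af))
  id <- if ("dnm_id" %in% names(records)) records$dnm_id else "."
  lines <- paste(records$chrom, records$pos, id, records$ref, records$alt,
                 ".", "PASS", info, "GT:DP:AD:ADF:ADR",
                 fmt("child", "0/1"), fmt("mother", "0/0"),
                 fmt("father", "0/0"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a trio VCF back into site records
#'
#' Inverse of [writeTrioVcf()]: parses a multi-sample VCF whose first
#' three samples are child, mother, father and whose FORMAT carries
#' GT:DP:AD:ADF:ADR.
#'
#' @param path VCF path.
#' @return evidence data.frame (alt components of AD/ADF/ADR recovered;
#'   genotypes in \code{child_gt} etc.).
#' @export
readTrioVcf <- function(path) {
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@gt) == 0) {
    out <- .emptyEvidence()
    out$child_gt <- out$mother_gt <- out$father_gt <- character(0)
    return(out)
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (length(samples) < 3)
    stop("trio VCF must contain three samples")
  get <- function(el) vcfR::extract.gt(vcf, element = el)
  gt <- get("GT"); dp <- get("DP"); ad <- get("AD")
  adf <- get("ADF"); adr <- get("ADR")
  if (anyNA(gt) || anyNA(dp) || anyNA(ad) || anyNA(adf) || anyNA(adr)) {
    bad <- which(apply(is.na(gt) | is.na(dp) | is.na(ad) |
                         is.na(adf) | is.na(adr), 1, any))
    stop("missing FORMAT field(s) at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  splitPair <- function(x, k) as.integer(vapply(strsplit(x, ","),
                                               `[`, character(1), k))
  role <- c("child", "mother", "father")
  out <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    stringsAsFactors = FALSE)
  if ("ID" %in% names(fix)) out$dnm_id <- fix$ID
  for (i in 1:3) {
    s <- samples[i]
    out[[paste0(role[i], "_gt")]] <- unname(gt[, s])
    out[[paste0(role[i], "_dp")]] <- as.integer(dp[, s])
    out[[paste0(role[i], "_ref_ad")]] <- splitPair(ad[, s], 1)
    out[[paste0(role[i], "_alt_ad")]] <- splitPair(ad[, s], 2)
    out[[paste0(role[i], "_adf")]] <- splitPair(adf[, s], 2)
    out[[paste0(role[i], "_adr")]] <- splitPair(adr[, s], 2)
  }
  info <- vcf@fix[, "INFO"]
  popaf <- suppressWarnings(
    as.numeric(sub("^.*POPAF=([0-9.eE+-]+).*$", "\\1", info)))
  popaf[!grepl("POPAF=", info)] <- NA_real_
  out$pop_af <- popaf
  out
}

#' Read a BED mask into GRanges
#'
#' Strict 3+ column BED (0-based half-open); malformed lines raise an
#' error naming the line number. Intervals are converted to 1-based
#' closed \code{GRanges}.
#'
#' @param path BED path.
#' @return a \code{GRanges}.
#' @export
readBedMask <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ok <- length(p) >= 3 &&
      !is.na(suppressWarnings(as.numeric(p[2]))) &&
      !is.na(suppressWarnings(as.numeric(p[3]))) &&
      as.numeric(p[2]) < as.numeric(p[3])
    if (!ok) stop("malformed BED line ", i, ": ", lines[i])
  }
  chrom <- vapply(parts, `[`, character(1), 1)
  start0 <- as.numeric(vapply(parts, `[`, character(1), 2))
  end0 <- as.numeric(vapply(parts, `[`, character(1), 3))
  GRanges(chrom, IRanges(start = start0 + 1, end = end0))
}

#' @rdname readBedMask
#' @param gr a \code{GRanges} to write.
#' @export
writeBedMask <- function(gr, path) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read a pedigree as a PED file
#'
#' One row per individual (family, id, father, mother, sex, phenotype)
#' with extra columns carrying the age at conception and MBD4 genotype.
#' The child's phenotype flags hypermutator status (2) versus control (1).
#'
#' @param pedigree pedigree data.frame from [buildPedigree()].
#' @param path file path.
#' @export
writePedFile <- function(pedigree, path) {
  rows <- list()
  for (i in seq_len(nrow(pedigree))) {
    p <- pedigree[i, ]
    rows[[length(rows) + 1L]] <- data.frame(
      fam = p$trio, id = p$father, father = "0", mother = "0", sex = 1,
      phenotype = 1, age = p$paternal_age, mbd4 = p$father_mbd4,
      callable = NA, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      fam = p$trio, id = p$mother, father = "0", mother = "0", sex = 2,
      phenotype = 1, age = p$maternal_age, mbd4 = p$mother_mbd4,
      callable = NA, stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      fam = p$trio, id = p$child, father = p$father, mother = p$mother,
      sex = if (p$child_sex == "M") 1 else 2,
      phenotype = if (p$hypermutator) 2 else 1,
      age = NA, mbd4 = NA, callable = p$callable,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePedFile
#' @return \code{readPedFile}: the pedigree data.frame (one row per trio).
#' @export
readPedFile <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  kids <- df[df$father != "0", , drop = FALSE]
  out <- lapply(seq_len(nrow(kids)), function(i) {
    k <- kids[i, ]
    fa <- df[df$id == k$father & df$fam == k$fam, ][1, ]
    mo <- df[df$id == k$mother & df$fam == k$fam, ][1, ]
    data.frame(trio = k$fam, child = k$id, mother = mo$id, father = fa$id,
               child_sex = if (k$sex == 1) "M" else "F",
               paternal_age = fa$age, maternal_age = mo$age,
               mother_mbd4 = mo$mbd4, father_mbd4 = fa$mbd4,
               hypermutator = k$phenotype == 2, callable = k$callable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Read / write a population allele-frequency table
#'
#' TSV with columns chrom, pos, ref, alt, af.
#'
#' @param path file path.
#' @export
readPopulationAf <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (any(df$af < 0 | df$af > 1))
    stop("allele frequency outside [0, 1]")
  df
}

#' @rdname readPopulationAf
#' @param af allele-frequency data.frame.
#' @export
writePopulationAf <- function(af, path) {
  write.table(af, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a BedGraph-style depth track
#'
#' @param path file path.
#' @export
readDepthTrack <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "depth"))
  df
}

#' @rdname readDepthTrack
#' @param track depth-track data.frame (chrom, start, end, depth).
#' @export
writeDepthTrack <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "depth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write / read the simulation truth manifest
#'
#' @param truth a [TruthSet-class].
#' @param path file path.
#' @export
writeTruthManifest <- function(truth, path) {
  write.table(truthDnms(truth), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthManifest
#' @export
readTruthManifest <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a filter trace as TSV
#'
#' @param trace a [FilterTrace-class].
#' @param path file path.
#' @export
writeFilterTrace <- function(trace, path) {
  rem <- stageRemovals(trace)
  surv <- trace@inputCount - cumsum(rem)
  df <- data.frame(stage = names(rem), removed = as.integer(rem),
                   surviving = as.integer(surv))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
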