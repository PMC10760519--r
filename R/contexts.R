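# Trinucleotide context conventions shared by the simulator, the spectrum
# builder and the catalog renormalisation.

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 SBS channel labels
#'
#' Channels follow the standard convention: substitutions ordered C>A, C>G,
#' C>T, T>A, T>C, T>G; within a substitution, contexts ordered by 5' then 3'
#' base (A, C, G, T). Purine-centred mutations are represented by their
#' reverse complement.
#'
#' @return character vector of 96 labels such as \code{"A[C>T]G"}.
#' @export
sbsChannels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  out <- character(0)
  for (s in subs) {
    ref <- substr(s, 1, 1)
    for (p5 in .BASES) for (p3 in .BASES)
      out <- c(out, paste0(p5, "[", s, "]", p3))
  }
  out
}

#' The 32 pyrimidine-centred trinucleotide contexts
#'
#' @return character vector of 32 contexts (central base C or T), ordered
#'   with C-centred before T-centred, then by 5' and 3' base.
#' @export
contexts32 <- function() {
  out <- character(0)
  for (ctr in c("C", "T")) for (p5 in .BASES) for (p3 in .BASES)
    out <- c(out, paste0(p5, ctr, p3))
  out
}

#' Artifact classes emitted by the synthetic cohort generator
#'
#' Each class is constructed to violate exactly one cascade stage:
#' \code{inherited_undercalled_in_parent} and \code{mosaic_parent_signal}
#' the parental-evidence filter (alt-read-count and VAF branch
#' respectively), \code{strand_biased_error} the strand filter,
#' \code{low_depth_site} the depth filter, \code{common_population_variant}
#' the population-frequency filter, \code{repeat_region_site} the repeat
#' mask and \code{allele_biased_site} the VAF filter.
#'
#' @return character vector of the seven class names.
#' @export
artifactClasses <- function() {
  c("inherited_undercalled_in_parent", "strand_biased_error",
    "low_depth_site", "common_population_variant", "repeat_region_site",
    "mosaic_parent_signal", "allele_biased_site")
}

# reverse complement of fixed-width uppercase ACGT strings
.revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, "", fixed = TRUE),
                function(s) paste(rev(s), collapse = ""), character(1)))
}

# collapse a trinucleotide to its pyrimidine-centred representative
.collapseContext <- function(ctx) {
  ctr <- substr(ctx, 2, 2)
  flip <- ctr %in% c("A", "G")
  out <- ctx
  out[flip] <- .revcomp(ctx[flip])
  out
}

#' Map a mutation to its 96-channel label
#'
#' Purine-centred inputs are reverse complemented so every mutation lands on
#' a pyrimidine-centred channel.
#'
#' @param context length-3 trinucleotide around the mutated base
#'   (forward strand); central base must equal \code{ref}.
#' @param ref,alt reference and alternate base.
#' @return channel label(s), e.g. \code{"A[C>T]G"}. Vectorised.
#' @examples
#' channelOf("ACG", "C", "T")  # "A[C>T]G"
#' channelOf("TGA", "G", "A")  # "T[C>T]A" after strand collapse
#' @export
channelOf <- function(context, ref, alt) {
  n <- max(length(context), length(ref), length(alt))
  context <- rep_len(toupper(context), n)
  ref <- rep_len(toupper(ref), n)
  alt <- rep_len(toupper(alt), n)
  if (any(nchar(context) != 3L))
    stop("context must have length 3")
  bad <- !vapply(strsplit(context, "", fixed = TRUE),
                 function(s) all(s %in% .BASES), logical(1)) |
    !(ref %in% .BASES) | !(alt %in% .BASES)
  if (any(bad))
    stop("non-ACGT base in context, ref or alt")
  if (any(substr(context, 2, 2) != ref))
    stop("central context base must equal ref")
  if (any(ref == alt))
    stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  context[flip] <- .revcomp(context[flip])
  ref[flip] <- .COMPLEMENT[ref[flip]]
  alt[flip] <- .COMPLEMENT[alt[flip]]
  paste0(substr(context, 1, 1), "[", ref, ">", alt, "]",
         substr(context, 3, 3))
}

# coerce any supported reference representation to a named character vector
.asReferenceChar <- function(reference) {
  if (is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    if (is.null(names(out)))
      names(out) <- paste0("chr", seq_along(out))
    return(out)
  }
  if (is(reference, "DNAString"))
    return(c(chr1 = as.character(reference)))
  if (is.character(reference)) {
    if (is.null(names(reference)))
      names(reference) <- paste0("chr", seq_along(reference))
    return(toupper(reference))
  }
  stop("reference must be a DNAString(Set) or character vector")
}

#' Trinucleotide context frequencies of a reference sequence
#'
#' Counts every interior trinucleotide of the reference, collapses
#' purine-centred occurrences onto their reverse complement, and normalises
#' to frequencies over the 32 pyrimidine-centred contexts. Windows
#' containing non-ACGT characters are skipped and counted in the
#' \code{skipped} slot.
#'
#' @param reference a \code{DNAStringSet}, \code{DNAString} or character
#'   vector of sequences.
#' @return a [ContextFrequencies-class] object.
#' @examples
#' buildContextModel("AAAA")   # a single collapsed context, TTT
#' @export
buildContextModel <- function(reference) {
  seqs <- .asReferenceChar(reference)
  if (any(nchar(seqs) < 3))
    stop("sequence length must be >= 3")
  dna <- DNAStringSet(seqs)
  counts64 <- colSums(oligonucleotideFrequency(dna, width = 3, step = 1))
  nWindows <- sum(pmax(nchar(seqs) - 2L, 0L))
  skipped <- nWindows - sum(counts64)
  if (sum(counts64) == 0)
    stop("no ACGT trinucleotide windows in the reference")
  if (skipped > 0)
    message(skipped, " window(s) with non-ACGT characters skipped")
  collapsed <- .collapseContext(names(counts64))
  freq <- vapply(contexts32(),
                 function(ctx) sum(counts64[collapsed == ctx]),
                 numeric(1))
  freq <- freq / sum(freq)
  new("ContextFrequencies", freq = freq, skipped = as.numeric(skipped))
}

#' @describeIn buildContextModel accessor for the frequency vector.
#' @param x a \code{ContextFrequencies} object.
#' @export
contextFreq <- function(x) {
  stopifnot(is(x, "ContextFrequencies"))
  x@freq
}

# ---- internal context index ------------------------------------------------
#
# Integer encoding of every interior trinucleotide of the reference so that
# simulated mutations can be placed uniformly among positions matching a
# requested (collapsed) context. Position i of chromosome c has code
# 16*b[i-1] + 4*b[i] + b[i+1] with A,C,G,T -> 0..3; non-ACGT windows get NA.

.contextIndex <- function(reference) {
  seqs <- .asReferenceChar(reference)
  # canonical ordering: code k corresponds to trinucs in base-4 order
  code2tri <- character(64)
  for (b1 in 0:3) for (b2 in 0:3) for (b3 in 0:3)
    code2tri[16 * b1 + 4 * b2 + b3 + 1] <-
      paste0(.BASES[b1 + 1], .BASES[b2 + 1], .BASES[b3 + 1])
  collapsed <- .collapseContext(code2tri)
  ctxLevels <- contexts32()
  code2ctx32 <- match(collapsed, ctxLevels)   # 1..32 per 64-code
  chromIdx <- lapply(seqs, function(s) {
    b <- utf8ToInt(s)
    map <- rep(NA_integer_, 255)
    map[utf8ToInt("A")] <- 0L; map[utf8ToInt("C")] <- 1L
    map[utf8ToInt("G")] <- 2L; map[utf8ToInt("T")] <- 3L
    v <- map[b]
    n <- length(v)
    if (n < 3) return(list(codes = integer(0)))
    codes <- 16L * v[-c(n - 1L, n)] + 4L * v[-c(1L, n)] + v[-c(1L, 2L)]
    list(codes = codes)   # codes[i] describes position i+1 (1-based)
  })
  env <- new.env(parent = emptyenv())
  list(seqs = seqs, chromIdx = chromIdx, code2ctx32 = code2ctx32,
       code2tri = code2tri,
       lens = setNames(nchar(seqs, type = "bytes"), names(seqs)),
       cache = env)
}

# positions (per chromosome) whose collapsed context matches ctx (1..32 id);
# the full partition is computed once per index and cached
.contextPositions <- function(index, ctx) {
  if (is.null(index$cache$partition)) {
    index$cache$partition <- lapply(index$chromIdx, function(ci) {
      ctx32 <- index$code2ctx32[ci$codes + 1L]
      split(seq_along(ci$codes) + 1L,
            factor(ctx32, levels = seq_len(32)))
    })
  }
  lapply(index$cache$partition, function(p) p[[ctx]])
}

# forward-strand trinucleotide at pos of chrom (NA near ends); vectorised
# over pos within one chromosome, via the precomputed code vector (O(1)
# per lookup; substring on long strings is O(sequence length))
.contextAt <- function(index, chrom, pos) {
  codes <- index$chromIdx[[chrom]]$codes
  out <- rep(NA_character_, length(pos))
  ok <- pos >= 2 & pos <= length(codes) + 1
  cd <- codes[pos[ok] - 1]
  out[ok] <- ifelse(is.na(cd), NA_character_, index$code2tri[cd + 1L])
  out
}

# vectorised context lookup across chromosomes (one substring call each)
.contextAtMulti <- function(index, chrom, pos) {
  out <- rep(NA_character_, length(pos))
  for (ch_ in unique(chrom)) {
    sel <- chrom == ch_
    out[sel] <- .contextAt(index, ch_, pos[sel])
  }
  out
}
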