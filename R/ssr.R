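# Perfect tandem-repeat (SSR) mining and classification.
#
# A locus is a maximal perfect run of a primitive 1-6 nt unit, reported
# once with the smallest unit size and anchored at the earliest phase.
# Runs touching an N are broken at the N, and the reported tract is
# trimmed to complete units so that tract_bp == unit_size * repeat_count.

#' Classify an SSR tract by length
#'
#' Class I (hypervariable) tracts are >= 20 bp, class II tracts are
#' 12-19 bp, shorter tracts are `sub12`.  The 20-bp boundary is the
#' standard hypervariable-SSR convention.
#'
#' @param tractBp Integer vector of tract lengths in bp (>= 1).
#' @return Character vector over `{"I", "II", "sub12"}`.
#' @examples
#' classifySSR(c(24, 12, 19, 20, 11))
#' @export
classifySSR <- function(tractBp) {
  tractBp <- as.integer(tractBp)
  if (any(is.na(tractBp)) || any(tractBp < 1L))
    .stopf("tract lengths must be positive integers")
  ifelse(tractBp >= 20L, "I", ifelse(tractBp >= 12L, "II", "sub12"))
}

.emptySSRFrame <- function() {
  data.frame(gene_id = character(0), unit = character(0),
             unit_size = integer(0), repeat_count = integer(0),
             start = integer(0), end = integer(0), tract_bp = integer(0),
             ssr_class = character(0), stringsAsFactors = FALSE)
}

## Core miner for a single sequence string.
.findSSRsOne <- function(s, thresholds) {
  L <- nchar(s)
  out <- .emptySSRFrame()[, -1]  # gene_id added by callers
  if (L < 2L) return(out)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  rows <- list()
  for (u in 1:6) {
    if (L < 2L * u) next
    a <- v[seq_len(L - u)]
    b <- v[seq.int(u + 1L, L)]
    m <- a == b & a != "N" & b != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (idx in which(r$values)) {
      i <- starts[idx]
      mlen <- r$lengths[idx]
      cnt <- (mlen + u) %/% u          # complete units
      if (cnt < 2L) next
      unit <- substr(s, i, i + u - 1L)
      if (!.isPrimitiveUnit(unit)) next   # reported at its smaller unit size
      tract <- cnt * u
      if (cnt < thresholds@minRepeats[[as.character(u)]]) next
      if (tract < thresholds@minTractBp) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit = unit, unit_size = u, repeat_count = cnt,
        start = i, end = i + tract - 1L, tract_bp = tract,
        ssr_class = classifySSR(tract), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(out)
  res <- do.call(rbind, rows)
  res <- res[order(res$start, res$unit_size), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mine perfect SSR tracts
#'
#' Reports every maximal perfect tandem run with a primitive unit of size
#' 1-6 that meets both the per-unit-size minimum repeat count and the
#' minimum tract length.  Runs are broken at `N` bases.  A run that could
#' be written with several unit sizes (e.g. `(GAGA)n` as `(GA)2n`) is
#' reported once, with the smallest (primitive) unit, anchored at the
#' earliest phase.
#'
#' @param x A single sequence string, or an [UpstreamSet-class].
#' @param thresholds An [SSRThresholds-class] (default [ssrThresholds()]).
#' @param ... Passed on between methods.
#' @return A data.frame with columns `gene_id` (for `UpstreamSet` input),
#'   `unit`, `unit_size`, `repeat_count`, `start`, `end` (string
#'   positions), `tract_bp`, `ssr_class`; loci sorted by start.
#' @examples
#' findSSRs(strrep("CAA", 7))       # (CAA)7, 21 bp, class I
#' findSSRs("TTCTTTCTTTCT")         # (TTCT)3, 12 bp, class II
#' @export
setGeneric("findSSRs",
           function(x, thresholds = ssrThresholds(), ...)
             standardGeneric("findSSRs"))

#' @rdname findSSRs
#' @export
setMethod("findSSRs", "character", function(x, thresholds = ssrThresholds()) {
  stopifnot(length(x) == 1L)
  s <- toupper(x)
  if (nchar(s)) {
    bad <- .badBases(s)
    if (length(bad))
      .stopf("sequence contains disallowed characters: %s",
             paste(bad, collapse = ", "))
  }
  .findSSRsOne(s, thresholds)
})

#' @rdname findSSRs
#' @export
setMethod("findSSRs", "UpstreamSet", function(x, thresholds = ssrThresholds()) {
  seqs <- as.character(upstreamSeqs(x))
  ids <- geneIds(x)
  rows <- lapply(seq_along(seqs), function(i) {
    df <- .findSSRsOne(seqs[[i]], thresholds)
    if (nrow(df)) cbind(gene_id = ids[i], df, stringsAsFactors = FALSE)
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptySSRFrame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})

#' Expand repeat-count allele series
#'
#' Given a repeat unit and a vector of repeat counts, returns the expanded
#' allele sequences and their lengths in bp.  Length differences between
#' alleles equal `unit_size` times the repeat-count differences, which is
#' what makes flanking-primer amplicon sizes track repeat variation.
#'
#' @param unit Repeat unit (1-6 nt).
#' @param counts Integer vector of repeat counts (>= 1).
#' @return data.frame with columns `repeat_count`, `allele`, `length_bp`.
#' @examples
#' repeatVariantAlleles("GA", c(12, 13, 14))$length_bp  # 24 26 28
#' @export
repeatVariantAlleles <- function(unit, counts) {
  unit <- toupper(unit)
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 1L))
    .stopf("repeat counts must be positive integers")
  if (nchar(unit) < 1L) .stopf("empty repeat unit")
  data.frame(repeat_count = counts,
             allele = strrep(unit, counts),
             length_bp = nchar(unit) * counts,
             stringsAsFactors = FALSE)
}
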