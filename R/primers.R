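# Flanking PCR primer design under hard constraints.
#
# Primers never overlap the marker locus, so amplicon length polymorphism
# tracks repeat variation: expanding the repeat by k units grows the
# product by exactly k * unit_size bp.

#' Primer melting temperature
#'
#' Two-regime convention: Wallace rule `2(A+T) + 4(G+C)` below 14 nt, and
#' the GC/length formula `64.9 + 41 (nG + nC - 16.4) / L` from 14 nt on.
#'
#' @param primer Primer sequence(s), `{A,C,G,T}` only, length >= 10.
#' @return Melting temperature(s) in deg C.
#' @examples
#' meltingTemp("ACGTACGTACGT")     # Wallace: 36
#' meltingTemp(strrep("A", 18))    # 64.9 + 41 * (0 - 16.4) / 18
#' @export
meltingTemp <- function(primer) {
  vapply(toupper(primer), function(p) {
    L <- nchar(p)
    if (L < 10L) .stopf("primer shorter than 10 nt")
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    if (any(ch == "N")) .stopf("primer contains N")
    bad <- setdiff(unique(ch), c("A", "C", "G", "T"))
    if (length(bad))
      .stopf("primer contains disallowed characters: %s",
             paste(bad, collapse = ", "))
    gc <- sum(ch %in% c("G", "C"))
    if (L < 14L) 2 * (L - gc) + 4 * gc
    else 64.9 + 41 * (gc - 16.4) / L
  }, numeric(1), USE.NAMES = FALSE)
}

## Longest suffix of `p` whose reverse complement occurs in `p` is
## > maxLen?  Monotone in suffix length, so testing maxLen + 1 suffices.
.endSelfComplementOK <- function(p, maxLen) {
  q <- maxLen + 1L
  if (nchar(p) < q) return(TRUE)
  suff <- substr(p, nchar(p) - q + 1L, nchar(p))
  !grepl(.revcompPlain(suff), p, fixed = TRUE)
}

## Candidate primers on one side: all (start, len) windows inside
## [from, to] meeting the single-primer constraints.  `v` is the template
## split into characters, `gcCum`/`nCum` cumulative G+C and N counts.
.sideCandidates <- function(template, gcCum, nCum, from, to, constraints) {
  if (to - from + 1L < constraints@primerMin) return(NULL)
  starts <- integer(0); lens <- integer(0)
  for (len in constraints@primerMin:constraints@primerMax) {
    if (to - len + 1L < from) next
    st <- from:(to - len + 1L)
    starts <- c(starts, st)
    lens <- c(lens, rep.int(len, length(st)))
  }
  if (!length(starts)) return(NULL)
  ends <- starts + lens - 1L
  nN <- nCum[ends + 1L] - nCum[starts]
  gc <- (gcCum[ends + 1L] - gcCum[starts]) / lens
  tm <- 64.9 + 41 * ((gcCum[ends + 1L] - gcCum[starts]) - 16.4) / lens
  keep <- nN == 0L & gc >= constraints@gcMin - 1e-9 &
    gc <= constraints@gcMax + 1e-9 &
    tm >= constraints@tmMin - 1e-9 & tm <= constraints@tmMax + 1e-9
  if (!any(keep)) return(NULL)
  data.frame(start = starts[keep], end = ends[keep], len = lens[keep],
             gc = gc[keep], tm = tm[keep])
}

#' Design a flanking primer pair for one locus
#'
#' Deterministically returns the qualifying pair whose product size is
#' closest to the midpoint of the allowed product window (ties: smaller
#' product, then leftmost forward primer, then shorter primers), or
#' `NULL` when no pair satisfies all constraints.  Neither primer may
#' overlap `[locusStart, locusEnd]`; the product must contain it.
#'
#' @param template Template sequence string (an upstream region) or a
#'   single-gene [UpstreamSet-class].
#' @param locusStart,locusEnd Composite marker interval to be bridged
#'   (1-based inclusive string positions).
#' @param constraints A [PrimerConstraints-class].
#' @return One-row data.frame (`fwd_seq`, `rev_seq` both written 5'->3',
#'   `fwd_start`, `fwd_end`, `rev_start`, `rev_end`, `gc_f`, `gc_r`,
#'   `tm_f`, `tm_r`, `product_size`) or `NULL`.
#' @export
designPrimers <- function(template, locusStart, locusEnd,
                          constraints = primerConstraints()) {
  if (methods::is(template, "UpstreamSet")) {
    stopifnot(length(template) == 1L)
    template <- as.character(upstreamSeqs(template))[[1]]
  }
  s <- toupper(template)
  L <- nchar(s)
  locusStart <- as.integer(locusStart); locusEnd <- as.integer(locusEnd)
  stopifnot(1L <= locusStart, locusStart <= locusEnd, locusEnd <= L)
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  gcCum <- c(0L, cumsum(v %in% c("G", "C")))
  nCum <- c(0L, cumsum(v == "N"))
  fwd <- if (locusStart > 1L)
    .sideCandidates(s, gcCum, nCum, 1L, locusStart - 1L, constraints)
  else NULL
  rev <- if (locusEnd < L)
    .sideCandidates(s, gcCum, nCum, locusEnd + 1L, L, constraints)
  else NULL
  if (is.null(fwd) || is.null(rev)) return(NULL)

  ## Sequence-level screens (self-complementarity, template uniqueness)
  ## are costlier; apply them once per surviving candidate.
  screen <- function(df, reverse) {
    seqs <- substring(s, df$start, df$end)
    ok <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      pr <- if (reverse) .revcompPlain(seqs[i]) else seqs[i]
      if (!.endSelfComplementOK(pr, constraints@maxEndSelfComp)) next
      if (constraints@requireUnique &&
          .countOccurrences(seqs[i], s) != 1L) next
      ok[i] <- TRUE
    }
    df[ok, , drop = FALSE]
  }
  fwd <- screen(fwd, reverse = FALSE)
  rev <- screen(rev, reverse = TRUE)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(NULL)

  prod <- outer(rev$end, fwd$start, "-") + 1L   # rows: rev, cols: fwd
  ok <- prod >= constraints@productMin & prod <= constraints@productMax
  if (!any(ok)) return(NULL)
  idx <- which(ok, arr.ind = TRUE)
  p <- prod[ok]
  target <- (constraints@productMin + constraints@productMax) / 2
  o <- order(abs(p - target), p, fwd$start[idx[, 2]], fwd$len[idx[, 2]],
             rev$len[idx[, 1]], rev$end[idx[, 1]])
  ri <- idx[o[1], 1]; fi <- idx[o[1], 2]
  fwdSeq <- substring(s, fwd$start[fi], fwd$end[fi])
  revWindow <- substring(s, rev$start[ri], rev$end[ri])
  data.frame(
    fwd_seq = fwdSeq, rev_seq = .revcompPlain(revWindow),
    fwd_start = fwd$start[fi], fwd_end = fwd$end[fi],
    rev_start = rev$start[ri], rev_end = rev$end[ri],
    gc_f = fwd$gc[fi], gc_r = rev$gc[ri],
    tm_f = fwd$tm[fi], tm_r = rev$tm[ri],
    product_size = p[o[1]], stringsAsFactors = FALSE)
}

#' Design primers for every marker in a table
#'
#' @param markers Marker table from [callCNMS()].
#' @param upstream The [UpstreamSet-class] the markers were called on.
#' @param constraints A [PrimerConstraints-class].
#' @return data.frame with one row per marker for which a pair exists
#'   (columns `marker_id` plus the [designPrimers()] columns).
#' @export
addPrimers <- function(markers, upstream,
                       constraints = primerConstraints()) {
  seqs <- as.character(upstreamSeqs(upstream))
  rows <- list()
  for (i in seq_len(nrow(markers))) {
    tpl <- seqs[[markers$gene_id[i]]]
    if (is.null(tpl)) .stopf("marker gene %s not in upstream set",
                             markers$gene_id[i])
    pp <- designPrimers(tpl, markers$comp_start[i], markers$comp_end[i],
                        constraints)
    if (!is.null(pp))
      rows[[length(rows) + 1L]] <- cbind(marker_id = markers$marker_id[i],
                                         pp, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(marker_id = character(0), fwd_seq = character(0),
                      rev_seq = character(0), fwd_start = integer(0),
                      fwd_end = integer(0), rev_start = integer(0),
                      rev_end = integer(0), gc_f = numeric(0),
                      gc_r = numeric(0), tm_f = numeric(0),
                      tm_r = numeric(0), product_size = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
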