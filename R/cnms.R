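# CNMS marker calling: SSR x element-overlap x conservation.
#
# A marker is emitted for every (SSR locus, element) pair where at least
# one hit of that element intersects the SSR tract by >= minOverlap bp
# and the composite interval (union span of the tract and the element's
# overlapping hits) is fully contained in a conserved block of at least
# one comparator.  Multiple hits of one element on one tract collapse
# into a single marker (hit count kept as metadata).

.emptyMarkerFrame <- function() {
  data.frame(marker_id = character(0), gene_id = character(0),
             unit = character(0), unit_size = integer(0),
             repeat_count = integer(0), ssr_class = character(0),
             ssr_start = integer(0), ssr_end = integer(0),
             element = character(0), n_element_hits = integer(0),
             comp_start = integer(0), comp_end = integer(0),
             up_start = integer(0), up_end = integer(0),
             supporting_species = character(0), n_supporting = integer(0),
             stringsAsFactors = FALSE)
}

#' Call CNMS markers
#'
#' @param ssrs SSR table from [findSSRs()] (must carry `gene_id`).
#' @param tfbsHits Element hit table from [scanElements()].
#' @param cnsBlocks CNS block table (rbind-ed [detectCNS()] output with
#'   `target_gene`, `comparator_species`, `t_start`, `t_end`).
#' @param genes Character vector of valid gene ids (the loaded upstream
#'   set).  Hits or blocks referring to other genes raise an error;
#'   default is the union of the inputs' gene ids.
#' @param seqLengths Named integer vector of upstream lengths per gene;
#'   needed to report ATG-relative composite coordinates (`up_start`,
#'   `up_end`).  If omitted those columns are `NA`.
#' @param eligibleClasses SSR classes eligible for marker design
#'   (default `c("I", "II")`: mononucleotide and sub-12 bp tracts are
#'   excluded).
#' @param minUnitSize Minimum SSR unit size (default 2: mononucleotide
#'   runs excluded).
#' @param minOverlap Minimum SSR/element intersection in bp (default 1).
#' @param idPrefix Marker id prefix (default `"CNMS"`); ids are assigned
#'   serially in (gene, position) order so reruns are bit-identical.
#' @return Marker data.frame (see package vignette for the column
#'   contract); markers sorted by gene then position.
#' @export
callCNMS <- function(ssrs, tfbsHits, cnsBlocks, genes = NULL,
                     seqLengths = NULL, eligibleClasses = c("I", "II"),
                     minUnitSize = 2L, minOverlap = 1L,
                     idPrefix = "CNMS") {
  if (is.null(genes))
    genes <- unique(c(ssrs$gene_id, tfbsHits$gene_id, cnsBlocks$target_gene))
  badH <- setdiff(unique(tfbsHits$gene_id), genes)
  badB <- setdiff(unique(cnsBlocks$target_gene), genes)
  badS <- setdiff(unique(ssrs$gene_id), genes)
  if (length(c(badH, badB, badS)))
    .stopf("inconsistent gene ids between inputs: %s",
           paste(unique(c(badH, badB, badS)), collapse = ", "))
  ssrs <- ssrs[ssrs$ssr_class %in% eligibleClasses &
               ssrs$unit_size >= minUnitSize, , drop = FALSE]
  if (nrow(ssrs) == 0L) return(.emptyMarkerFrame())
  rows <- list()
  for (g in sort(unique(ssrs$gene_id))) {
    sg <- ssrs[ssrs$gene_id == g, , drop = FALSE]
    hg <- tfbsHits[tfbsHits$gene_id == g, , drop = FALSE]
    bg <- cnsBlocks[cnsBlocks$target_gene == g, , drop = FALSE]
    if (nrow(hg) == 0L) next
    for (si in seq_len(nrow(sg))) {
      ov <- pmin(sg$end[si], hg$end) - pmax(sg$start[si], hg$start) + 1L
      cand <- hg[ov >= minOverlap, , drop = FALSE]
      if (nrow(cand) == 0L) next
      for (el in sort(unique(cand$element))) {
        ce <- cand[cand$element == el, , drop = FALSE]
        compStart <- min(sg$start[si], ce$start)
        compEnd <- max(sg$end[si], ce$end)
        supp <- conservationSupport(compStart, compEnd, bg)
        if (!length(supp)) next
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, unit = sg$unit[si], unit_size = sg$unit_size[si],
          repeat_count = sg$repeat_count[si], ssr_class = sg$ssr_class[si],
          ssr_start = sg$start[si], ssr_end = sg$end[si],
          element = el, n_element_hits = nrow(ce),
          comp_start = compStart, comp_end = compEnd,
          supporting_species = paste(supp, collapse = ","),
          n_supporting = length(supp), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.emptyMarkerFrame())
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$comp_start, out$comp_end, out$element), ,
             drop = FALSE]
  out <- cbind(marker_id = sprintf("%s%04d", idPrefix, seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  if (!is.null(seqLengths)) {
    L <- as.integer(seqLengths[out$gene_id])
    up <- toUpstreamFrame(out$comp_start, out$comp_end, L)
    out$up_start <- up$start_up
    out$up_end <- up$end_up
  } else {
    out$up_start <- NA_integer_
    out$up_end <- NA_integer_
  }
  rownames(out) <- NULL
  out[, names(.emptyMarkerFrame())]
}

#' Positional histogram of marker midpoints
#'
#' Bins markers by the midpoint of their composite interval in the
#' ATG-relative frame, in `binWidth`-bp intervals over `[1, window]`.
#'
#' @param markers Marker table from [callCNMS()] with non-`NA` `up_start`
#'   and `up_end`.
#' @param binWidth Bin width in bp (default 100).
#' @param window Upstream window in bp (default 1000).
#' @return data.frame with columns `bin_start`, `bin_end`, `count`;
#'   the total is carried in `attr(, "total")` and equals `nrow(markers)`.
#' @export
binPositions <- function(markers, binWidth = 100L, window = 1000L) {
  binWidth <- as.integer(binWidth); window <- as.integer(window)
  nBins <- ceiling(window / binWidth)
  counts <- integer(nBins)
  if (nrow(markers)) {
    if (any(is.na(markers$up_start)) || any(is.na(markers$up_end)))
      .stopf("markers lack ATG-relative coordinates (up_start/up_end)")
    mid <- (markers$up_start + markers$up_end) / 2
    if (any(mid < 1 | mid > window))
      .stopf("marker %s lies outside the [1, %d] window",
             markers$marker_id[which(mid < 1 | mid > window)[1]], window)
    bin <- pmin(nBins, ceiling(mid / binWidth))
    tab <- table(factor(bin, levels = seq_len(nBins)))
    counts <- as.integer(tab)
  }
  out <- data.frame(
    bin_start = (seq_len(nBins) - 1L) * binWidth + 1L,
    bin_end = pmin(seq_len(nBins) * binWidth, window),
    count = counts)
  attr(out, "total") <- sum(counts)
  out
}

#' Physical marker density
#'
#' Average spacing in kb per marker: `span_bp / n_markers / 1000`,
#' reported to one decimal (half-up).
#'
#' @param nMarkers Number of markers (>= 1).
#' @param spanBp Physical span covered, in bp (>= 1).
#' @return Density in kb per marker, one decimal.
#' @examples
#' markerDensity(10, 1e6)   # 100.0
#' @export
markerDensity <- function(nMarkers, spanBp) {
  nMarkers <- as.numeric(nMarkers); spanBp <- as.numeric(spanBp)
  if (is.na(nMarkers) || nMarkers < 1) .stopf("need at least one marker")
  if (is.na(spanBp) || spanBp < 1) .stopf("span must be >= 1 bp")
  roundHalfUp(spanBp / nMarkers / 1000, 1)
}
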