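# Accessors and show methods.

#' @rdname UpstreamSet-class
#' @param object,x An `UpstreamSet`.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname UpstreamSet-class
#' @export
setMethod("geneIds", "UpstreamSet", function(x) as.character(x@info$gene_id))

#' @rdname UpstreamSet-class
#' @export
setGeneric("upstreamSeqs", function(x) standardGeneric("upstreamSeqs"))

#' @rdname UpstreamSet-class
#' @export
setMethod("upstreamSeqs", "UpstreamSet", function(x) x@seqs)

#' @rdname UpstreamSet-class
#' @export
setGeneric("upstreamInfo", function(x) standardGeneric("upstreamInfo"))

#' @rdname UpstreamSet-class
#' @export
setMethod("upstreamInfo", "UpstreamSet",
          function(x) as.data.frame(x@info, optional = TRUE))

#' @rdname UpstreamSet-class
#' @export
setMethod("length", "UpstreamSet", function(x) length(x@seqs))

#' @rdname UpstreamSet-class
#' @export
setMethod("names", "UpstreamSet", function(x) names(x@seqs))

#' @rdname UpstreamSet-class
#' @param i Index (numeric, logical or gene id).
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "UpstreamSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, geneIds(x))
  methods::initialize(x, seqs = x@seqs[i], info = x@info[i, , drop = FALSE])
})

setMethod("show", "UpstreamSet", function(object) {
  cat(sprintf("UpstreamSet of %d sequence(s), species '%s'\n",
              length(object),
              if (length(object)) object@info$species[1] else "?"))
  if (length(object)) {
    w <- Biostrings::width(object@seqs)
    cat(sprintf("  widths: %d..%d bp\n", min(w), max(w)))
    n <- min(5L, length(object))
    cat("  genes:", paste(utils::head(geneIds(object), n), collapse = ", "),
        if (length(object) > n) "..." else "", "\n")
  }
})

setMethod("show", "SSRThresholds", function(object) {
  cat("SSRThresholds: min repeats",
      paste(sprintf("%s-mer>=%d", names(object@minRepeats),
                    object@minRepeats), collapse = ", "),
      sprintf("; min tract %d bp\n", object@minTractBp))
})

setMethod("show", "CNSParams", function(object) {
  cat(sprintf("CNSParams: seed %d-mer, min length %d bp, min identity %.2f\n",
              object@seedK, object@minLen, object@minIdentity))
})

setMethod("show", "PrimerConstraints", function(object) {
  cat(sprintf(
    "PrimerConstraints: product %d-%d bp, primer %d-%d nt, GC %.2f-%.2f, Tm %.1f-%.1f C\n",
    object@productMin, object@productMax, object@primerMin, object@primerMax,
    object@gcMin, object@gcMax, object@tmMin, object@tmMax))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d true + %d/%d/%d decoy genes, %d bp window, %d comparators (%d supporting), GC %.2f, flank mutation %.2f, seed %d\n",
    object@nTrue, object@nDecoySSR, object@nDecoyTFBS, object@nDecoyUncons,
    object@window, object@nComparators, object@nSupporting,
    object@gcContent, object@mutationRate, object@seed))
})

#' @rdname CNMSResult-class
#' @param x A `CNMSResult`.
#' @export
setGeneric("cnmsMarkers", function(x) standardGeneric("cnmsMarkers"))

#' @rdname CNMSResult-class
#' @export
setMethod("cnmsMarkers", "CNMSResult", function(x) x@markers)

#' @rdname CNMSResult-class
#' @export
setGeneric("cnmsPrimers", function(x) standardGeneric("cnmsPrimers"))

#' @rdname CNMSResult-class
#' @export
setMethod("cnmsPrimers", "CNMSResult", function(x) x@primers)

#' @rdname CNMSResult-class
#' @export
setGeneric("cnmsHistogram", function(x) standardGeneric("cnmsHistogram"))

#' @rdname CNMSResult-class
#' @export
setMethod("cnmsHistogram", "CNMSResult", function(x) x@histogram)

#' @rdname CNMSResult-class
#' @export
setGeneric("cnmsReport", function(x) standardGeneric("cnmsReport"))

#' @rdname CNMSResult-class
#' @export
setMethod("cnmsReport", "CNMSResult", function(x) x@report)

setMethod("show", "CNMSResult", function(object) {
  rep <- object@report
  cat("CNMSResult\n")
  if (!is.null(rep$counts)) {
    cn <- rep$counts
    cat(sprintf("  genes: %d | SSR loci: %d | element hits: %d | CNS blocks: %d\n",
                cn$genes, cn$ssr_loci, cn$tfbs_hits, cn$cns_blocks))
    cat(sprintf("  CNMS markers: %d (class I %d, class II %d) | primer pairs: %d\n",
                cn$markers, cn$class_I, cn$class_II, cn$primer_pairs))
  }
})
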