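# End-to-end discovery: ssr -> scan -> cns -> call -> primers -> summaries.

.asUpstreamSet <- function(x, species) {
  if (methods::is(x, "UpstreamSet")) x
  else readUpstreamFasta(x, species = species)
}

#' Run the full CNMS discovery pipeline
#'
#' Executes SSR mining, element scanning, conserved-block detection over
#' the orthology table, CNMS calling, primer design and the positional /
#' per-element summaries, optionally writing all result tables to
#' `outDir`.  Identical inputs and configuration give byte-identical
#' outputs.
#'
#' @param target Target-species [UpstreamSet-class] or FASTA path.
#' @param comparators Named list (by species) of `UpstreamSet` objects or
#'   FASTA paths.
#' @param orthology Orthology data.frame (`target_gene`,
#'   `comparator_species`, `comparator_gene`) or TSV path.
#' @param elements Element library data.frame or TSV path (default the
#'   bundled five-element library).
#' @param thresholds [SSRThresholds-class].
#' @param cns [CNSParams-class].
#' @param primers [PrimerConstraints-class], or `NULL` to skip primer
#'   design.
#' @param eligibleClasses,minUnitSize,minOverlap Marker-calling options,
#'   see [callCNMS()].
#' @param binWidth Histogram bin width in bp (default 100).
#' @param genomeSizeBp Optional physical span for the marker-density
#'   summary.
#' @param outDir Optional output directory; when given, writes
#'   `markers.tsv`, `markers.gff3`, `histogram.tsv`, `primers.tsv`,
#'   `report.txt`.
#' @param verbose Print stage banners with record counts (default FALSE).
#' @return A [CNMSResult-class].
#' @export
runDiscover <- function(target, comparators, orthology,
                        elements = cnmsElements(),
                        thresholds = ssrThresholds(),
                        cns = cnsParams(),
                        primers = primerConstraints(),
                        eligibleClasses = c("I", "II"),
                        minUnitSize = 2L, minOverlap = 1L,
                        binWidth = 100L, genomeSizeBp = NULL,
                        outDir = NULL, verbose = FALSE) {
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))

  target <- .asUpstreamSet(target, "target")
  if (!is.list(comparators))
    comparators <- list(comparator = comparators)
  comparators <- lapply(comparators, .asUpstreamSet, species = NA)
  for (sp in names(comparators)) {
    info <- comparators[[sp]]@info
    if (all(is.na(info$species)) || all(info$species == "unknown"))
      comparators[[sp]]@info$species <- sp
  }
  if (is.character(orthology)) orthology <- readOrthologyTable(orthology)
  if (is.character(elements)) elements <- readElementLibrary(elements)

  say("stage ssr: %d upstream sequences", length(target))
  ssrs <- findSSRs(target, thresholds)
  say("stage ssr: %d loci", nrow(ssrs))

  hits <- scanElements(target, elements)
  say("stage scan: %d element hits (%d elements)", nrow(hits),
      nrow(elements))

  blockRows <- list()
  lens <- stats::setNames(Biostrings::width(upstreamSeqs(target)),
                          geneIds(target))
  tSeqs <- as.character(upstreamSeqs(target))
  for (i in seq_len(nrow(orthology))) {
    tg <- orthology$target_gene[i]
    sp <- orthology$comparator_species[i]
    cg <- orthology$comparator_gene[i]
    if (!tg %in% geneIds(target))
      .stopf("orthology row %d: unknown target gene %s", i, tg)
    cset <- if (sp %in% names(comparators)) comparators[[sp]]
            else if (identical(sp, upstreamInfo(target)$species[1])) target
            else .stopf("orthology row %d: unknown comparator species %s",
                        i, sp)
    if (!cg %in% geneIds(cset))
      .stopf("orthology row %d: unknown comparator gene %s", i, cg)
    df <- .detectCNSOne(tSeqs[[tg]],
                        as.character(upstreamSeqs(cset[cg]))[[1]], cns)
    if (nrow(df))
      blockRows[[length(blockRows) + 1L]] <-
        cbind(target_gene = tg, comparator_species = sp,
              comparator_gene = cg, df, stringsAsFactors = FALSE)
  }
  blocks <- if (length(blockRows)) do.call(rbind, blockRows)
            else .emptyCNSFrame()
  say("stage cns: %d blocks over %d orthology pairs", nrow(blocks),
      nrow(orthology))

  markers <- callCNMS(ssrs, hits, blocks, genes = geneIds(target),
                      seqLengths = lens, eligibleClasses = eligibleClasses,
                      minUnitSize = minUnitSize, minOverlap = minOverlap)
  say("stage call: %d CNMS markers", nrow(markers))

  primerTab <- if (!is.null(primers) && nrow(markers))
    addPrimers(markers, target, primers)
  else addPrimers(.emptyMarkerFrame(), target)
  say("stage primers: %d pairs designed", nrow(primerTab))

  window <- max(c(1L, Biostrings::width(upstreamSeqs(target))))
  hist <- binPositions(markers, binWidth = binWidth, window = window)

  perElement <- if (nrow(markers)) {
    tab <- table(markers$element)
    data.frame(element = names(tab), n = as.integer(tab),
               pct = surveyPercent(as.integer(tab), nrow(markers)),
               stringsAsFactors = FALSE)
  } else data.frame(element = character(0), n = integer(0), pct = numeric(0))

  report <- list(
    counts = list(genes = length(target), ssr_loci = nrow(ssrs),
                  tfbs_hits = nrow(hits), cns_blocks = nrow(blocks),
                  markers = nrow(markers),
                  class_I = sum(markers$ssr_class == "I"),
                  class_II = sum(markers$ssr_class == "II"),
                  primer_pairs = nrow(primerTab)),
    per_element = perElement,
    density_kb = if (!is.null(genomeSizeBp) && nrow(markers))
      markerDensity(nrow(markers), genomeSizeBp) else NA_real_)

  res <- methods::new("CNMSResult", markers = markers, primers = primerTab,
                      histogram = hist, report = report)
  if (!is.null(outDir)) .writeResult(res, outDir)
  res
}

.writeResult <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outDir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(res@markers, "markers.tsv")
  wt(res@primers, "primers.tsv")
  hist <- res@histogram
  hist$total <- attr(res@histogram, "total")
  wt(hist, "histogram.tsv")
  m <- res@markers
  loci <- data.frame(gene_id = m$gene_id, start = m$comp_start,
                     end = m$comp_end,
                     type = rep("CNMS_marker", nrow(m)), ID = m$marker_id,
                     up_start = m$up_start, up_end = m$up_end,
                     element = m$element, unit = m$unit,
                     stringsAsFactors = FALSE)
  writeLociGFF3(loci, file.path(outDir, "markers.gff3"))
  cn <- res@report$counts
  lines <- c(
    "cnmscan discovery report",
    sprintf("genes\t%d", cn$genes),
    sprintf("ssr_loci\t%d", cn$ssr_loci),
    sprintf("tfbs_hits\t%d", cn$tfbs_hits),
    sprintf("cns_blocks\t%d", cn$cns_blocks),
    sprintf("markers\t%d", cn$markers),
    sprintf("class_I\t%d", cn$class_I),
    sprintf("class_II\t%d", cn$class_II),
    sprintf("primer_pairs\t%d", cn$primer_pairs))
  pe <- res@report$per_element
  if (nrow(pe))
    lines <- c(lines, sprintf("element\t%s\t%d\t%.1f", pe$element, pe$n,
                              pe$pct))
  if (!is.na(res@report$density_kb))
    lines <- c(lines, sprintf("density_kb\t%.1f", res@report$density_kb))
  writeLines(lines, file.path(outDir, "report.txt"))
  invisible(outDir)
}
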