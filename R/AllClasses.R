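# S4 classes shared across the package.

#' @import methods
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

#' UpstreamSet: a set of 5' upstream gene regions
#'
#' Holds one species' upstream sequences (each written 5'->3' with its last
#' base immediately adjacent to the translation start codon ATG) together
#' with per-gene annotation: chromosome, strand and the 1-based genomic
#' coordinate of the A of ATG.  Sequences are stored on the coding-strand
#' orientation; all string coordinates used by the package are 1-based
#' inclusive positions on these stored strings.
#'
#' @slot seqs A [Biostrings::DNAStringSet] named by gene id.
#' @slot info A [S4Vectors::DataFrame] with columns `gene_id`, `species`,
#'   `chromosome`, `strand` (`+`, `-` or `*` when unknown) and `atg_pos`
#'   (genomic position of the A of ATG; `NA` when unknown), one row per
#'   sequence, in the same order as `seqs`.
#'
#' @seealso [readUpstreamFasta()], [UpstreamSet()]
#' @export
setClass("UpstreamSet",
  slots = c(seqs = "DNAStringSet", info = "DataFrame"))

setValidity("UpstreamSet", function(object) {
  msgs <- character(0)
  if (length(object@seqs) != nrow(object@info))
    msgs <- c(msgs, "seqs and info must have the same length")
  if (!all(c("gene_id", "species", "chromosome", "strand", "atg_pos") %in%
           colnames(object@info)))
    msgs <- c(msgs, "info must have columns gene_id, species, chromosome, strand, atg_pos")
  else {
    if (!identical(names(object@seqs), as.character(object@info$gene_id)))
      msgs <- c(msgs, "names(seqs) must equal info$gene_id")
    if (anyDuplicated(object@info$gene_id))
      msgs <- c(msgs, "duplicate gene_id")
    if (!all(object@info$strand %in% c("+", "-", "*")))
      msgs <- c(msgs, "strand must be '+', '-' or '*'")
  }
  if (length(object@seqs)) {
    if (any(Biostrings::width(object@seqs) == 0L))
      msgs <- c(msgs, "zero-length sequence")
    freq <- Biostrings::alphabetFrequency(object@seqs, baseOnly = FALSE)
    allowed <- c("A", "C", "G", "T", "N")
    if (any(rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE]) > 0))
      msgs <- c(msgs, "sequences must use only A, C, G, T, N")
  }
  if (length(msgs)) msgs else TRUE
})

#' SSRThresholds: search thresholds for SSR mining
#'
#' Minimum repeat counts by unit size and a minimum tract length in bp.
#' Both filters are applied independently: a tract qualifies only if its
#' complete-unit repeat count meets `minRepeats[unit_size]` *and* its
#' length in bp meets `minTractBp`.
#'
#' The defaults (10/6/4/3/3/3 repeats for unit sizes 1-6, 12 bp tract) are
#' chosen so every repeat class reported for validated chickpea CNMS
#' markers — down to (AG)6, (TTCT)3, (ATGGT)3, (AAG)4 — is discoverable;
#' classic MISA defaults would miss several of them.
#'
#' @slot minRepeats Named integer vector of length 6 (names "1".."6").
#' @slot minTractBp Single integer, minimum tract length in bp.
#' @seealso [ssrThresholds()], [findSSRs()]
#' @export
setClass("SSRThresholds",
  slots = c(minRepeats = "integer", minTractBp = "integer"))

setValidity("SSRThresholds", function(object) {
  msgs <- character(0)
  if (length(object@minRepeats) != 6L ||
      !identical(names(object@minRepeats), as.character(1:6)))
    msgs <- c(msgs, "minRepeats must be a length-6 integer vector named '1'..'6'")
  else if (any(object@minRepeats < 2L))
    msgs <- c(msgs, "all minimum repeat counts must be >= 2")
  if (length(object@minTractBp) != 1L || is.na(object@minTractBp) ||
      object@minTractBp < 1L)
    msgs <- c(msgs, "minTractBp must be a single positive integer")
  if (length(msgs)) msgs else TRUE
})

#' CNSParams: parameters of the conserved non-coding block detector
#'
#' @slot seedK Exact-match seed length (bp).
#' @slot minLen Minimum reported block length (bp).
#' @slot minIdentity Minimum block identity, in (0.5, 1].
#' @seealso [cnsParams()], [detectCNS()]
#' @export
setClass("CNSParams",
  slots = c(seedK = "integer", minLen = "integer", minIdentity = "numeric"))

setValidity("CNSParams", function(object) {
  msgs <- character(0)
  if (object@seedK < 1L) msgs <- c(msgs, "seedK must be >= 1")
  if (object@seedK > object@minLen)
    msgs <- c(msgs, "seedK must be <= minLen")
  if (!(object@minIdentity > 0.5 && object@minIdentity <= 1))
    msgs <- c(msgs, "minIdentity must be in (0.5, 1]")
  if (length(msgs)) msgs else TRUE
})

#' PrimerConstraints: hard constraints for flanking primer design
#'
#' Amplification products must span the marker locus and fall within
#' `[productMin, productMax]` bp; each primer must satisfy length, GC
#' fraction, melting-temperature and 3'-end self-complementarity limits,
#' occur exactly once in the template, and not overlap the SSR tract.
#'
#' @slot productMin,productMax Product size window (bp), default 100-300.
#' @slot primerMin,primerMax Primer length window (nt), default 18-24.
#' @slot gcMin,gcMax GC fraction window, default 0.40-0.60.
#' @slot tmMin,tmMax Melting temperature window (deg C), default 50-62.
#' @slot maxEndSelfComp Maximum 3'-end self-complementarity (nt), default 4.
#' @slot requireUnique Require each primer sequence to occur exactly once
#'   in the template (logical, default TRUE).
#' @seealso [primerConstraints()], [designPrimers()]
#' @export
setClass("PrimerConstraints",
  slots = c(productMin = "integer", productMax = "integer",
            primerMin = "integer", primerMax = "integer",
            gcMin = "numeric", gcMax = "numeric",
            tmMin = "numeric", tmMax = "numeric",
            maxEndSelfComp = "integer", requireUnique = "logical"))

setValidity("PrimerConstraints", function(object) {
  msgs <- character(0)
  if (object@productMin >= object@productMax)
    msgs <- c(msgs, "productMin must be < productMax")
  if (object@primerMin > object@primerMax || object@primerMin < 10L)
    msgs <- c(msgs, "primer length window invalid (need 10 <= min <= max)")
  if (object@gcMin > object@gcMax || object@gcMin < 0 || object@gcMax > 1)
    msgs <- c(msgs, "GC window invalid")
  if (object@tmMin > object@tmMax) msgs <- c(msgs, "Tm window invalid")
  if (object@maxEndSelfComp < 0L)
    msgs <- c(msgs, "maxEndSelfComp must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: configuration of the synthetic upstream-set generator
#'
#' Describes a multi-species simulated input bundle: a target species with
#' planted SSR+element composites and decoys, plus comparator species
#' carrying (mutated-flank) copies of the conserved windows.  Decoys come
#' in the three failure modes of the CNMS predicate: SSR without element
#' overlap, element without SSR, and composite without conservation.
#'
#' @slot nTrue Number of genes with a fully qualifying planted composite.
#' @slot nDecoySSR Number of SSR-only decoy genes (conserved, no element).
#' @slot nDecoyTFBS Number of element-only decoy genes (conserved, no SSR).
#' @slot nDecoyUncons Number of unconserved-composite decoy genes.
#' @slot window Upstream window length (bp), default 1000.
#' @slot nComparators Number of comparator species, default 6.
#' @slot nSupporting Comparator species carrying the conserved copy,
#'   default 3 (must be <= nComparators).
#' @slot gcContent Background GC fraction, default 0.38 (AT-rich plant
#'   promoter composition).
#' @slot mutationRate Point-substitution rate applied to the copied
#'   conserved-window flanks in comparators (never inside the composite
#'   core), default 0.10; must stay below 1 - minIdentity of the intended
#'   conservation parameters.
#' @slot flank Conserved-window flank copied around the composite (bp),
#'   default 30.
#' @slot seed Integer RNG seed.
#' @seealso [simConfig()], [simulateUpstreamSet()]
#' @export
setClass("SimConfig",
  slots = c(nTrue = "integer", nDecoySSR = "integer", nDecoyTFBS = "integer",
            nDecoyUncons = "integer", window = "integer",
            nComparators = "integer", nSupporting = "integer",
            gcContent = "numeric", mutationRate = "numeric",
            flank = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nTrue + object@nDecoySSR + object@nDecoyTFBS +
      object@nDecoyUncons < 1L)
    msgs <- c(msgs, "at least one gene must be simulated")
  if (object@nSupporting > object@nComparators)
    msgs <- c(msgs, "nSupporting must be <= nComparators")
  if (object@nSupporting < 1L)
    msgs <- c(msgs, "nSupporting must be >= 1")
  if (object@gcContent <= 0 || object@gcContent >= 1)
    msgs <- c(msgs, "gcContent must be in (0, 1)")
  if (object@mutationRate < 0 || object@mutationRate >= 0.3)
    msgs <- c(msgs, "mutationRate must be in [0, 0.3) so conserved copies stay above the default identity floor")
  if (object@window < 2L * object@flank + 60L)
    msgs <- c(msgs, "window too small for the planted features")
  if (length(msgs)) msgs else TRUE
})

#' CNMSResult: the output of a full discovery run
#'
#' @slot markers Marker table (one row per CNMS marker).
#' @slot primers Primer table (one row per marker with a designed pair).
#' @slot histogram Positional histogram of marker midpoints in ATG-relative
#'   coordinates.
#' @slot report Named list of stage record counts and summary tables.
#' @seealso [runDiscover()]
#' @export
setClass("CNMSResult",
  slots = c(markers = "data.frame", primers = "data.frame",
            histogram = "data.frame", report = "list"))
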