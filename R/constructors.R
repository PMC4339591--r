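# User-facing constructors for the parameter classes.

#' Construct an UpstreamSet
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] of upstream
#'   sequences (5'->3', last base adjacent to ATG).
#' @param geneId Character vector of gene ids (defaults to `names(seqs)`).
#' @param species Single species tag.
#' @param chromosome,strand,atgPos Optional per-gene annotation; recycled
#'   defaults are `NA`, `"*"`, `NA`.
#' @return An [UpstreamSet-class] object.
#' @examples
#' u <- UpstreamSet(c(g1 = "ACGTACGT"), species = "cicer")
#' geneIds(u)
#' @export
UpstreamSet <- function(seqs, geneId = names(seqs), species = "unknown",
                        chromosome = NA_character_, strand = "*",
                        atgPos = NA_integer_) {
  if (is.character(seqs)) {
    seqs <- toupper(chartr("Uu", "Tt", seqs))
    for (i in seq_along(seqs)) {
      bad <- .badBases(seqs[[i]])
      if (length(bad))
        .stopf("sequence %s contains disallowed characters: %s",
               if (is.null(geneId)) i else geneId[i],
               paste(bad, collapse = ", "))
    }
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (is.null(geneId)) .stopf("gene ids are required (name the sequences)")
  n <- length(seqs)
  info <- S4Vectors::DataFrame(
    gene_id = as.character(geneId),
    species = rep_len(as.character(species), n),
    chromosome = rep_len(as.character(chromosome), n),
    strand = rep_len(as.character(strand), n),
    atg_pos = rep_len(as.integer(atgPos), n))
  names(seqs) <- info$gene_id
  methods::new("UpstreamSet", seqs = seqs, info = info)
}

#' SSR search thresholds
#'
#' @param minRepeats Named numeric/integer vector of minimum repeat counts
#'   for unit sizes 1-6 (names "1".."6").
#' @param minTractBp Minimum tract length in bp.
#' @return An [SSRThresholds-class] object.
#' @examples
#' ssrThresholds()                         # defaults
#' ssrThresholds(minRepeats = c(`1` = 10, `2` = 5, `3` = 4, `4` = 3,
#'                              `5` = 3, `6` = 3), minTractBp = 10)
#' @export
ssrThresholds <- function(minRepeats = c(`1` = 10, `2` = 6, `3` = 4,
                                         `4` = 3, `5` = 3, `6` = 3),
                          minTractBp = 12) {
  mr <- as.integer(minRepeats)
  names(mr) <- names(minRepeats)
  methods::new("SSRThresholds", minRepeats = mr,
               minTractBp = as.integer(minTractBp))
}

#' Conserved-block detection parameters
#'
#' @param seedK Exact seed length (default 8).
#' @param minLen Minimum block length in bp (default 20).
#' @param minIdentity Minimum block identity fraction (default 0.70).
#' @return A [CNSParams-class] object.
#' @export
cnsParams <- function(seedK = 8, minLen = 20, minIdentity = 0.70) {
  methods::new("CNSParams", seedK = as.integer(seedK),
               minLen = as.integer(minLen),
               minIdentity = as.numeric(minIdentity))
}

#' Primer design constraints
#'
#' @param productMin,productMax Amplicon size window in bp (default 100-300).
#' @param primerMin,primerMax Primer length window in nt (default 18-24).
#' @param gcMin,gcMax GC fraction window (default 0.40-0.60).
#' @param tmMin,tmMax Melting temperature window in deg C (default 50-62).
#' @param maxEndSelfComp Maximum allowed 3'-end self-complementarity in nt
#'   (default 4).
#' @param requireUnique Require each primer to occur exactly once in the
#'   template (default TRUE).
#' @return A [PrimerConstraints-class] object.
#' @export
primerConstraints <- function(productMin = 100, productMax = 300,
                              primerMin = 18, primerMax = 24,
                              gcMin = 0.40, gcMax = 0.60,
                              tmMin = 50, tmMax = 62,
                              maxEndSelfComp = 4, requireUnique = TRUE) {
  methods::new("PrimerConstraints",
               productMin = as.integer(productMin),
               productMax = as.integer(productMax),
               primerMin = as.integer(primerMin),
               primerMax = as.integer(primerMax),
               gcMin = as.numeric(gcMin), gcMax = as.numeric(gcMax),
               tmMin = as.numeric(tmMin), tmMax = as.numeric(tmMax),
               maxEndSelfComp = as.integer(maxEndSelfComp),
               requireUnique = isTRUE(requireUnique))
}

#' Synthetic upstream-set configuration
#'
#' Defaults emulate the study conditions the package is designed around:
#' 1000-bp upstream windows, six comparator species, AT-rich (GC 0.38)
#' promoter background, conserved copies supported by three comparators
#' with 10% point substitution in the copied flanks.
#'
#' @param nTrue,nDecoySSR,nDecoyTFBS,nDecoyUncons Gene counts per planted
#'   category (defaults 5, 2, 1, 2).
#' @param window Upstream window length in bp (default 1000).
#' @param nComparators Number of comparator species (default 6).
#' @param nSupporting Comparators carrying each conserved copy (default 3).
#' @param gcContent Background GC fraction (default 0.38).
#' @param mutationRate Substitution rate on copied flanks (default 0.10).
#' @param flank Conserved-window flank around the composite in bp
#'   (default 30).
#' @param seed RNG seed (default 1).
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nTrue = 5, nDecoySSR = 2, nDecoyTFBS = 1,
                      nDecoyUncons = 2, window = 1000, nComparators = 6,
                      nSupporting = 3, gcContent = 0.38,
                      mutationRate = 0.10, flank = 30, seed = 1) {
  methods::new("SimConfig",
               nTrue = as.integer(nTrue), nDecoySSR = as.integer(nDecoySSR),
               nDecoyTFBS = as.integer(nDecoyTFBS),
               nDecoyUncons = as.integer(nDecoyUncons),
               window = as.integer(window),
               nComparators = as.integer(nComparators),
               nSupporting = as.integer(nSupporting),
               gcContent = as.numeric(gcContent),
               mutationRate = as.numeric(mutationRate),
               flank = as.integer(flank), seed = as.integer(seed))
}
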