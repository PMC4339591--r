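# Seeded generator of multi-species upstream bundles with planted
# SSR/element/conservation composites and per-clause decoys.
#
# The generator *constructs* the guarantees its truth table states:
#   * planted tracts cannot extend into the background (repeat-breaking
#     bases are placed at both tract edges);
#   * conserved copies keep the composite core exact and mutate only the
#     copied flanks, so containment of the composite in a detected block
#     is certain whenever mutationRate < 1 - minIdentity;
#   * comparators that must NOT support a locus are redrawn until they
#     share no seed k-mer with the composite neighbourhood, so no seed
#     can anchor an accidental supporting block;
#   * target backgrounds are redrawn until the neighbourhood of each
#     planted feature is free of accidental SSR/element co-occurrences
#     that would blur the planted truth.

## Composite catalogue: each element's signal occurs inside the expansion
## of the paired repeat unit.
.SIM_CATALOG <- data.frame(
  element = c("GAGA8HVBKN3", "CTRMCAMV35S", "RAV1AAT",
              "S1FBOXSORPS1L21", "CANBNNAPA"),
  unit = c("GA", "CT", "CAA", "ATGGT", "ACACAA"),
  count = c(12L, 8L, 7L, 3L, 4L),
  stringsAsFactors = FALSE)

## Concrete (N-free) signal instances plantable without creating an SSR.
.SIM_TFBS_ONLY <- c("CAACA", "ATGGTA", "CTAACAC")

.randSeq <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.kmerSet <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  unique(substring(s, seq_len(L - k + 1L), seq.int(k, L)))
}

## Replace [at] in s with a base different from `avoid` (and from N).
.breakBase <- function(s, at, avoid) {
  if (at < 1L || at > nchar(s)) return(s)
  pick <- setdiff(c("A", "C", "G", "T"), avoid)[1]
  paste0(substr(s, 1L, at - 1L), pick, substr(s, at + 1L, nchar(s)))
}

.mutateFlanks <- function(copy, coreLo, coreHi, rate) {
  if (rate <= 0) return(copy)
  v <- strsplit(copy, "", fixed = TRUE)[[1]]
  flankIdx <- setdiff(seq_along(v), coreLo:coreHi)
  hit <- flankIdx[stats::runif(length(flankIdx)) < rate]
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

## Sanity screen of one target gene draw; returns NULL on failure or the
## comma-separated expected element list (for composite kinds).
.screenTargetGene <- function(seq, kind, p, coreLen, flank, elements,
                              thresholds, window) {
  tractLo <- p; tractHi <- p + coreLen - 1L
  wLo <- max(1L, p - flank); wHi <- min(window, tractHi + flank)
  ssrs <- findSSRs(seq, thresholds)
  eligible <- ssrs[ssrs$ssr_class %in% c("I", "II") & ssrs$unit_size >= 2L, ,
                   drop = FALSE]
  hits <- scanElements(seq, elements)
  overlaps <- function(a1, a2, b1, b2) pmin(a2, b2) - pmax(a1, b1) + 1L >= 1L
  if (kind %in% c("true", "unconserved", "ssr_only")) {
    if (!any(ssrs$start == tractLo & ssrs$end == tractHi)) return(NULL)
  }
  if (kind %in% c("true", "unconserved")) {
    tractHits <- hits[overlaps(hits$start, hits$end, tractLo, tractHi), ,
                      drop = FALSE]
    if (nrow(tractHits) == 0L) return(NULL)
    ## keep the composite equal to the tract: overlapping hits must nest
    if (any(tractHits$start < tractLo | tractHits$end > tractHi))
      return(NULL)
    expected <- sort(unique(tractHits$element))
  } else if (kind == "ssr_only") {
    if (any(overlaps(hits$start, hits$end, tractLo, tractHi))) return(NULL)
    expected <- character(0)
  } else {  # tfbs_only: planted signal, no SSR may touch any hit in window
    if (!any(hits$start == tractLo & hits$end == tractHi)) return(NULL)
    expected <- character(0)
  }
  ## inside the conserved window, no *other* eligible SSR may touch an
  ## element hit (it would be a conserved composite the truth table does
  ## not know about)
  winHits <- hits[hits$start <= wHi & hits$end >= wLo, , drop = FALSE]
  other <- eligible[!(eligible$start == tractLo & eligible$end == tractHi), ,
                    drop = FALSE]
  if (nrow(other) && nrow(winHits)) {
    for (i in seq_len(nrow(other)))
      if (any(overlaps(other$start[i], other$end[i],
                       winHits$start, winHits$end)))
        return(NULL)
  }
  paste(expected, collapse = ",")
}

#' Simulate a multi-species upstream bundle with planted truth
#'
#' Generates a target-species upstream set carrying planted
#' SSR+element composites and decoys, comparator-species upstream sets in
#' which a chosen subset of species carries a (flank-mutated) copy of
#' each conserved window, an orthology table, the bundled element
#' library, and a truth table describing exactly which genes must yield
#' CNMS markers.  Deterministic under `config@seed`.
#'
#' @param config A [SimConfig-class] from [simConfig()].
#' @param elements Element library (default the bundled five-element
#'   library, [cnmsElements()]).
#' @param thresholds [SSRThresholds-class] the downstream run will use
#'   (the generator keeps planted-feature neighbourhoods clean with
#'   respect to these thresholds).
#' @return A list with components `target` ([UpstreamSet-class]),
#'   `comparators` (named list of `UpstreamSet`), `orthology`
#'   (data.frame), `elements` (data.frame), `truth` (data.frame with one
#'   row per gene: `gene_id`, `kind`, `element`, `expected_elements`,
#'   `unit`, `repeat_count`, `tract_start`, `tract_end`, `up_start`,
#'   `up_end`, `expected_marker`, `supporting_species`) and `config`.
#' @export
simulateUpstreamSet <- function(config = simConfig(),
                                elements = cnmsElements(),
                                thresholds = ssrThresholds()) {
  stopifnot(methods::is(config, "SimConfig"))
  set.seed(config@seed)
  window <- config@window; flank <- config@flank
  kinds <- c(rep("true", config@nTrue),
             rep("ssr_only", config@nDecoySSR),
             rep("tfbs_only", config@nDecoyTFBS),
             rep("unconserved", config@nDecoyUncons))
  nGenes <- length(kinds)
  compSpecies <- sprintf("comp%d", seq_len(config@nComparators))
  geneIdsV <- sprintf("g%03d", seq_len(nGenes))

  targetSeqs <- character(nGenes)
  compSeqs <- matrix(NA_character_, nrow = config@nComparators,
                     ncol = nGenes, dimnames = list(compSpecies, geneIdsV))
  truthRows <- list()
  ctTrue <- ctT <- 0L

  for (gi in seq_len(nGenes)) {
    kind <- kinds[gi]
    if (kind %in% c("true", "unconserved")) {
      ctTrue <- ctTrue + 1L
      cat_row <- .SIM_CATALOG[(ctTrue - 1L) %% nrow(.SIM_CATALOG) + 1L, ]
      core <- strrep(cat_row$unit, cat_row$count)
      unit <- cat_row$unit; cnt <- cat_row$count
      intended <- cat_row$element
    } else if (kind == "ssr_only") {
      core <- strrep("AT", 8L); unit <- "AT"; cnt <- 8L
      intended <- NA_character_
    } else {
      ctT <- ctT + 1L
      core <- .SIM_TFBS_ONLY[(ctT - 1L) %% length(.SIM_TFBS_ONLY) + 1L]
      unit <- NA_character_; cnt <- NA_integer_
      intended <- c("RAV1AAT", "S1FBOXSORPS1L21",
                    "CANBNNAPA")[(ctT - 1L) %% 3L + 1L]
    }
    coreLen <- nchar(core)
    if (coreLen + 2L * flank + 2L > window)
      .stopf("planted feature (%d bp + flanks) does not fit the %d bp window",
             coreLen, window)
    p <- sample(seq.int(flank + 2L, window - flank - coreLen), 1L)

    expected <- NULL
    for (try in seq_len(200L)) {
      s <- .randSeq(window, config@gcContent)
      substr(s, p, p + coreLen - 1L) <- core
      if (!is.na(unit)) {
        u <- nchar(unit)
        s <- .breakBase(s, p - 1L, substr(s, p - 1L + u, p - 1L + u))
        s <- .breakBase(s, p + coreLen,
                        substr(s, p + coreLen - u, p + coreLen - u))
        ## breaking can desynchronise only outside the tract; re-plant to
        ## be safe against edge effects
        substr(s, p, p + coreLen - 1L) <- core
      }
      expected <- .screenTargetGene(s, kind, p, coreLen, flank, elements,
                                    thresholds, window)
      if (!is.null(expected)) break
    }
    if (is.null(expected))
      .stopf("could not generate a clean background for gene %s", geneIdsV[gi])
    targetSeqs[gi] <- s

    conserved <- kind != "unconserved"
    supp <- if (conserved)
      sort(sample(seq_len(config@nComparators), config@nSupporting))
    else integer(0)
    wLo <- max(1L, p - flank)
    wHi <- min(window, p + coreLen - 1L + flank)
    copyStr <- substr(s, wLo, wHi)
    nbh <- substr(s, max(1L, wLo - 10L), min(window, wHi + 10L))
    nbhKmers <- .kmerSet(nbh, 8L)

    for (ci in seq_len(config@nComparators)) {
      if (ci %in% supp) {
        cseq <- .randSeq(window, config@gcContent)
        mutated <- .mutateFlanks(copyStr, p - wLo + 1L,
                                 p - wLo + coreLen, config@mutationRate)
        substr(cseq, wLo, wHi) <- mutated
      } else {
        for (try in seq_len(100L)) {
          cseq <- .randSeq(window, config@gcContent)
          if (!any(.kmerSet(cseq, 8L) %in% nbhKmers)) break
          cseq <- NULL
        }
        if (is.null(cseq))
          .stopf("could not draw a seed-free comparator background for %s",
                 geneIdsV[gi])
      }
      compSeqs[ci, gi] <- cseq
    }

    up <- toUpstreamFrame(p, p + coreLen - 1L, window)
    truthRows[[gi]] <- data.frame(
      gene_id = geneIdsV[gi], kind = kind, element = intended,
      expected_elements = if (nzchar(expected)) expected else NA_character_,
      unit = unit, repeat_count = cnt,
      tract_start = p, tract_end = p + coreLen - 1L,
      up_start = up$start_up, up_end = up$end_up,
      expected_marker = kind == "true",
      supporting_species = paste(compSpecies[supp], collapse = ","),
      stringsAsFactors = FALSE)
  }

  target <- UpstreamSet(stats::setNames(targetSeqs, geneIdsV),
                        species = "target", chromosome = "Chr1",
                        strand = "+",
                        atgPos = 50000L * seq_len(nGenes))
  comparators <- lapply(compSpecies, function(sp) {
    ids <- paste0(sp, "_", geneIdsV)
    UpstreamSet(stats::setNames(compSeqs[sp, ], ids), species = sp)
  })
  names(comparators) <- compSpecies
  orthology <- do.call(rbind, lapply(compSpecies, function(sp) {
    data.frame(target_gene = geneIdsV, comparator_species = sp,
               comparator_gene = paste0(sp, "_", geneIdsV),
               stringsAsFactors = FALSE)
  }))
  orthology <- orthology[order(orthology$target_gene,
                               orthology$comparator_species), ]
  rownames(orthology) <- NULL
  list(target = target, comparators = comparators, orthology = orthology,
       elements = elements, truth = do.call(rbind, truthRows),
       config = config)
}

#' Write a simulated bundle to disk
#'
#' Emits `target.fa`, one `comp_<species>.fa` per comparator,
#' `orthology.tsv`, `elements.tsv`, `truth.tsv` and `truth.bed`
#' (0-based half-open tract coordinates).  Byte-identical across runs
#' with the same bundle.
#'
#' @param sim Bundle from [simulateUpstreamSet()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSimBundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeUpstreamFasta(sim$target, file.path(dir, "target.fa"))
  for (sp in names(sim$comparators))
    writeUpstreamFasta(sim$comparators[[sp]],
                       file.path(dir, paste0("comp_", sp, ".fa")))
  utils::write.table(sim$orthology, file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$elements, file.path(dir, "elements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(chrom = sim$truth$gene_id,
                    start = sim$truth$tract_start - 1L,
                    end = sim$truth$tract_end,
                    name = paste0(sim$truth$kind, "_", sim$truth$gene_id))
  utils::write.table(bed, file.path(dir, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Simulate a genotype matrix with group-specific allele series
#'
#' Individuals are assigned to groups of the given sizes; each marker
#' draws every individual's allele uniformly from that group's allele
#' set (homozygous inbred lines: one call per individual).  Missing
#' entries are then injected at `missingRate`.  Deterministic under
#' `seed`.
#'
#' @param markers Named list; each element is a list of per-group allele
#'   vectors (length equal to `length(groupSizes)`).  A group fixed for
#'   one allele gets a length-1 vector.
#' @param groupSizes Named integer vector of group sizes.
#' @param missingRate Fraction of cells set to `NA` (default 0).
#' @param seed RNG seed.
#' @return List with `matrix` (marker x individual), `groups`
#'   (per-individual labels) and `truth` (the input allele series).
#' @export
simulateGenotypes <- function(markers, groupSizes, missingRate = 0,
                              seed = 1) {
  set.seed(as.integer(seed))
  stopifnot(missingRate >= 0, missingRate < 1)
  groups <- rep(names(groupSizes), groupSizes)
  n <- length(groups)
  inds <- sprintf("ind%03d", seq_len(n))
  mat <- matrix(NA, nrow = length(markers), ncol = n,
                dimnames = list(names(markers), inds))
  for (mi in seq_along(markers)) {
    series <- markers[[mi]]
    stopifnot(length(series) == length(groupSizes))
    for (g in seq_along(groupSizes)) {
      idx <- which(groups == names(groupSizes)[g])
      pool <- series[[g]]
      mat[mi, idx] <- if (length(pool) == 1L) pool
                      else sample(pool, length(idx), replace = TRUE)
    }
  }
  if (missingRate > 0) {
    drop <- stats::runif(length(mat)) < missingRate
    mat[drop] <- NA
  }
  list(matrix = mat, groups = stats::setNames(groups, inds),
       truth = markers)
}
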