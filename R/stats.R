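# Marker informativeness and survey statistics.

#' Allele frequencies for one marker
#'
#' Frequencies over non-missing calls; missing calls are excluded from
#' the denominator.
#'
#' @param calls Vector of allele codes (fragment sizes in bp); `NA` marks
#'   missing.
#' @param marker Optional marker name used in error messages.
#' @return Named numeric vector of frequencies summing to 1.
#' @examples
#' alleleFrequencies(c(150, 150, 156, 156))
#' @export
alleleFrequencies <- function(calls, marker = "marker") {
  calls <- calls[!is.na(calls)]
  if (!length(calls))
    .stopf("all calls missing for %s", marker)
  tab <- table(calls)
  freqs <- as.numeric(tab) / sum(tab)
  names(freqs) <- names(tab)
  freqs
}

#' Polymorphism information content (PIC)
#'
#' Botstein's definition, as implemented by PowerMarker:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2}
#' A monomorphic marker has PIC 0.
#'
#' @param freqs Numeric vector of allele frequencies (must sum to 1
#'   within 1e-9; all > 0), e.g. from [alleleFrequencies()].
#' @return PIC value in `[0, 1)`.
#' @examples
#' pic(c(0.5, 0.5))          # 0.375
#' pic(rep(0.25, 4))         # 0.703125
#' @export
pic <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (any(is.na(freqs)) || any(freqs <= 0))
    .stopf("allele frequencies must be positive")
  if (abs(sum(freqs) - 1) > 1e-9)
    .stopf("allele frequencies must sum to 1 (got %.12f)", sum(freqs))
  s2 <- sum(freqs^2)
  ## sum_{i<j} 2 p_i^2 p_j^2 == (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(freqs^4))
}

#' Survey percentage
#'
#' `100 * numerator / denominator`, rounded half-up to `decimals` places.
#'
#' @param numerator,denominator Counts, `0 <= numerator <= denominator`,
#'   `denominator > 0`.
#' @param decimals Decimal places (default 1).
#' @return Percentage.
#' @examples
#' surveyPercent(256, 631)   # 40.6
#' surveyPercent(631, 666)   # 94.7
#' @export
surveyPercent <- function(numerator, denominator, decimals = 1) {
  numerator <- as.numeric(numerator); denominator <- as.numeric(denominator)
  if (any(is.na(denominator)) || any(denominator <= 0))
    .stopf("denominator must be positive")
  if (any(is.na(numerator)) || any(numerator < 0) ||
      any(numerator > denominator))
    .stopf("numerator must satisfy 0 <= numerator <= denominator")
  roundHalfUp(100 * numerator / denominator, decimals)
}

#' Summarize a linkage map table
#'
#' Adds the average intermarker distance per linkage group —
#' `map_length / n_markers`, rounded half-up to two decimals — and a
#' `Total` row whose spacing is `sum(length) / sum(markers)`.  The
#' `length/n` convention (rather than `length/(n-1)`) matches how such
#' transcript-map totals are conventionally reported.
#'
#' @param map data.frame with columns `linkage_group`, `n_markers`,
#'   `map_length_cM`.
#' @return The input with an `avg_spacing_cM` column and an appended
#'   `Total` row.
#' @examples
#' summarizeMap(data.frame(linkage_group = "LG1", n_markers = 27,
#'                         map_length_cM = 124.3))
#' @export
summarizeMap <- function(map) {
  required <- c("linkage_group", "n_markers", "map_length_cM")
  if (!all(required %in% names(map)))
    .stopf("map table must have columns: %s", paste(required, collapse = ", "))
  if (any(map$n_markers < 1L))
    .stopf("every linkage group needs at least one marker")
  if (any(map$map_length_cM < 0))
    .stopf("map lengths must be non-negative")
  out <- map[, required]
  out$avg_spacing_cM <- roundHalfUp(out$map_length_cM / out$n_markers, 2)
  total <- data.frame(
    linkage_group = "Total",
    n_markers = sum(out$n_markers),
    map_length_cM = sum(out$map_length_cM),
    avg_spacing_cM = roundHalfUp(sum(out$map_length_cM) / sum(out$n_markers), 2))
  rbind(out, total)
}

#' Read a genotype matrix
#'
#' Tab-separated, rows = markers (first column marker id), columns =
#' individuals; empty cells, `NA` or `-` mark missing calls.
#'
#' @param path TSV path.
#' @return Numeric matrix, markers x individuals.
#' @export
readGenotypeMatrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "-", ""))
  as.matrix(df)
}

#' Per-marker polymorphism flags and allele counts
#'
#' A marker is polymorphic iff it has at least two distinct non-missing
#' alleles.  With group labels, also reports whether the marker is
#' polymorphic *within* some group (two alleles inside one group) and
#' *between* groups (group allele sets differ).
#'
#' @param mat Marker x individual matrix of allele codes (`NA` missing).
#' @param groups Optional character/factor vector of per-individual group
#'   labels (length `ncol(mat)`).
#' @return data.frame with columns `marker`, `n_alleles`, `polymorphic`
#'   and, when `groups` is given, `within_group_polymorphic` and
#'   `between_group_polymorphic`.
#' @export
polymorphicFlags <- function(mat, groups = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, ncol(mat) >= 2L)
  markers <- rownames(mat)
  if (is.null(markers)) markers <- sprintf("m%d", seq_len(nrow(mat)))
  nAll <- apply(mat, 1, function(r) length(unique(r[!is.na(r)])))
  out <- data.frame(marker = markers, n_alleles = as.integer(nAll),
                    polymorphic = nAll >= 2L, stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    stopifnot(length(groups) == ncol(mat))
    groups <- as.character(groups)
    within <- between <- logical(nrow(mat))
    for (i in seq_len(nrow(mat))) {
      sets <- lapply(split(mat[i, ], groups),
                     function(v) sort(unique(v[!is.na(v)])))
      sets <- sets[vapply(sets, length, integer(1)) > 0]
      within[i] <- any(vapply(sets, length, integer(1)) >= 2L)
      between[i] <- length(sets) >= 2L &&
        length(unique(vapply(sets, paste, character(1), collapse = "/"))) > 1L
    }
    out$within_group_polymorphic <- within
    out$between_group_polymorphic <- between
  }
  rownames(out) <- NULL
  out
}

#' Constitute haplotypes across the markers of one gene
#'
#' For homozygous (inbred) lines: the haplotype of an individual is the
#' ordered tuple of its allele codes across the gene's markers.  Distinct
#' tuples are enumerated with their member counts.  Heterozygous calls
#' (written `a/b`) are an error; individuals with missing calls are
#' dropped with a warning.
#'
#' @param mat Marker x individual matrix (rows ordered along the gene).
#' @return List with `haplotypes` (data.frame `haplotype`, `n`, sorted by
#'   decreasing `n` then haplotype) and `assignments` (named character
#'   vector, individual -> haplotype).
#' @export
constituteHaplotypes <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  if (is.character(mat) && any(grepl("/", mat, fixed = TRUE), na.rm = TRUE))
    .stopf("heterozygous call found; haplotypes require homozygous lines")
  inds <- colnames(mat)
  if (is.null(inds)) inds <- sprintf("ind%d", seq_len(ncol(mat)))
  complete <- colSums(is.na(mat)) == 0L
  if (!all(complete)) {
    warning(sprintf("dropping %d individual(s) with missing calls",
                    sum(!complete)))
    mat <- mat[, complete, drop = FALSE]
    inds <- inds[complete]
  }
  if (ncol(mat) == 0L)
    return(list(haplotypes = data.frame(haplotype = character(0),
                                        n = integer(0)),
                assignments = stats::setNames(character(0), character(0))))
  hap <- apply(mat, 2, paste, collapse = "-")
  tab <- table(hap)
  df <- data.frame(haplotype = names(tab), n = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$n, df$haplotype), , drop = FALSE]
  rownames(df) <- NULL
  list(haplotypes = df, assignments = stats::setNames(hap, inds))
}
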