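# Regulatory-element signal-consensus scanning (IUPAC, both strands).
#
# Matching is exact-degenerate: a consensus letter matches exactly the
# base set it denotes; a sequence N matches nothing except consensus N.
# The conservative N rule keeps masked regions from spawning spurious
# element hits.

#' Expand repeat notation in a signal consensus
#'
#' Rewrites every `(X)n` group as `X` repeated `n` times, e.g. `(GA)8` to
#' a 16-nt string; plain consensi pass through unchanged.
#'
#' @param x Character vector of signal strings.
#' @return Character vector of expanded IUPAC strings.
#' @examples
#' expandRepeatNotation("(GA)8")
#' expandRepeatNotation("CTGAAGAAGAA")
#' @export
expandRepeatNotation <- function(x) {
  vapply(x, function(s0) {
    s <- toupper(s0)
    repeat {
      m <- regexpr("\\(([A-Z]+)\\)([0-9]+)", s, perl = TRUE)
      if (m == -1L) break
      whole <- regmatches(s, m)
      unit <- sub("\\(([A-Z]+)\\)([0-9]+)", "\\1", whole)
      n <- as.integer(sub("\\(([A-Z]+)\\)([0-9]+)", "\\2", whole))
      regmatches(s, m) <- strrep(unit, n)
    }
    if (grepl("[()]", s))
      .stopf("malformed repeat notation in signal '%s' (missing count?)", s0)
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Read a regulatory-element library
#'
#' Tab-separated file with at least two columns: element name and signal
#' consensus (IUPAC, optionally in repeat notation such as `(GA)8`); an
#' optional third column is a free source tag.  Signals are expanded to
#' plain IUPAC strings on load.
#'
#' @param path TSV path.
#' @return data.frame with columns `name`, `signal` (expanded), `source`.
#' @seealso [cnmsElements()] for the bundled five-element library.
#' @export
readElementLibrary <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    .stopf("element library must have >= 2 columns (name, signal)")
  names(df)[1:2] <- c("name", "signal")
  if (ncol(df) < 3L) df$source <- NA_character_ else names(df)[3] <- "source"
  dup <- df$name[duplicated(df$name)]
  if (length(dup))
    .stopf("duplicate element name(s): %s", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(df))) {
    sig <- tryCatch(expandRepeatNotation(df$signal[i]),
                    error = function(e)
                      .stopf("row %d (%s): %s", i, df$name[i], conditionMessage(e)))
    bad <- setdiff(unique(strsplit(sig, "", fixed = TRUE)[[1]]), .IUPAC_LETTERS)
    if (length(bad))
      .stopf("row %d (%s): illegal IUPAC letter(s): %s", i, df$name[i],
             paste(bad, collapse = ", "))
    if (nchar(sig) < 4L)
      .stopf("row %d (%s): expanded signal shorter than 4 nt", i, df$name[i])
    df$signal[i] <- sig
  }
  df[, c("name", "signal", "source")]
}

#' The bundled five-element signal library
#'
#' Loads the packaged PLACE-style fixture library (GAGA8HVBKN3,
#' CTRMCAMV35S, RAV1AAT, S1FBOXSORPS1L21, CANBNNAPA) shipped in
#' `inst/extdata/regulatory_elements.tsv`.
#'
#' @return data.frame as from [readElementLibrary()].
#' @export
cnmsElements <- function() {
  readElementLibrary(system.file("extdata", "regulatory_elements.tsv",
                                 package = "cnmscan", mustWork = TRUE))
}

## Consensus -> regex character classes under the package's N semantics.
.signalRegex <- function(signal) {
  ch <- strsplit(signal, "", fixed = TRUE)[[1]]
  classes <- vapply(ch, function(letter) {
    set <- .IUPAC_SETS[[letter]]
    if (letter == "N") set <- c(set, "N")  # consensus N also matches sequence N
    paste0("[", paste(set, collapse = ""), "]")
  }, character(1))
  paste(classes, collapse = "")
}

.emptyHitFrame <- function() {
  data.frame(gene_id = character(0), element = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             matched_seq = character(0), stringsAsFactors = FALSE)
}

## All (overlapping) match starts of an expanded consensus on one strand.
.scanStarts <- function(s, signal) {
  if (nchar(signal) > nchar(s)) return(integer(0))
  hits <- gregexpr(paste0("(?=", .signalRegex(signal), ")"), s,
                   perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

.scanElementsOne <- function(s, elements, bothStrands) {
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    sig <- elements$signal[i]
    w <- nchar(sig)
    st <- .scanStarts(s, sig)
    if (length(st))
      rows[[length(rows) + 1L]] <- data.frame(
        element = elements$name[i], start = st, end = st + w - 1L,
        strand = "+", matched_seq = substring(s, st, st + w - 1L),
        stringsAsFactors = FALSE)
    if (bothStrands) {
      rc <- .revcompIupac(sig)
      st <- .scanStarts(s, rc)
      if (length(st))
        rows[[length(rows) + 1L]] <- data.frame(
          element = elements$name[i], start = st, end = st + w - 1L,
          strand = "-", matched_seq = substring(s, st, st + w - 1L),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyHitFrame()[, -1])
  out <- do.call(rbind, rows)
  out <- out[order(out$element, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan sequences for regulatory-element signal consensi
#'
#' Reports every position (all overlapping occurrences) where an expanded
#' consensus matches under exact-degenerate IUPAC semantics, on the plus
#' strand and — unless `bothStrands = FALSE` — on the minus strand.
#' Minus-strand hits are reported in plus-strand coordinates with
#' `strand == "-"`; their `matched_seq` is the plus-strand substring,
#' whose reverse complement matches the consensus.
#'
#' @param x A single sequence string or an [UpstreamSet-class].
#' @param elements Element library data.frame (`name`, `signal`,
#'   optionally `source`), e.g. from [readElementLibrary()]; signals may
#'   still carry repeat notation and are expanded here.
#' @param bothStrands Scan the minus strand too (default TRUE).
#' @param ... Passed on between methods.
#' @return data.frame with columns `gene_id` (for `UpstreamSet` input),
#'   `element`, `start`, `end`, `strand`, `matched_seq`.
#' @examples
#' lib <- data.frame(name = "RAV1AAT", signal = "CAACA")
#' scanElements(strrep("CAA", 7), lib)
#' @export
setGeneric("scanElements",
           function(x, elements, bothStrands = TRUE, ...)
             standardGeneric("scanElements"))

.prepElements <- function(elements) {
  stopifnot(is.data.frame(elements),
            all(c("name", "signal") %in% names(elements)))
  if (nrow(elements))
    elements$signal <- expandRepeatNotation(elements$signal)
  elements
}

#' @rdname scanElements
#' @export
setMethod("scanElements", "character",
          function(x, elements, bothStrands = TRUE) {
  stopifnot(length(x) == 1L)
  s <- toupper(x)
  bad <- .badBases(s)
  if (length(bad))
    .stopf("sequence contains disallowed characters: %s",
           paste(bad, collapse = ", "))
  .scanElementsOne(s, .prepElements(elements), bothStrands)
})

#' @rdname scanElements
#' @export
setMethod("scanElements", "UpstreamSet",
          function(x, elements, bothStrands = TRUE) {
  elements <- .prepElements(elements)
  seqs <- as.character(upstreamSeqs(x))
  ids <- geneIds(x)
  rows <- lapply(seq_along(seqs), function(i) {
    df <- .scanElementsOne(seqs[[i]], elements, bothStrands)
    if (nrow(df)) cbind(gene_id = ids[i], df, stringsAsFactors = FALSE)
    else NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(.emptyHitFrame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
})
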