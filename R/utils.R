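# Shared helpers: rounding convention, alphabets, small string utilities.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves always rounded up
#' (`0.5 -> 1`), the convention used by the marker survey statistics.
#' Base R's [round()] rounds halves to even, which disagrees with how
#' marker tables are conventionally reported.
#'
#' @param x Numeric vector (non-negative values expected).
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @examples
#' roundHalfUp(3.945, 2)
#' roundHalfUp(40.57, 1)
#' @export
roundHalfUp <- function(x, digits = 0) {
  stopifnot(is.numeric(x), all(x >= 0 | is.na(x)))
  m <- 10^digits
  floor(x * m + 0.5) / m
}

## IUPAC nucleotide codes -> the set of plain bases each denotes.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_LETTERS <- names(.IUPAC_SETS)

## Plain-base reverse complement for sequences over {A,C,G,T,N}.
.revcompPlain <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Reverse complement honouring IUPAC ambiguity codes (for consensi).
.revcompIupac <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Check that a character scalar uses only {A,C,G,T,N}; returns offending
## characters (empty if clean).
.badBases <- function(s) {
  ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
  setdiff(ch, c("A", "C", "G", "T", "N"))
}

## TRUE if `unit` is primitive, i.e. not itself a whole-number repetition
## of a shorter string.
.isPrimitiveUnit <- function(unit) {
  u <- nchar(unit)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        strrep(substr(unit, 1L, d), u %/% d) == unit) {
      return(FALSE)
    }
  }
  TRUE
}

## Count all (possibly overlapping) occurrences of fixed `pattern` in
## `subject`; used for the primer uniqueness constraint.
.countOccurrences <- function(pattern, subject) {
  if (nchar(pattern) == 0L || nchar(pattern) > nchar(subject)) return(0L)
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(0L)
  ## fixed=TRUE gregexpr is non-overlapping; rescan shifted starts.
  n <- 0L
  start <- 1L
  while (start + nchar(pattern) - 1L <= nchar(subject)) {
    hit <- regexpr(pattern, substr(subject, start, nchar(subject)),
                   fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    start <- start + hit  # next search begins one past this match start
  }
  n
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
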