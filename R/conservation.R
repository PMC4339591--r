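# Conserved non-coding block detection: ungapped seed-and-extend.
#
# Every exact seed_k-mer shared between target and comparator defines a
# diagonal position.  From each seed the block is extended ungapped, one
# base at a time (right first, then left), accepting a base only while
# the running identity of the grown block stays >= min_identity; leading
# and trailing mismatches are then trimmed so blocks end on matches.
# Blocks shorter than min_len are dropped.  Overlapping blocks on one
# diagonal are resolved by keeping the longer block, then the higher
# identity, then the smaller t_start.

.emptyCNSFrame <- function() {
  data.frame(target_gene = character(0), comparator_species = character(0),
             comparator_gene = character(0),
             t_start = integer(0), t_end = integer(0),
             c_start = integer(0), c_end = integer(0),
             length = integer(0), identity = numeric(0),
             stringsAsFactors = FALSE)
}

## Seed t-positions per diagonal: all (t,c) position pairs sharing an
## N-free k-mer, keyed by diagonal d = t - c.
.sharedSeeds <- function(t, c, k) {
  Lt <- nchar(t); Lc <- nchar(c)
  if (Lt < k || Lc < k) return(list())
  tk <- substring(t, seq_len(Lt - k + 1L), seq.int(k, Lt))
  ck <- substring(c, seq_len(Lc - k + 1L), seq.int(k, Lc))
  keepT <- !grepl("N", tk, fixed = TRUE)
  keepC <- !grepl("N", ck, fixed = TRUE)
  tpos <- split(which(keepT), tk[keepT])
  cpos <- split(which(keepC), ck[keepC])
  shared <- intersect(names(tpos), names(cpos))
  if (!length(shared)) return(list())
  ts <- cs <- integer(0)
  for (km in shared) {
    grid <- expand.grid(t = tpos[[km]], c = cpos[[km]])
    ts <- c(ts, grid$t); cs <- c(cs, grid$c)
  }
  split(ts, ts - cs)
}

## Greedy extension of one seed on a precomputed diagonal match vector.
## `m` is logical over target positions lo..hi (index 1 == position lo),
## `P` its prefix-sum with a leading 0.  Returns c(bs, be) in local index
## space, or NULL.
.extendSeed <- function(m, P, sLoc, k, minIdentity) {
  n <- length(m)
  bs <- sLoc; be <- sLoc + k - 1L
  j <- be + 1L
  while (j <= n) {
    if ((P[j + 1L] - P[bs]) >= minIdentity * (j - bs + 1L) - 1e-9) {
      be <- j; j <- j + 1L
    } else break
  }
  i <- bs - 1L
  while (i >= 1L) {
    if ((P[be + 1L] - P[i]) >= minIdentity * (be - i + 1L) - 1e-9) {
      bs <- i; i <- i - 1L
    } else break
  }
  while (bs <= be && !m[bs]) bs <- bs + 1L
  while (be >= bs && !m[be]) be <- be - 1L
  if (be < bs) return(NULL)
  c(bs, be)
}

## Resolve overlaps on one diagonal: longer, then higher identity, then
## smaller t_start wins; losers overlapping a kept block are dropped.
.resolveDiagonal <- function(blocks) {
  ord <- order(-blocks$length, -blocks$identity, blocks$t_start)
  blocks <- blocks[ord, , drop = FALSE]
  kept <- logical(nrow(blocks))
  for (i in seq_len(nrow(blocks))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (blocks$t_start[i] <= blocks$t_end[j] &&
          blocks$t_end[i] >= blocks$t_start[j]) { ok <- FALSE; break }
    }
    kept[i] <- ok
  }
  blocks[kept, , drop = FALSE]
}

.detectCNSOne <- function(t, c, params) {
  k <- params@seedK
  seedsByDiag <- .sharedSeeds(t, c, k)
  if (!length(seedsByDiag)) return(.emptyCNSFrame()[, 4:9])
  tv <- strsplit(t, "", fixed = TRUE)[[1]]
  cv <- strsplit(c, "", fixed = TRUE)[[1]]
  Lt <- length(tv); Lc <- length(cv)
  out <- list()
  for (dStr in names(seedsByDiag)) {
    d <- as.integer(dStr)
    lo <- max(1L, 1L + d)
    hi <- min(Lt, Lc + d)
    tIdx <- lo:hi
    cIdx <- tIdx - d
    m <- tv[tIdx] == cv[cIdx] & tv[tIdx] != "N" & cv[cIdx] != "N"
    P <- c(0L, cumsum(m))
    found <- list()
    for (s in sort(unique(seedsByDiag[[dStr]]))) {
      ext <- .extendSeed(m, P, s - lo + 1L, k, params@minIdentity)
      if (is.null(ext)) next
      key <- paste(ext, collapse = ":")
      if (is.null(found[[key]])) found[[key]] <- ext
    }
    if (!length(found)) next
    blocks <- do.call(rbind, found)
    len <- blocks[, 2] - blocks[, 1] + 1L
    matches <- P[blocks[, 2] + 1L] - P[blocks[, 1]]
    keep <- len >= params@minLen
    if (!any(keep)) next
    df <- data.frame(
      t_start = blocks[keep, 1] + lo - 1L,
      t_end = blocks[keep, 2] + lo - 1L,
      length = len[keep],
      identity = matches[keep] / len[keep],
      stringsAsFactors = FALSE)
    df$c_start <- df$t_start - d
    df$c_end <- df$t_end - d
    out[[length(out) + 1L]] <- .resolveDiagonal(df)
  }
  if (!length(out)) return(.emptyCNSFrame()[, 4:9])
  res <- do.call(rbind, out)
  res <- res[order(res$t_start, res$c_start), ,
             drop = FALSE][, c("t_start", "t_end", "c_start", "c_end",
                               "length", "identity")]
  rownames(res) <- NULL
  res
}

#' Detect conserved non-coding blocks between two upstream sequences
#'
#' Ungapped seed-and-extend: shared exact `seedK`-mers anchor diagonals
#' that are extended while the running identity stays at or above
#' `minIdentity`; blocks of at least `minLen` bp are reported, trimmed to
#' end on matches, with overlaps on a diagonal resolved in favour of the
#' longer (then higher-identity, then leftmost) block.  `N` never matches.
#'
#' @param target,comparator Sequence strings, or single-gene
#'   [UpstreamSet-class] objects.
#' @param params A [CNSParams-class] (default [cnsParams()]).
#' @param ... Passed on between methods.
#' @return data.frame with columns `t_start`, `t_end`, `c_start`, `c_end`
#'   (1-based inclusive string positions), `length`, `identity` (and
#'   `target_gene`, `comparator_species`, `comparator_gene` for
#'   `UpstreamSet` input).
#' @examples
#' s <- strrep("ACGTTGCAAC", 4)
#' detectCNS(s, s)   # one full-length identity-1 block
#' @export
setGeneric("detectCNS",
           function(target, comparator, params = cnsParams(), ...)
             standardGeneric("detectCNS"))

#' @rdname detectCNS
#' @export
setMethod("detectCNS", signature("character", "character"),
          function(target, comparator, params = cnsParams()) {
  stopifnot(length(target) == 1L, length(comparator) == 1L,
            nchar(target) > 0L, nchar(comparator) > 0L)
  .detectCNSOne(toupper(target), toupper(comparator), params)
})

#' @rdname detectCNS
#' @export
setMethod("detectCNS", signature("UpstreamSet", "UpstreamSet"),
          function(target, comparator, params = cnsParams()) {
  stopifnot(length(target) == 1L, length(comparator) == 1L)
  df <- .detectCNSOne(as.character(upstreamSeqs(target))[[1]],
                      as.character(upstreamSeqs(comparator))[[1]], params)
  if (!nrow(df)) return(.emptyCNSFrame())
  cbind(target_gene = geneIds(target)[1],
        comparator_species = upstreamInfo(comparator)$species[1],
        comparator_gene = geneIds(comparator)[1],
        df, stringsAsFactors = FALSE)
})

#' Which comparator species conserve an interval?
#'
#' A species supports the interval iff one of its blocks *fully contains*
#' it on the target coordinates (containment, not mere overlap: the
#' composite element itself must be conserved).
#'
#' @param start,end Target-string interval (1-based inclusive).
#' @param blocks data.frame of CNS blocks with columns
#'   `comparator_species`, `t_start`, `t_end` (e.g. rbind-ed output of
#'   [detectCNS()] across comparators).
#' @return Sorted, deduplicated character vector of supporting species.
#' @examples
#' b <- data.frame(comparator_species = "A", t_start = 1, t_end = 40)
#' conservationSupport(10, 25, b)   # "A"
#' conservationSupport(10, 25, data.frame(comparator_species = "A",
#'                                        t_start = 12, t_end = 40))
#' @export
conservationSupport <- function(start, end, blocks) {
  stopifnot(length(start) == 1L, length(end) == 1L, start <= end)
  if (is.null(blocks) || nrow(blocks) == 0L) return(character(0))
  hit <- blocks$t_start <= start & blocks$t_end >= end
  sort(unique(as.character(blocks$comparator_species[hit])))
}
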