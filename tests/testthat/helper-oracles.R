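# Independent naive oracles used to cross-check the optimized
# implementations.  They share the definitions with the package code but
# none of its internals: all comparisons are done character by character.

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## --- SSR oracle: per-position comparisons, whole-unit greedy counting ---

oraclePrimitive <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(max(u - 1L, 0L))) {
    if (u %% d == 0L && paste(rep(substr(unit, 1L, d), u / d),
                              collapse = "") == unit) return(FALSE)
  }
  TRUE
}

ssrOracle <- function(s, th = cnmscan::ssrThresholds()) {
  s <- toupper(s)
  L <- nchar(s)
  rows <- list()
  charAt <- function(p) substr(s, p, p)
  for (u in 1:6) {
    if (L < 2L * u) next
    pcmp <- function(pos) {
      a <- charAt(pos); b <- charAt(pos + u)
      a == b && a != "N"
    }
    for (i in seq_len(L - 2L * u + 1L)) {
      if (!pcmp(i)) next
      if (i > 1L && pcmp(i - 1L)) next       # not a run start
      j <- i
      while (j + u <= L && pcmp(j)) j <- j + 1L
      mlen <- j - i                          # consecutive matches from i
      cnt <- (mlen + u) %/% u
      if (cnt < 2L) next
      unit <- substr(s, i, i + u - 1L)
      if (!oraclePrimitive(unit)) next
      if (cnt < th@minRepeats[[as.character(u)]]) next
      if (cnt * u < th@minTractBp) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit = unit, unit_size = u, repeat_count = cnt,
        start = i, end = i + cnt * u - 1L, tract_bp = cnt * u,
        ssr_class = if (cnt * u >= 20) "I" else if (cnt * u >= 12) "II"
                    else "sub12",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(unit = character(0), unit_size = integer(0),
                      repeat_count = integer(0), start = integer(0),
                      end = integer(0), tract_bp = integer(0),
                      ssr_class = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- IUPAC scan oracle: per-position set membership ---

oracleIupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))

oracleComplement <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                      S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                      D = "H", H = "D", N = "N")

oracleRevcompIupac <- function(p) {
  paste(rev(oracleComplement[strsplit(p, "", fixed = TRUE)[[1]]]),
        collapse = "")
}

scanOracle <- function(s, name, signal, bothStrands = TRUE) {
  sv <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  matchAt <- function(pat, pos) {
    pv <- strsplit(pat, "", fixed = TRUE)[[1]]
    for (k in seq_along(pv)) {
      if (!sv[pos + k - 1L] %in% oracleIupac[[pv[k]]]) return(FALSE)
    }
    TRUE
  }
  rows <- list()
  pats <- list(`+` = signal)
  if (bothStrands) pats[["-"]] <- oracleRevcompIupac(signal)
  w <- nchar(signal)
  for (strand in names(pats)) {
    pat <- pats[[strand]]
    if (w > length(sv)) next
    for (pos in seq_len(length(sv) - w + 1L)) {
      if (matchAt(pat, pos))
        rows[[length(rows) + 1L]] <- data.frame(
          element = name, start = pos, end = pos + w - 1L, strand = strand,
          matched_seq = substr(s, pos, pos + w - 1L),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(element = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      matched_seq = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$element, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## --- CNS oracle: per-seed greedy extension, identity recomputed naively ---

cnsOracle <- function(t, c, params = cnmscan::cnsParams()) {
  t <- toupper(t); c <- toupper(c)
  k <- params@seedK; theta <- params@minIdentity
  Lt <- nchar(t); Lc <- nchar(c)
  tv <- strsplit(t, "", fixed = TRUE)[[1]]
  cv <- strsplit(c, "", fixed = TRUE)[[1]]
  mch <- function(ti, ci) tv[ti] == cv[ci] && tv[ti] != "N" && cv[ci] != "N"
  ident <- function(bs, be, d) {
    mean(vapply(bs:be, function(x) mch(x, x - d), logical(1)))
  }
  blocks <- list()
  if (Lt >= k && Lc >= k) {
    for (ts in seq_len(Lt - k + 1L)) {
      tk <- substr(t, ts, ts + k - 1L)
      if (grepl("N", tk, fixed = TRUE)) next
      for (cs in seq_len(Lc - k + 1L)) {
        if (substr(c, cs, cs + k - 1L) != tk) next
        d <- ts - cs
        bs <- ts; be <- ts + k - 1L
        repeat {
          j <- be + 1L
          if (j > Lt || j - d > Lc || j - d < 1L) break
          if (ident(bs, j, d) >= theta - 1e-9) be <- j else break
        }
        repeat {
          i <- bs - 1L
          if (i < 1L || i - d < 1L || i - d > Lc) break
          if (ident(i, be, d) >= theta - 1e-9) bs <- i else break
        }
        while (bs <= be && !mch(bs, bs - d)) bs <- bs + 1L
        while (be >= bs && !mch(be, be - d)) be <- be - 1L
        if (be < bs || be - bs + 1L < params@minLen) next
        blocks[[length(blocks) + 1L]] <- data.frame(
          d = d, t_start = bs, t_end = be, length = be - bs + 1L,
          identity = ident(bs, be, d))
      }
    }
  }
  empty <- data.frame(t_start = integer(0), t_end = integer(0),
                      c_start = integer(0), c_end = integer(0),
                      length = integer(0), identity = numeric(0))
  if (!length(blocks)) return(empty)
  df <- unique(do.call(rbind, blocks))
  ## per diagonal: keep longer, then higher identity, then smaller t_start
  out <- list()
  for (d in unique(df$d)) {
    sub <- df[df$d == d, , drop = FALSE]
    sub <- sub[order(-sub$length, -sub$identity, sub$t_start), , drop = FALSE]
    kept <- sub[0, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      if (!any(sub$t_start[r] <= kept$t_end & sub$t_end[r] >= kept$t_start))
        kept <- rbind(kept, sub[r, , drop = FALSE])
    }
    out[[length(out) + 1L]] <- kept
  }
  res <- do.call(rbind, out)
  res$c_start <- res$t_start - res$d
  res$c_end <- res$t_end - res$d
  res <- res[order(res$t_start, res$c_start),
             c("t_start", "t_end", "c_start", "c_end", "length", "identity")]
  rownames(res) <- NULL
  res
}

## Construct a sequence pair sharing exactly one planted segment, with a
## construction-level guarantee: every k-mer shared between the final
## strings lies inside the planted windows on the planted diagonal, and
## the diagonal positions flanking the segment are forced mismatches
## (so greedy extension stops inside the guard and trims back exactly to
## the segment).
plantedPair <- function(tLen = 300, cLen = 300, segLen = 30,
                        tAt = 101, cAt = 51, k = 8, guard = 13) {
  kmerList <- function(s) substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  nextBase <- c(A = "C", C = "G", G = "T", T = "A")
  d <- tAt - cAt
  repeat {
    seg <- randomSeq(segLen)
    if (anyDuplicated(kmerList(seg))) next
    t <- randomSeq(tLen); c <- randomSeq(cLen)
    substr(t, tAt, tAt + segLen - 1) <- seg
    substr(c, cAt, cAt + segLen - 1) <- seg
    for (tp in c(seq(tAt - guard, tAt - 1),
                 seq(tAt + segLen, tAt + segLen + guard - 1))) {
      cp <- tp - d
      if (tp >= 1 && tp <= tLen && cp >= 1 && cp <= cLen &&
          substr(c, cp, cp) == substr(t, tp, tp))
        substr(c, cp, cp) <- nextBase[[substr(t, tp, tp)]]
    }
    ## verify: shared k-mers only from the segment, on the planted diagonal
    tk <- kmerList(t); ck <- kmerList(c)
    shared <- intersect(tk, ck)
    ok <- TRUE
    for (km in shared) {
      ts <- which(tk == km); cs <- which(ck == km)
      pairs <- expand.grid(ts = ts, cs = cs)
      if (!all(pairs$ts - pairs$cs == d &
               pairs$ts >= tAt & pairs$ts <= tAt + segLen - k)) {
        ok <- FALSE; break
      }
    }
    if (ok) return(list(t = t, c = c, seg = seg))
  }
}
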