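# SSR mining: examples, thresholds, and oracle equivalence.

test_that("known repeat tracts are mined with the right unit and class", {
  r <- findSSRs(strrep("CAA", 7))
  expect_identical(r$unit, "CAA")
  expect_identical(r$repeat_count, 7L)
  expect_identical(r$tract_bp, 21L)
  expect_identical(r$ssr_class, "I")

  r <- findSSRs("TTCTTTCTTTCT")
  expect_identical(r$unit, "TTCT")
  expect_identical(r$repeat_count, 3L)
  expect_identical(r$ssr_class, "II")

  expect_identical(nrow(findSSRs("ACGTCGTAGCTAGNCATG")), 0L)
  expect_identical(nrow(findSSRs("")), 0L)
})

test_that("every validated chickpea marker motif passes the default thresholds", {
  motifs <- utils::read.delim(
    system.file("extdata", "chickpea_seedweight_markers.tsv",
                package = "cnmscan"), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(motifs))) {
    tract <- strrep(motifs$motif_unit[i], motifs$motif_count[i])
    r <- findSSRs(tract)
    expect_identical(r$unit[1], motifs$motif_unit[i])
    expect_identical(r$repeat_count[1], as.integer(motifs$motif_count[i]))
  }
})

test_that("class boundaries sit at 12 and 20 bp", {
  expect_identical(classifySSR(c(24, 12, 19, 20, 11, 1)),
                   c("I", "II", "II", "I", "sub12", "sub12"))
  expect_error(classifySSR(0), "positive")
})

test_that("a run writable with several unit sizes is reported once, smallest unit", {
  r <- findSSRs(strrep("GA", 12))
  expect_identical(nrow(r), 1L)
  expect_identical(r$unit, "GA")
  ## anchored at the earliest phase for shifted runs
  r <- findSSRs(paste0("CC", strrep("AG", 7), "A"), ssrThresholds(
    minRepeats = c(`1` = 10, `2` = 2, `3` = 2, `4` = 2, `5` = 2, `6` = 2),
    minTractBp = 2))
  expect_identical(r$start[1], 3L)
  expect_identical(r$unit[1], "AG")
})

test_that("N breaks runs", {
  r <- findSSRs(paste0(strrep("GA", 6), "N", strrep("GA", 6)))
  expect_identical(nrow(r), 2L)
  expect_identical(r$repeat_count, c(6L, 6L))
})

test_that("miner equals the exhaustive oracle on all short {A,C,G} strings", {
  th <- ssrThresholds(minRepeats = c(`1` = 2, `2` = 2, `3` = 2, `4` = 2,
                                     `5` = 2, `6` = 2), minTractBp = 2)
  for (L in 1:7) {
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G")), L))
    strs <- do.call(paste0, grid)
    for (s in strs) {
      expect_identical(findSSRs(s, th), ssrOracle(s, th), label = s)
    }
  }
})

test_that("miner equals the oracle on seeded random strings with N", {
  set.seed(1234)
  ths <- list(ssrThresholds(),
              ssrThresholds(minRepeats = c(`1` = 4, `2` = 3, `3` = 2,
                                           `4` = 2, `5` = 2, `6` = 2),
                            minTractBp = 6))
  for (rep in 1:40) {
    L <- sample(20:500, 1)
    s <- randomSeq(L, alphabet = c("A", "C", "G", "T", "A", "C", "G", "T",
                                   "A", "A", "N"))
    ## splice in repeat tracts so qualifying loci actually occur
    tract <- strrep(sample(c("A", "GA", "CT", "CAA", "TTCT", "ACACAA"), 1),
                    sample(3:12, 1))
    if (nchar(tract) < L) {
      at <- sample(L - nchar(tract) + 1, 1)
      substr(s, at, at + nchar(tract) - 1) <- tract
    }
    th <- ths[[sample(2, 1)]]
    expect_identical(findSSRs(s, th), ssrOracle(s, th))
  }
})

test_that("reported loci are maximal and non-redundant", {
  set.seed(99)
  th <- ssrThresholds(minRepeats = c(`1` = 3, `2` = 2, `3` = 2, `4` = 2,
                                     `5` = 2, `6` = 2), minTractBp = 4)
  for (rep in 1:25) {
    s <- randomSeq(sample(30:120, 1), alphabet = c("A", "C", "G"))
    r <- findSSRs(s, th)
    if (!nrow(r)) next
    for (i in seq_len(nrow(r))) {
      u <- r$unit_size[i]; st <- r$start[i]; en <- r$end[i]
      unit <- r$unit[i]
      ## cannot extend by one unit on either side
      if (st - u >= 1)
        expect_false(substr(s, st - u, st - 1) == unit)
      if (en + u <= nchar(s))
        expect_false(substr(s, en + 1, en + u) ==
                       substr(s, en + 1 - u, en))
      ## the tract really is unit repeated repeat_count times
      expect_identical(substr(s, st, en), strrep(unit, r$repeat_count[i]))
    }
    ## non-redundancy: no containment among same-unit loci
    for (i in seq_len(nrow(r))) for (j in seq_len(nrow(r))) {
      if (i != j && r$unit[i] == r$unit[j])
        expect_false(r$start[i] >= r$start[j] && r$end[i] <= r$end[j])
    }
  }
})

test_that("repeat allele series expand with unit-size length steps", {
  a <- repeatVariantAlleles("GA", c(12, 13, 14))
  expect_identical(a$length_bp, c(24L, 26L, 28L))
  expect_identical(diff(a$length_bp), c(2L, 2L))
  expect_identical(repeatVariantAlleles("GAA", 18)$length_bp, 54L)
  a <- repeatVariantAlleles("CAA", c(7, 9))
  expect_identical(a$length_bp, c(21L, 27L))
  expect_identical(a$allele[1], strrep("CAA", 7))
  expect_error(repeatVariantAlleles("GA", 0), "positive")
})
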