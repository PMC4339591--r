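# CNMS calling, positional binning, and marker density.

## Small hand-built inputs around a (GA)12 tract overlapping a GAGA8HVBKN3
## hit, conserved in two comparator species.
makeCallInputs <- function() {
  ssrs <- data.frame(gene_id = "g1", unit = "GA", unit_size = 2L,
                     repeat_count = 12L, start = 101L, end = 124L,
                     tract_bp = 24L, ssr_class = "I",
                     stringsAsFactors = FALSE)
  hits <- data.frame(gene_id = "g1", element = "GAGA8HVBKN3",
                     start = c(101L, 103L), end = c(116L, 118L),
                     strand = "+", matched_seq = strrep("GA", 8),
                     stringsAsFactors = FALSE)
  blocks <- data.frame(target_gene = "g1",
                       comparator_species = c("medicago", "soybean"),
                       comparator_gene = c("m_g1", "s_g1"),
                       t_start = 80L, t_end = 140L,
                       c_start = 80L, c_end = 140L,
                       length = 61L, identity = 0.9,
                       stringsAsFactors = FALSE)
  list(ssrs = ssrs, hits = hits, blocks = blocks)
}

test_that("an SSR overlapping an element hit inside a conserved block becomes one marker", {
  x <- makeCallInputs()
  m <- callCNMS(x$ssrs, x$hits, x$blocks,
                seqLengths = c(g1 = 1000L))
  expect_identical(nrow(m), 1L)
  expect_identical(m$marker_id, "CNMS0001")
  expect_identical(m$element, "GAGA8HVBKN3")
  expect_identical(m$n_element_hits, 2L)          # hits collapse
  expect_identical(m$comp_start, 101L)
  expect_identical(m$comp_end, 124L)              # union span
  expect_identical(m$supporting_species, "medicago,soybean")
  expect_identical(m$n_supporting, 2L)
  expect_identical(m$up_start, 877L)
  expect_identical(m$up_end, 900L)
})

test_that("each defining clause is necessary", {
  x <- makeCallInputs()
  ## no conservation support
  expect_identical(nrow(callCNMS(x$ssrs, x$hits, x$blocks[0, ])), 0L)
  ## partial containment is not support
  b <- x$blocks; b$t_start <- 110L
  expect_identical(nrow(callCNMS(x$ssrs, x$hits, b)), 0L)
  ## no element overlap
  h <- x$hits; h$start <- c(300L, 320L); h$end <- h$start + 15L
  expect_identical(nrow(callCNMS(x$ssrs, h, x$blocks)), 0L)
  ## no SSR at all
  expect_identical(nrow(callCNMS(x$ssrs[0, ], x$hits, x$blocks)), 0L)
  ## sub-eligible SSR class excluded by default
  s <- x$ssrs; s$ssr_class <- "sub12"
  expect_identical(nrow(callCNMS(s, x$hits, x$blocks)), 0L)
  ## mononucleotide excluded by default
  s <- x$ssrs; s$unit_size <- 1L
  expect_identical(nrow(callCNMS(s, x$hits, x$blocks)), 0L)
})

test_that("inconsistent gene ids across inputs raise an error", {
  x <- makeCallInputs()
  h <- x$hits; h$gene_id <- "gX"
  expect_error(callCNMS(x$ssrs, h, x$blocks, genes = "g1"), "gX")
})

test_that("one marker per (SSR, element) pair; ids deterministic", {
  x <- makeCallInputs()
  hits2 <- rbind(x$hits,
                 data.frame(gene_id = "g1", element = "CTRMCAMV35S",
                            start = 104L, end = 112L, strand = "-",
                            matched_seq = "AGAGAGAGA",
                            stringsAsFactors = FALSE))
  m <- callCNMS(x$ssrs, hits2, x$blocks, seqLengths = c(g1 = 1000L))
  expect_identical(nrow(m), 2L)
  expect_identical(sort(m$element), c("CTRMCAMV35S", "GAGA8HVBKN3"))
  expect_identical(anyDuplicated(m[, c("gene_id", "ssr_start", "ssr_end",
                                       "element")]), 0L)
  m2 <- callCNMS(x$ssrs, hits2, x$blocks, seqLengths = c(g1 = 1000L))
  expect_identical(m, m2)
})

test_that("positional binning uses composite midpoints and conserves totals", {
  mk <- data.frame(marker_id = sprintf("CNMS%04d", 1:3),
                   up_start = c(145L, 175L, 945L),
                   up_end = c(155L, 185L, 955L))
  h <- binPositions(mk)
  expect_identical(attr(h, "total"), 3L)
  expect_identical(h$count[h$bin_start == 101], 2L)
  expect_identical(h$count[h$bin_start == 901], 1L)
  expect_identical(sum(h$count), 3L)

  h0 <- binPositions(mk[0, ])
  expect_identical(sum(h0$count), 0L)
  expect_identical(nrow(h0), 10L)

  bad <- data.frame(marker_id = "CNMS0001", up_start = 1001L,
                    up_end = 1010L)
  expect_error(binPositions(bad), "outside")
})

test_that("uniformly planted midpoints look uniform to a chi-square test", {
  for (seed in c(2, 12, 22)) {
    set.seed(seed)
    mid <- sample.int(1000, 100, replace = TRUE)
    mk <- data.frame(marker_id = sprintf("M%03d", 1:100),
                     up_start = mid, up_end = mid)
    h <- binPositions(mk)
    expect_identical(sum(h$count), 100L)
    p <- stats::chisq.test(h$count, p = rep(0.1, 10))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("marker density is span per marker in kb, one decimal", {
  expect_identical(markerDensity(10, 1e6), 100.0)
  expect_identical(markerDensity(3, 10500), 3.5)
  expect_identical(markerDensity(666, 347252400), 521.4)
  expect_error(markerDensity(0, 100), "marker")
})
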