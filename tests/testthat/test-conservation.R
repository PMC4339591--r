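# Conserved-block detection and conservation support.

test_that("identical sequences give one full-length identity-1 block", {
  set.seed(5)
  s <- randomSeq(40)
  b <- detectCNS(s, s)
  expect_identical(nrow(b), 1L)
  expect_identical(b$t_start, 1L)
  expect_identical(b$t_end, 40L)
  expect_identical(b$c_start, 1L)
  expect_identical(b$c_end, 40L)
  expect_equal(b$identity, 1)
})

test_that("sequences sharing no seed k-mer give no blocks", {
  b <- detectCNS(strrep("A", 60), strrep("C", 60))
  expect_identical(nrow(b), 0L)
})

test_that("a planted 30-nt shared segment is recovered at its exact coordinates", {
  set.seed(42)
  for (rep in 1:5) {
    pp <- plantedPair(tLen = 300, cLen = 300, segLen = 30,
                      tAt = 101, cAt = 51)
    b <- detectCNS(pp$t, pp$c)
    expect_identical(nrow(b), 1L)
    expect_identical(b$t_start, 101L)
    expect_identical(b$t_end, 130L)
    expect_identical(b$c_start, 51L)
    expect_identical(b$c_end, 80L)
    expect_equal(b$identity, 1)
  }
})

test_that("detector equals the naive per-seed oracle on short pairs", {
  set.seed(314)
  for (rep in 1:30) {
    n1 <- sample(20:50, 1); n2 <- sample(20:50, 1)
    t <- randomSeq(n1, alphabet = c("A", "C", "G", "T"))
    c <- randomSeq(n2, alphabet = c("A", "C", "G", "T"))
    ## splice a shared fragment in half of the cases so blocks exist
    if (rep %% 2 == 0) {
      fl <- sample(8:15, 1)
      frag <- randomSeq(fl)
      ta <- sample(n1 - fl + 1, 1); ca <- sample(n2 - fl + 1, 1)
      substr(t, ta, ta + fl - 1) <- frag
      substr(c, ca, ca + fl - 1) <- frag
    }
    params <- cnsParams(seedK = sample(4:6, 1), minLen = sample(8:14, 1),
                        minIdentity = sample(c(0.6, 0.7, 0.8, 1.0), 1))
    got <- detectCNS(t, c, params)
    want <- cnsOracle(t, c, params)
    expect_equal(got, want, label = sprintf("rep %d", rep))
  }
})

test_that("stored identities re-verify against the raw sequences", {
  set.seed(88)
  for (rep in 1:5) {
    t <- randomSeq(400); c <- randomSeq(400)
    frag <- randomSeq(60)
    substr(t, 101, 160) <- frag
    ## 85%-identity copy
    fv <- strsplit(frag, "")[[1]]
    mut <- which(runif(60) < 0.15)
    for (i in mut) fv[i] <- sample(setdiff(c("A", "C", "G", "T"), fv[i]), 1)
    substr(c, 201, 260) <- paste(fv, collapse = "")
    b <- detectCNS(t, c)
    for (r in seq_len(nrow(b))) {
      tseg <- strsplit(substr(t, b$t_start[r], b$t_end[r]), "")[[1]]
      cseg <- strsplit(substr(c, b$c_start[r], b$c_end[r]), "")[[1]]
      expect_identical(b$length[r], length(tseg))
      expect_identical(length(tseg), length(cseg))  # ungapped
      expect_equal(b$identity[r], mean(tseg == cseg & tseg != "N"))
      expect_gte(b$identity[r], 0.70)
      expect_gte(b$length[r], 20L)
      ## blocks end on matches
      expect_identical(tseg[1], cseg[1])
      expect_identical(tseg[length(tseg)], cseg[length(cseg)])
    }
  }
})

test_that("raising min_len shrinks the block set; raising min_identity keeps blocks nested", {
  set.seed(202)
  for (rep in 1:10) {
    t <- randomSeq(300); c <- randomSeq(300)
    frag <- randomSeq(50)
    substr(t, 51, 100) <- frag
    fv <- strsplit(frag, "")[[1]]
    for (i in which(runif(50) < 0.12))
      fv[i] <- sample(setdiff(c("A", "C", "G", "T"), fv[i]), 1)
    substr(c, 151, 200) <- paste(fv, collapse = "")
    loose <- detectCNS(t, c, cnsParams(minLen = 20, minIdentity = 0.70))
    strictLen <- detectCNS(t, c, cnsParams(minLen = 30, minIdentity = 0.70))
    ## min_len: strict result is an exact subset
    key <- function(df) paste(df$t_start, df$t_end, df$c_start, df$c_end)
    expect_true(all(key(strictLen) %in% key(loose)))
    strictId <- detectCNS(t, c, cnsParams(minLen = 20, minIdentity = 0.85))
    ## min_identity: every strict block nests inside some loose block
    for (r in seq_len(nrow(strictId))) {
      expect_true(any(loose$t_start <= strictId$t_start[r] &
                      loose$t_end >= strictId$t_end[r] &
                      loose$c_start <= strictId$c_start[r] &
                      loose$c_end >= strictId$c_end[r]))
    }
  }
})

test_that("conservation support requires full containment", {
  blocks <- data.frame(comparator_species = c("A", "B"),
                       t_start = c(1L, 12L), t_end = c(40L, 40L))
  expect_identical(conservationSupport(10, 25, blocks), "A")
  expect_identical(conservationSupport(10, 25, blocks[2, , drop = FALSE]),
                   character(0))
  expect_identical(conservationSupport(12, 25, blocks), c("A", "B"))
  expect_identical(conservationSupport(5, 8, NULL), character(0))
})

test_that("support lists are exact on a planted multi-species bundle", {
  sim <- simulateUpstreamSet(simConfig(nTrue = 3, nDecoySSR = 0,
                                       nDecoyTFBS = 0, nDecoyUncons = 1,
                                       seed = 9))
  for (gi in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[gi, ]
    blocks <- list()
    for (sp in names(sim$comparators)) {
      cg <- paste0(sp, "_", tr$gene_id)
      b <- detectCNS(sim$target[tr$gene_id], sim$comparators[[sp]][cg])
      if (nrow(b)) blocks[[length(blocks) + 1L]] <- b
    }
    blocks <- if (length(blocks)) do.call(rbind, blocks)
              else data.frame(comparator_species = character(0),
                              t_start = integer(0), t_end = integer(0))
    supp <- conservationSupport(tr$tract_start, tr$tract_end, blocks)
    want <- if (nzchar(tr$supporting_species))
      strsplit(tr$supporting_species, ",")[[1]] else character(0)
    expect_identical(supp, want, label = tr$gene_id)
  }
})
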