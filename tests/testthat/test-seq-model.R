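# Upstream FASTA I/O and the ATG-relative coordinate frame.

test_that("FASTA headers in the geneID|chrom|strand|atgPos dialect parse", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1|Chr2|+|3541793", strrep("ACGT", 250),
               ">g2", "ACGT"), fa)
  up <- readUpstreamFasta(fa, "cicer")
  info <- upstreamInfo(up)
  expect_identical(geneIds(up), c("g1", "g2"))
  expect_identical(info$chromosome, c("Chr2", NA))
  expect_identical(info$strand, c("+", "*"))
  expect_identical(info$atg_pos, c(3541793L, NA))
  expect_identical(unname(Biostrings::width(upstreamSeqs(up))), c(1000L, 4L))
  expect_identical(info$species, c("cicer", "cicer"))
})

test_that("sequences are uppercased, U converted, bad characters rejected", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1", "acgu", ">g2", "NNAC"), fa)
  up <- readUpstreamFasta(fa)
  expect_identical(as.character(upstreamSeqs(up))[["g1"]], "ACGT")
  expect_identical(as.character(upstreamSeqs(up))[["g2"]], "NNAC")

  writeLines(c(">g1", "ACXT"), fa)
  expect_error(readUpstreamFasta(fa), "X")
})

test_that("duplicate gene ids and malformed headers are rejected by name", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1", "ACGT", ">g1", "TTTT"), fa)
  expect_error(readUpstreamFasta(fa), "g1")
  writeLines(c(">g1|Chr1|x|100", "ACGT"), fa)
  expect_error(readUpstreamFasta(fa), "strand")
  writeLines(c(">g1|Chr1|+|notanumber", "ACGT"), fa)
  expect_error(readUpstreamFasta(fa), "record 1")
})

test_that("FASTA write/read round-trip preserves records byte-for-byte", {
  set.seed(11)
  n <- 8
  seqs <- vapply(50 + sample(200, n), randomSeq, character(1))
  names(seqs) <- sprintf("gene%02d", seq_len(n))
  up <- UpstreamSet(seqs, species = "sp1",
                    chromosome = sprintf("Chr%d", sample(8, n, TRUE)),
                    strand = sample(c("+", "-"), n, TRUE),
                    atgPos = sample.int(1e6, n))
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeUpstreamFasta(up, f1)
  back <- readUpstreamFasta(f1, species = "sp1")
  expect_identical(upstreamInfo(back), upstreamInfo(up))
  expect_identical(as.character(upstreamSeqs(back)),
                   as.character(upstreamSeqs(up)))
  writeUpstreamFasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("ATG-relative transform matches the stated examples", {
  expect_identical(toUpstreamFrame(991, 1000, 1000),
                   data.frame(start_up = 1L, end_up = 10L))
  expect_identical(toUpstreamFrame(1, 1, 1000),
                   data.frame(start_up = 1000L, end_up = 1000L))
  expect_identical(toUpstreamFrame(3, 5, 10),
                   data.frame(start_up = 6L, end_up = 8L))
  expect_error(toUpstreamFrame(0, 5, 10), "out of range")
  expect_error(toUpstreamFrame(3, 11, 10), "out of range")
})

test_that("the coordinate transform is a self-inverse bijection", {
  set.seed(4)
  for (L in c(1L, 2L, 17L, 1000L)) {
    i <- sample.int(L, 50, replace = TRUE)
    j <- pmin(L, i + sample(0:20, 50, replace = TRUE))
    f <- toUpstreamFrame(i, j, L)
    back <- toUpstreamFrame(f$start_up, f$end_up, L)
    expect_identical(back$start_up, i)
    expect_identical(back$end_up, j)
    ## bijectivity on single positions
    pos <- toUpstreamFrame(seq_len(L), seq_len(L), L)$start_up
    expect_identical(sort(pos), seq_len(L))
  }
})

test_that("GFF3 export writes 1-based inclusive records and reads back", {
  f <- tempfile(fileext = ".gff3")
  writeLociGFF3(data.frame(gene_id = "g1", start = 101, end = 124,
                           type = "SSR", up_start = 877, up_end = 900), f)
  lines <- readLines(f)
  expect_true(any(grepl("\t101\t124\t", lines)))
  back <- readLociGFF3(f)
  expect_identical(back$start, 101L)
  expect_identical(back$end, 124L)
  expect_identical(back$up_start, "877")
})

test_that("empty locus collections give a header-only GFF3", {
  f <- tempfile(fileext = ".gff3")
  writeLociGFF3(data.frame(gene_id = character(0), start = integer(0),
                           end = integer(0), type = character(0)), f)
  expect_identical(readLines(f), "##gff-version 3")
  expect_identical(nrow(readLociGFF3(f)), 0L)
})

test_that("GFF3 round-trips 50 random features exactly", {
  set.seed(21)
  loci <- data.frame(
    gene_id = sprintf("g%02d", sample(10, 50, TRUE)),
    start = sample.int(900, 50, TRUE), type = "CNMS_marker",
    strand = sample(c("+", "-"), 50, TRUE),
    ID = sprintf("feat%03d", 1:50), stringsAsFactors = FALSE)
  loci$end <- loci$start + sample(5:50, 50, TRUE)
  loci <- loci[, c("gene_id", "start", "end", "type", "strand", "ID")]
  up <- toUpstreamFrame(loci$start, loci$end, 1000)
  loci$up_start <- up$start_up; loci$up_end <- up$end_up
  f <- tempfile(fileext = ".gff3")
  writeLociGFF3(loci, f)
  back <- readLociGFF3(f)
  back <- back[match(loci$ID, back$ID), ]
  expect_equal(back$start, loci$start)
  expect_equal(back$end, loci$end)
  expect_equal(back$gene_id, loci$gene_id)
  expect_equal(back$strand, loci$strand)
  expect_equal(as.integer(back$up_start), loci$up_start)
  expect_equal(as.integer(back$up_end), loci$up_end)
})
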