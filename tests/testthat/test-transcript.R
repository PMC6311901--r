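test_that("FASTA records without annotation become single-exon transcripts", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tx1", "ATGAAATAG"), fa)
  ts <- read_transcripts(fa)
  expect_length(ts, 1)
  expect_equal(ts$tx1$exon_lengths, 9L)
  expect_equal(ts$tx1$intron_lengths, integer(0))
})

test_that("BED12 block structure yields exon and intron lengths", {
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  set.seed(1)
  writeLines(c(">tx1", random_dna(150)), fa)
  # blocks of 100 and 50 with a 200-nt gap, chromStart 1000 (0-based BED)
  writeLines(paste("chr1", 1000, 1350, "tx1", 0, "+", 1000, 1000, "0",
                   2, "100,50,", "0,300,", sep = "\t"), bed)
  ts <- read_transcripts(fa, bed)
  expect_equal(ts$tx1$exon_lengths, c(100L, 50L))
  expect_equal(ts$tx1$intron_lengths, 200L)
  expect_equal(ts$tx1$genome_intervals$start, c(1001L, 1301L))
  expect_equal(ts$tx1$genome_intervals$end, c(1100L, 1350L))
})

test_that("minus-strand GTF exons are reordered 5'->3'", {
  fa <- tempfile(fileext = ".fa")
  gtf <- tempfile(fileext = ".gtf")
  set.seed(2)
  writeLines(c(">txm", random_dna(80)), fa)
  writeLines(c(
    paste("chr1", "src", "exon", 2001, 2050, ".", "-", ".",
          'transcript_id "txm";', sep = "\t"),
    paste("chr1", "src", "exon", 1001, 1030, ".", "-", ".",
          'transcript_id "txm";', sep = "\t")), gtf)
  ts <- read_transcripts(fa, gtf)
  # 5'-most exon on the minus strand is the genomically rightmost one
  expect_equal(ts$txm$exon_lengths, c(50L, 30L))
  expect_equal(ts$txm$intron_lengths, 970L)
  expect_equal(ts$txm$genome_intervals$start, c(2001L, 1001L))
})

test_that("alphabet is normalized: U -> T, other symbols -> N", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">tx1", "AugWrA"), fa)
  ts <- read_transcripts(fa)
  expect_equal(ts$tx1$seq, "ATGNNA")
})

test_that("annotation/sequence length mismatch is a per-record error", {
  fa <- tempfile(fileext = ".fa")
  bed <- tempfile(fileext = ".bed")
  writeLines(c(">tx1", "ACGTACGTAC"), fa)     # 10 nt
  writeLines(paste("chr1", 0, 25, "tx1", 0, "+", 0, 0, "0",
                   2, "10,10,", "0,15,", sep = "\t"), bed)
  expect_error(read_transcripts(fa, bed), "tx1.*20.*10")
})

test_that("empty FASTA and duplicate ids are errors", {
  fa <- tempfile(fileext = ".fa")
  file.create(fa)
  expect_error(read_transcripts(fa), "empty|read|parse")
  writeLines(c(">a", "ACGTAA", ">a", "ACGTAA"), fa)
  expect_error(read_transcripts(fa), "duplicate")
})

test_that("gc_content handles ambiguity and degenerate input", {
  expect_equal(gc_content("GCGC"), 1.0)
  expect_equal(gc_content("ATAT"), 0.0)
  expect_equal(gc_content("GCATN"), 0.5)      # N excluded: 2/4
  expect_true(is.na(gc_content("NNNN")))
  expect_true(is.na(gc_content("")))
})

test_that("extract_regions partitions the transcript around each ORF", {
  t <- transcript("t", paste0("AAAAA", "ATGAAACCCGGGTTTTAG", "CCCCCCC"))
  orfs <- find_orf_set(t$seq)
  r <- extract_regions(t, orfs)
  expect_equal(r$porf$five_utr, c(1L, 5L))
  expect_equal(r$porf$orf, c(6L, 23L))
  expect_equal(r$porf$three_utr, c(24L, 30L))
  # ORF starting at position 1: empty 5'UTR
  t2 <- transcript("t2", "ATGAAATAGCC")
  r2 <- extract_regions(t2, find_orf_set(t2$seq))
  expect_equal(r2$porf$five_utr, c(1L, 0L))
  expect_equal(interval_width <- r2$porf$five_utr[2] - r2$porf$five_utr[1] + 1L, 0L)
  # no ORF at all: regions are NULL
  t3 <- transcript("t3", "CCCCCCCCCC")
  r3 <- extract_regions(t3, find_orf_set(t3$seq))
  expect_null(r3$porf)
  expect_null(r3$uorf)
  # out-of-bounds ORF errors
  expect_error(extract_regions(t3, list(porf = list(start = 5, end = 99))),
               "outside")
})

test_that("regions partition [1, len] exactly for random transcripts", {
  set.seed(11)
  for (i in 1:1000) {
    s <- random_dna(sample(30:120, 1))
    t <- transcript(paste0("r", i), s)
    r <- extract_regions(t, find_orf_set(s))
    for (kind in c("porf", "forf", "uorf")) {
      reg <- r[[kind]]
      if (is.null(reg)) next
      covered <- c(if (reg$five_utr[2] >= reg$five_utr[1])
                     reg$five_utr[1]:reg$five_utr[2],
                   reg$orf[1]:reg$orf[2],
                   if (reg$three_utr[2] >= reg$three_utr[1])
                     reg$three_utr[1]:reg$three_utr[2])
      expect_identical(as.integer(covered), seq_len(nchar(s)))
    }
  }
})

test_that("transcripts round-trip through FASTA + BED12", {
  set.seed(3)
  ts <- lapply(1:5, function(i) {
    k <- sample(1:3, 1)
    el <- sample(30:80, k)
    il <- if (k > 1) sample(50:500, k - 1) else integer(0)
    starts <- 1000 * i + cumsum(c(0L, el[-k] + il))
    gi <- data.frame(chrom = "chr7", start = starts, end = starts + el - 1L,
                     strand = "+", stringsAsFactors = FALSE)
    transcript(paste0("tx", i), random_dna(sum(el)), el, il, gi)
  })
  names(ts) <- vapply(ts, `[[`, "", "id")
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
  write_transcripts(ts, fa, bed)
  back <- read_transcripts(fa, bed)
  for (id in names(ts)) {
    expect_equal(back[[id]]$seq, ts[[id]]$seq)
    expect_equal(back[[id]]$exon_lengths, ts[[id]]$exon_lengths)
    expect_equal(back[[id]]$intron_lengths, ts[[id]]$intron_lengths)
    expect_equal(back[[id]]$genome_intervals$start, ts[[id]]$genome_intervals$start)
  }
})
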