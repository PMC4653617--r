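test_that("read_fasta parses, normalizes and validates", {
  f <- tmp_lines(c(">a", "ACGT"), ".fa")
  x <- read_fasta(f)
  expect_equal(x, tibble::tibble(id = "a", seq = "ACGT"))

  f <- tmp_lines(c(">a desc here", "acgn", ">b", "TTTT"), ".fa")
  x <- read_fasta(f)
  expect_equal(x$id, c("a", "b"))
  expect_equal(x$seq[1], "ACGN")

  f <- tmp_lines(c(">a", "ACGT", ">a", "GGGG"), ".fa")
  expect_error(read_fasta(f), "duplicate")

  f <- tmp_lines(c(">a", "ACRYGT"), ".fa")
  expect_message(x <- read_fasta(f), "IUPAC")
  expect_equal(x$seq, "ACNNGT")
})

test_that("write_fasta round-trips and wraps correctly", {
  set.seed(11)
  recs <- tibble::tibble(
    id = c("r1", "r2", "r3"),
    seq = vapply(c(125, 60, 7), function(n) {
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }, character(1))
  )
  f <- tempfile(fileext = ".fa")
  write_fasta(recs, f, line_width = 60)
  expect_identical(read_fasta(f), recs)
  lines <- readLines(f)
  r1 <- lines[(which(lines == ">r1") + 1):(which(lines == ">r2") - 1)]
  expect_equal(nchar(r1), c(60, 60, 5))

  write_fasta(recs[0, ], f)
  expect_length(readLines(f), 0)
})

test_that("read_alignments handles PSL forward, gapped and minus records", {
  one <- paste(c(10, 0, 0, 0, 0, 0, 0, 0, "+", "q1", 10, 0, 10,
                 "t1", 200, 100, 110, 1, "10,", "0,", "100,"), collapse = "\t")
  x <- read_alignments(tmp_lines(one, ".psl"))
  expect_equal(x$blocks[[1]], cbind(qstart = 0L, tstart = 100L, len = 10L))

  two <- paste(c(16, 0, 0, 0, 0, 0, 1, 5, "+", "q1", 16, 0, 16,
                 "t1", 200, 100, 121, 2, "8,8,", "0,8,", "100,113,"),
               collapse = "\t")
  x <- read_alignments(tmp_lines(two, ".psl"))
  b <- x$blocks[[1]]
  expect_true(all(diff(b[, "tstart"]) > 0))
  expect_equal(unname(b[2, "tstart"] - (b[1, "tstart"] + b[1, "len"])), 5)

  # minus strand: per-block query starts are on the reverse-complemented
  # query, so they still increase with target position
  minus <- paste(c(16, 0, 0, 0, 1, 4, 1, 7, "-", "q1", 20, 0, 20,
                   "t1", 100, 10, 33, 2, "8,8,", "0,12,", "10,25,"),
                 collapse = "\t")
  x <- read_alignments(tmp_lines(minus, ".psl"))
  b <- x$blocks[[1]]
  expect_equal(x$strand, "-")
  expect_equal(b[, "qstart"], c(0L, 12L))
  expect_true(all(diff(b[, "tstart"]) > 0))

  bad <- paste(c(10, 0, 0, 0, 0, 0, 0, 0, "+", "q1", 10, 0, 10,
                 "t1", 200, 100, 110, 2, "10,", "0,", "100,"), collapse = "\t")
  expect_error(read_alignments(tmp_lines(bad, ".psl")), "line 1")
})

test_that("alignment round trip preserves blocks on both strands", {
  px <- fixture_pipeline()
  f <- tempfile(fileext = ".psl")
  write_alignments(px$alignments, f)
  back <- read_alignments(f)
  expect_equal(back$query_id, px$alignments$query_id)
  expect_equal(back$strand, px$alignments$strand)
  expect_true(any(back$strand == "-"))
  for (i in seq_len(nrow(back))) {
    expect_equal(back$blocks[[i]], px$alignments$blocks[[i]],
                 ignore_attr = TRUE)
  }
})

test_that("GTF reading and writing round-trips coordinates byte-identically", {
  f <- tmp_lines(paste("chr1", "src", "exon", 100, 200, ".", "+", ".",
                       'transcript_id "t1"; gene_id "g1";', sep = "\t"),
                 ".gtf")
  x <- read_annotations(f)
  expect_equal(x$start, 100L)
  expect_equal(x$end, 200L)

  px <- fixture_pipeline()
  feats <- px$ann$features
  expect_equal(sum(feats$feature_type == "exon" &
                     feats$transcript_id == feats$transcript_id[2]) >= 1, TRUE)
  out1 <- tempfile(fileext = ".gtf"); out2 <- tempfile(fileext = ".gtf")
  write_annotations(feats, out1)
  back <- read_annotations(out1)
  write_annotations(back, out2)
  cols <- function(f) {
    do.call(rbind, strsplit(readLines(f), "\t"))[, 4:5]
  }
  expect_identical(cols(out1), cols(out2))
  expect_identical(back$start, feats$start)
  expect_identical(back$end, feats$end)
  expect_identical(back$transcript_id, feats$transcript_id)

  # exons of one transcript share transcript_id
  tx <- back[back$feature_type == "exon" & back$transcript_id == "tx_fill_01", ]
  expect_gt(nrow(tx), 1)
  expect_length(unique(tx$transcript_id), 1)
})

test_that("read_variants extracts depth and keeps multi-allelic records", {
  f <- tmp_lines(c("##fileformat=VCFv4.2",
                   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
                   "chr1\t100\t.\tA\tG\t60\tPASS\tDP=30",
                   "chr1\t200\t.\tC\tG,T\t50\tPASS\tDP=80"), ".vcf")
  v <- read_variants(f)
  expect_equal(v$pos, c(100L, 200L))
  expect_equal(v$depth, c(30L, 80L))
  expect_equal(v$ref[1], "A")
  expect_equal(v$alt[[1]], "G")
  expect_length(v$alt[[2]], 2)

  f <- tmp_lines(c("##fileformat=VCFv4.2",
                   "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), ".vcf")
  expect_equal(nrow(read_variants(f)), 0)
})

test_that("chain files round-trip and sums are enforced", {
  ident <- identity_chain("chr1", 1000L)
  f <- tempfile(fileext = ".chain")
  write_chain(ident, f)
  back <- read_chain(f)
  expect_length(back, 1)
  expect_equal(back[[1]]$blocks, ident$blocks)
  expect_equal(back[[1]]$source_end, 1000L)

  # 10-bp insertion in target: spans differ by 10, sums verified on read
  ins <- coord_chain("chr1", 990L, 0L, 990L, "chr1", 1000L, 0L, 1000L,
                     rbind(c(500L, 0L, 10L), c(490L, 0L, 0L)))
  write_chain(ins, f)
  back <- read_chain(f)[[1]]
  expect_equal(back$target_end - back$source_end, 10L)
  expect_equal(back$blocks, ins$blocks)

  # corrupted size column
  lines <- readLines(f)
  lines[2] <- "50x 0 10"
  expect_error(read_chain(tmp_lines(lines, ".chain")), "malformed")

  # block sums disagreeing with the declared spans
  expect_error(
    coord_chain("a", 100L, 0L, 100L, "a", 100L, 0L, 100L,
                rbind(c(50L, 0L, 0L))),
    "disagree"
  )
})

test_that("extract_unmapped selects exactly the FLAG 0x4 records", {
  sam <- tmp_lines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
                     "r1\t0\tchr1\t1\t60\t4M\t*\t0\t0\tACGT\tFFFF",
                     "r2\t4\t*\t0\t0\t*\t*\t0\t0\tGGGG\tFFFF",
                     "r3\t77\t*\t0\t0\t*\t*\t0\t0\tTTTT\tFFFF",
                     "r4\t16\tchr1\t5\t60\t4M\t*\t0\t0\tCCCC\tFFFF"), ".sam")
  um <- extract_unmapped(sam)
  expect_setequal(um$qname, c("r2", "r3")) # FLAG 77 has bit 4 set
  expect_true(all(bitwAnd(um$flag, 4L) == 4L))
  expect_setequal(um$seq[um$qname == "r2"], "GGGG")
  # selection + complement covers all records
  expect_equal(nrow(um) + 2, 4)
})
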