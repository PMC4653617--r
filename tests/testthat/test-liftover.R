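test_that("lift_interval maps through identity, insertion and deletion chains", {
  ident <- identity_chain("chr1", 1000L)
  lr <- lift_interval(ident, "chr1", 100, 200)
  expect_equal(lr$status, "full")
  expect_equal(lr$parts, tibble::tibble(start = 100L, end = 200L))

  # 10-bp target insertion at source position 50 shifts everything by 10
  ins <- coord_chain("chr1", 1000L, 0L, 1000L, "chr1", 1010L, 0L, 1010L,
                     rbind(c(50L, 0L, 10L), c(950L, 0L, 0L)))
  lr <- lift_interval(ins, "chr1", 100, 200)
  expect_equal(lr$status, "full")
  expect_equal(lr$parts, tibble::tibble(start = 110L, end = 210L))

  # interval fully inside a deleted source segment fails
  del <- coord_chain("chr1", 1000L, 0L, 1000L, "chr1", 900L, 0L, 900L,
                     rbind(c(100L, 100L, 0L), c(800L, 0L, 0L)))
  lr <- lift_interval(del, "chr1", 120, 180)
  expect_equal(lr$status, "failed")
  expect_equal(lr$mapped, 0L)

  # interval straddling the deletion lifts partially
  lr <- lift_interval(del, "chr1", 50, 250)
  expect_equal(lr$status, "partial")
  expect_equal(lr$mapped, 100L)

  # unknown chromosome
  lr <- lift_interval(ident, "chrZ", 0, 10)
  expect_equal(lr$status, "failed")
})

test_that("lifting is monotonic and inverts exactly", {
  px <- fixture_pipeline()
  ch <- px$res$chains$chr1
  set.seed(31)
  pos <- sort(sample(0:(ch$source_len - 1), 300))
  lifted <- vapply(pos, function(p) {
    lr <- lift_interval(ch, "chr1", p, p + 1)
    if (lr$status == "full") lr$parts$start else NA_integer_
  }, integer(1))
  ok <- !is.na(lifted)
  expect_true(all(diff(lifted[ok]) > 0))
  # round trip through the inverse chain
  inv <- invert_chain(ch)
  back <- vapply(lifted[ok], function(p) {
    lift_interval(inv, "chr1", p, p + 1)$parts$start
  }, integer(1))
  expect_equal(back, pos[ok])
})

test_that("lift_transcript classifies full, partial and failed lifts", {
  feats <- tibble::tibble(
    chrom = "chr1", source = "t", feature_type = "exon",
    start = c(101L, 301L, 501L), end = c(200L, 400L, 600L), strand = "+",
    transcript_id = "t1", gene_id = "g1"
  )
  up <- lift_transcript(identity_chain("chr1", 1000L), feats)
  expect_equal(up$status, "full")
  expect_equal(up$features$start, feats$start)
  expect_equal(up$features$end, feats$end)

  # chain deleting the middle exon
  del <- coord_chain("chr1", 1000L, 0L, 1000L, "chr1", 900L, 0L, 900L,
                     rbind(c(300L, 100L, 0L), c(600L, 0L, 0L)))
  up <- lift_transcript(del, feats)
  expect_equal(up$status, "partial")
  expect_true(is.na(up$features$start[2]))

  # chromosome absent from the chain set
  up <- lift_transcript(identity_chain("chr2", 1000L), feats)
  expect_equal(up$status, "failed")
})

test_that("fixture annotations lift to their truth coordinates exactly", {
  px <- fixture_pipeline()
  la <- lift_annotations(px$res$chains, px$ann$features)
  expect_true(all(la$report$status == "full"))
  for (id in la$report$transcript_id) {
    u <- la$updates[[id]]
    ex0 <- px$ann$features[px$ann$features$transcript_id == id &
                             px$ann$features$feature_type == "exon", ]
    ex0 <- ex0[order(ex0$start), ]
    expect_identical(u$features$start, ex0$start)
    expect_identical(u$features$end, ex0$end)
  }
})

test_that("classify_filled requires a draft gap and an N-free lifted span", {
  px <- fixture_pipeline()
  la <- lift_annotations(px$res$chains, px$ann$features)
  filled <- names(which(vapply(la$updates, classify_filled, logical(1),
                               draft_gaps = px$gaps,
                               patched_genome = px$res$genome)))
  expect_setequal(filled, px$ann$expected_filled)

  # a transcript never overlapping a gap is not eligible even though N-free
  bg <- la$updates[[grep("tx_bg", names(la$updates))[1]]]
  expect_false(classify_filled(bg, px$gaps, px$res$genome))

  # same transcript against the *unpatched* draft still contains N -> FALSE
  fill_id <- px$ann$expected_filled[1]
  u <- la$updates[[fill_id]]
  expect_true(classify_filled(u, px$gaps, px$res$genome))
  expect_false(classify_filled(u, px$gaps, px$draft))
})

test_that("classify_novel combines reference overlap and filled-gap location", {
  ref <- tibble::tibble(id = "ref1", chrom = "chr1",
                        start = 1000L, end = 2000L)
  gaps <- tibble::tibble(chrom = "chr1", start = 5000L, end = 5400L)
  q <- tibble::tibble(
    id = c("overlap1bp", "in_gap", "plain"),
    chrom = "chr1",
    start = c(1999L, 5100L, 8000L),
    end = c(2100L, 5200L, 8100L)
  )
  lab <- classify_novel(q, ref, gaps)
  expect_equal(lab$novel, c(FALSE, TRUE, TRUE))
  expect_equal(lab$in_filled_gap, c(FALSE, TRUE, FALSE))
})

test_that("our lifting agrees with rtracklayer::liftOver through a chain file", {
  px <- fixture_pipeline()
  f <- tempfile(fileext = ".chain")
  write_chain(px$res$chains, f)
  ch <- rtracklayer::import.chain(f)
  ex <- px$ann$features[px$ann$features$feature_type == "exon", ]
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  lo <- rtracklayer::liftOver(gr, ch)
  for (i in seq_len(nrow(ex))) {
    r <- IRanges::reduce(lo[[i]])
    p <- lift_interval(px$res$chains, ex$chrom[i], ex$start[i] - 1L,
                       ex$end[i])$parts
    expect_equal(nrow(p), length(r))
    expect_equal(p$start + 1L, GenomicRanges::start(r))
    expect_equal(p$end, GenomicRanges::end(r))
  }
})
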