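test_that("select_placements applies thresholds, secondaries and greedy overlap", {
  a <- dplyr::bind_rows(
    aln_row("c1", 600, "+", "chr1", 10000, 0, 100, 600),
    aln_row("c2", 600, "+", "chr1", 10000, 0, 2000, 600)
  )
  plan <- select_placements(a)
  expect_equal(nrow(plan$accepted), 2)
  expect_equal(nrow(plan$rejected), 0)

  # same interval, scores 900 vs 800: greedy keeps the higher
  a <- dplyr::bind_rows(
    aln_row("win", 900, "+", "chr1", 10000, 0, 100, 900),
    aln_row("lose", 800, "+", "chr1", 10000, 0, 100, 800)
  )
  plan <- select_placements(a)
  expect_equal(plan$accepted$contig_id, "win")
  expect_equal(plan$rejected$reason, "overlap")

  # identity below threshold
  a <- aln_row("bad", 600, "+", "chr1", 10000, 0, 100, 600, mismatches = 120)
  plan <- select_placements(a)
  expect_equal(nrow(plan$accepted), 0)
  expect_equal(plan$rejected$reason, "identity")

  # aligned length below threshold
  plan <- select_placements(aln_row("short", 100, "+", "chr1", 10000, 0, 5, 100))
  expect_equal(plan$rejected$reason, "aligned_len")

  # multi-chromosome contig: only the best placement is eligible
  a <- dplyr::bind_rows(
    aln_row("c1", 900, "+", "chr1", 10000, 0, 100, 900),
    aln_row("c1", 900, "+", "chr2", 10000, 0, 100, 800)
  )
  plan <- select_placements(a)
  expect_equal(plan$accepted$chrom, "chr1")
  expect_equal(plan$rejected$reason, "secondary")
})

test_that("detect_gap_spans follows the single-contig flanking rule", {
  gaps <- tibble::tibble(chrom = "chr1", start = 5L, end = 10L, length = 5L)

  # abutting flanking blocks, tol = 0: filled
  plan <- select_placements(aln_row("c1", 10, "+", "chr1", 15,
                                    c(0, 5), c(0, 10), c(5, 5)),
                            min_aligned_len = 1)
  led <- detect_gap_spans(plan, gaps, flank_tol = 0)
  expect_equal(led$status, "filled")
  expect_equal(led$filler, "c1")

  # only an upstream flank: open
  plan <- select_placements(aln_row("c1", 5, "+", "chr1", 15, 0, 0, 5),
                            min_aligned_len = 1)
  led <- detect_gap_spans(plan, gaps, flank_tol = 1000)
  expect_equal(led$status, "open")

  # flanks from two different contigs: open
  plan <- select_placements(dplyr::bind_rows(
    aln_row("up", 5, "+", "chr1", 15, 0, 0, 5),
    aln_row("down", 5, "+", "chr1", 15, 0, 10, 5)
  ), min_aligned_len = 1)
  led <- detect_gap_spans(plan, gaps, flank_tol = 1000)
  expect_equal(led$status, "open")
})

test_that("apply_patches replaces aligned spans and fills spanned gaps", {
  # identity patch: contig equals the draft region
  draft <- tibble::tibble(id = "chr1", seq = "AAAAACCCCCGGGGG")
  contigs <- tibble::tibble(id = "c1", seq = "CCCCC")
  plan <- select_placements(aln_row("c1", 5, "+", "chr1", 15, 0, 5, 5),
                            min_aligned_len = 1)
  res <- apply_patches(draft, plan, contigs)
  expect_identical(res$genome$seq, draft$seq)
  expect_equal(res$chains$chr1$blocks,
               identity_chain("chr1", 15L)$blocks)

  # gap fill through a spanning contig
  draft <- tibble::tibble(id = "chr1", seq = "AAAAANNNNNCCCCC")
  contigs <- tibble::tibble(id = "c1", seq = "AAAAATTTTTCCCCC")
  aln <- aln_row("c1", 15, "+", "chr1", 15, c(0, 10), c(0, 10), c(5, 5))
  plan <- select_placements(aln, min_aligned_len = 1)
  led <- detect_gap_spans(plan, find_gaps(draft), flank_tol = 0)
  res <- apply_patches(draft, plan, contigs, led)
  expect_equal(res$genome$seq, "AAAAATTTTTCCCCC")
  expect_equal(sum(res$ledger$status == "filled"), 1)
  expect_equal(res$ledger$patched_start, 5L)
  expect_equal(res$ledger$patched_end, 10L)
  expect_equal(assembly_stats(res$genome)$n_gaps, 0)

  # strand symmetry: the reverse-complemented contig with strand "-" gives
  # the identical patched output
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contigs$seq)))
  aln_rc <- aln_row("c1", 15, "-", "chr1", 15, c(0, 10), c(0, 10), c(5, 5))
  res_rc <- apply_patches(draft, select_placements(aln_rc, min_aligned_len = 1),
                          tibble::tibble(id = "c1", seq = rc))
  expect_identical(res_rc$genome$seq, res$genome$seq)

  # missing contig and out-of-bounds placement are errors
  expect_error(apply_patches(draft, plan, tibble::tibble(id = "x", seq = "A")),
               "missing")
  aln_oob <- aln_row("c1", 15, "+", "chr1", 30, c(0, 10), c(10, 25), c(5, 5))
  plan_oob <- select_placements(aln_oob, min_aligned_len = 1)
  expect_error(apply_patches(draft, plan_oob, contigs), "bounds")
})

test_that("contigs keeping their own Ns leave the gap open in the ledger", {
  draft <- tibble::tibble(id = "chr1", seq = "AAAAANNNNNCCCCC")
  contigs <- tibble::tibble(id = "c1", seq = "AAAAATTNTTCCCCC")
  aln <- aln_row("c1", 15, "+", "chr1", 15, c(0, 10), c(0, 10), c(5, 5))
  plan <- select_placements(aln, min_aligned_len = 1)
  led <- detect_gap_spans(plan, find_gaps(draft), flank_tol = 0)
  expect_equal(led$status, "filled")
  res <- apply_patches(draft, plan, contigs, led)
  expect_equal(res$genome$seq, "AAAAATTNTTCCCCC")
  expect_equal(res$ledger$status, "open")
})

test_that("build_chain emits a consistent partition of the chromosome", {
  # identity
  draft <- tibble::tibble(id = "chr1", seq = strrep("A", 100))
  plan <- select_placements(aln_row("c", 10, "+", "chrX", 10, 0, 0, 10),
                            min_aligned_len = 1)
  ch <- build_chain(draft, draft, plan) # no placements on chr1
  expect_equal(nrow(ch$blocks), 1)
  expect_equal(unname(ch$blocks[1, "size"]), 100L)

  # 5-bp net insertion inside one placement
  draft <- tibble::tibble(id = "chr1", seq = paste0(strrep("A", 50),
                                                    strrep("N", 10),
                                                    strrep("C", 50)))
  contig <- paste0(strrep("A", 10), strrep("T", 15), strrep("C", 10))
  aln <- aln_row("c1", 35, "+", "chr1", 110, c(0, 25), c(40, 60), c(10, 10))
  plan <- select_placements(aln, min_aligned_len = 1)
  res <- apply_patches(draft, plan, tibble::tibble(id = "c1", seq = contig))
  ch <- res$chains$chr1
  expect_equal(ch$target_len - ch$source_len, 5L)
  expect_equal(sum(ch$blocks[, "size"]) + sum(ch$blocks[, "dsource"]), 110)
  expect_equal(sum(ch$blocks[, "size"]) + sum(ch$blocks[, "dtarget"]), 115)
  expect_identical(build_chain(draft, res$genome, plan)$blocks, ch$blocks)

  # two placements on a 200-bp fixture: every draft position maps at most
  # once and the mapping is strictly monotonic
  set.seed(2)
  base <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
  draft <- tibble::tibble(id = "chr1", seq = base)
  c1 <- substr(base, 21, 60); c2 <- substr(base, 121, 180)
  aln <- dplyr::bind_rows(
    aln_row("c1", 40, "+", "chr1", 200, 0, 20, 40),
    aln_row("c2", 60, "+", "chr1", 200, 0, 120, 60)
  )
  plan <- select_placements(aln, min_aligned_len = 1)
  res <- apply_patches(draft, plan, tibble::tibble(id = c("c1", "c2"),
                                                   seq = c(c1, c2)))
  expect_identical(res$genome$seq, base)
  lifted <- vapply(0:199, function(p) {
    lr <- lift_interval(res$chains, "chr1", p, p + 1)
    if (nrow(lr$parts) == 1) lr$parts$start else NA_integer_
  }, integer(1))
  expect_false(anyNA(lifted))
  expect_false(any(duplicated(lifted)))
  expect_true(all(diff(lifted) > 0))
})

test_that("the pipeline recovers the truth genome from the masked draft", {
  px <- fixture_pipeline()
  expect_equal(nrow(px$plan$accepted), nrow(px$gaps))
  expect_identical(px$res$genome$seq, px$truth$seq)
  expect_equal(sum(px$res$ledger$status == "filled"), nrow(px$gaps))

  # length conservation
  delta <- sum((px$plan$accepted$query_end - px$plan$accepted$query_start) -
                 (px$plan$accepted$target_end - px$plan$accepted$target_start))
  expect_equal(sum(nchar(px$res$genome$seq)),
               sum(nchar(px$draft$seq)) + delta)
})

test_that("patching is idempotent", {
  px <- fixture_pipeline()
  patched <- px$res$genome
  # contigs align exactly to the patched genome at their original spans
  fl <- px$cfg$contig_flank
  aln2 <- dplyr::bind_rows(lapply(seq_len(nrow(px$gaps)), function(i) {
    qlen <- px$gaps$length[i] + 2L * fl
    strand <- px$alignments$strand[i]
    aln_row(px$alignments$query_id[i], qlen, strand, px$gaps$chrom[i],
            nchar(patched$seq[patched$id == px$gaps$chrom[i]]),
            0, px$gaps$start[i] - fl, qlen)
  }))
  plan2 <- select_placements(aln2)
  res2 <- apply_patches(patched, plan2, px$contigs)
  expect_identical(res2$genome$seq, patched$seq)
})
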