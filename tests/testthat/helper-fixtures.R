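# Shared fixtures, built once per test run. The standard pipeline fixture is
# the generator default: 2 chromosomes x 100 kb, 10 masked gaps of 200-2000
# bp, 500 bp contig flanks.

.fixture_cache <- new.env(parent = emptyenv())

fixture_pipeline <- function(seed = 42) {
  key <- paste0("pipe", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- sim_config(seed = seed)
  truth <- make_truth_genome(cfg)
  md <- mask_to_draft(truth, cfg)
  sc <- shred_contigs(truth, md$gaps, cfg)
  plan <- select_placements(sc$alignments)
  ledger <- detect_gap_spans(plan, md$gaps)
  res <- apply_patches(md$draft, plan, sc$contigs, ledger)
  ann <- make_annotations(truth, md$gaps, cfg)
  out <- list(cfg = cfg, truth = truth, draft = md$draft, gaps = md$gaps,
              contigs = sc$contigs, alignments = sc$alignments,
              plan = plan, ledger = ledger, res = res, ann = ann)
  .fixture_cache[[key]] <- out
  out
}

tmp_lines <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Single-placement alignment tibble builder for hand fixtures.
aln_row <- function(query_id, query_len, strand, target_id, target_len,
                    qstart, tstart, len, mismatches = 0L) {
  blocks <- cbind(qstart = as.integer(qstart), tstart = as.integer(tstart),
                  len = as.integer(len))
  tibble::tibble(
    query_id = query_id, query_len = as.integer(query_len), strand = strand,
    target_id = target_id, target_len = as.integer(target_len),
    matches = as.integer(sum(len) - mismatches),
    mismatches = as.integer(mismatches), blocks = list(blocks)
  )
}

end_row <- function(clone_id, end_label, chrom, start, end, strand) {
  tibble::tibble(clone_id = clone_id, end_label = end_label, chrom = chrom,
                 start = start, end = end, strand = strand)
}

# Independent N50 oracle: sort descending, walk the cumulative sum.
n50_oracle <- function(lengths) {
  lengths <- sort(lengths, decreasing = TRUE)
  total <- sum(lengths)
  acc <- 0
  for (x in lengths) {
    acc <- acc + x
    if (2 * acc >= total) return(x)
  }
}
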