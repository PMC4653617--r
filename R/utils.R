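# Internal helpers shared across modules. All internal coordinates are
# 0-based half-open; GTF/VCF values are converted at the I/O boundary.

# Reverse complement of a plain character string (ACGTN alphabet).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Deterministic per-generator substream: a label-keyed seed derived from the
# global seed, so adding a generator never perturbs existing fixtures.
# Arithmetic kept below 2^53 so it is exact in doubles; result < 2^31.
substream_seed <- function(seed, label) {
  m <- 2147483647
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) %% m
  as.integer((seed %% m + (h * 1000003) %% m) %% m)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_genome_tbl <- function(x, arg = "genome") {
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort(sprintf("`%s` must be a data frame with columns `id` and `seq`", arg))
  }
  if (anyDuplicated(x$id)) {
    abort(sprintf("duplicate sequence id in `%s`: %s", arg,
                  x$id[duplicated(x$id)][1]))
  }
  invisible(x)
}

genome_seq <- function(genome, id) {
  i <- match(id, genome$id)
  if (is.na(i)) abort(sprintf("sequence `%s` not found", id))
  genome$seq[i]
}

# Overlap of two sets of half-open intervals on named chromosomes; returns a
# tibble of (query index, subject index) hits with >= 1 shared base.
interval_overlaps <- function(q_chrom, q_start, q_end, s_chrom, s_start, s_end) {
  out <- list()
  for (ch in unique(q_chrom)) {
    qi <- which(q_chrom == ch)
    si <- which(s_chrom == ch)
    if (!length(qi) || !length(si)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = q_start[qi] + 1L, end = q_end[qi]),
      IRanges::IRanges(start = s_start[si] + 1L, end = s_end[si]),
      minoverlap = 1L
    )
    if (length(hits)) {
      out[[ch]] <- tibble(
        query = qi[S4Vectors::queryHits(hits)],
        subject = si[S4Vectors::subjectHits(hits)]
      )
    }
  }
  if (!length(out)) return(tibble(query = integer(), subject = integer()))
  bind_rows(out)
}
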