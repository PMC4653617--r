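# Gap discovery, scaffold splitting and assembly statistics. A "gap" is a
# maximal run of N of length >= min_run (default 1); shorter N runs count as
# ordinary sequence, so the min_run knob is self-consistent between gap
# statistics and contig splitting.

#' Find N-run gaps in sequences
#'
#' @param x Sequence tibble (`id`, `seq`) or a single sequence string.
#' @param min_run Minimum N-run length to report as a gap (default 1).
#' @param id Sequence name when `x` is a bare string.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open)
#'   and `length`, left to right within each sequence. Maximal runs only:
#'   flanking bases (when inside the sequence) are non-N.
#' @examples
#' find_gaps(tibble::tibble(id = "s", seq = "ACGTNNNNACGT"))
#' @export
find_gaps <- function(x, min_run = 1L, id = "seq") {
  if (is.character(x) && length(x) == 1) x <- tibble(id = id, seq = x)
  assert_genome_tbl(x, "x")
  if (min_run < 1) abort("`min_run` must be >= 1")
  out <- map(seq_len(nrow(x)), function(i) {
    m <- gregexpr("N+", x$seq[i])[[1]]
    if (m[1] == -1) return(NULL)
    len <- attr(m, "match.length")
    keep <- len >= min_run
    if (!any(keep)) return(NULL)
    tibble(chrom = x$id[i], start = as.integer(m[keep] - 1L),
           end = as.integer(m[keep] - 1L + len[keep]),
           length = as.integer(len[keep]))
  })
  out <- bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(chrom = character(), start = integer(),
                  end = integer(), length = integer())
  }
  out
}

#' Split scaffolds into contigs at gaps
#'
#' Cuts each sequence at its N-run gaps (length >= `min_run`); edge N-runs
#' are dropped. Concatenating the returned segments with the removed runs
#' reconstructs the input.
#'
#' @inheritParams find_gaps
#' @return Sequence tibble of the non-N segments, in order, ids suffixed with
#'   `_1`, `_2`, ... per source sequence. All-N sequences contribute nothing
#'   (with a warning).
#' @export
split_at_gaps <- function(x, min_run = 1L, id = "seq") {
  if (is.character(x) && length(x) == 1) x <- tibble(id = id, seq = x)
  assert_genome_tbl(x, "x")
  gaps <- find_gaps(x, min_run)
  out <- map(seq_len(nrow(x)), function(i) {
    s <- x$seq[i]; L <- nchar(s)
    g <- gaps[gaps$chrom == x$id[i], , drop = FALSE]
    cuts_start <- c(0L, g$end)
    cuts_end <- c(g$start, L)
    keep <- cuts_end > cuts_start
    if (!any(keep)) {
      warn(sprintf("sequence %s is all N; no contigs emitted", x$id[i]))
      return(NULL)
    }
    segs <- substring(s, cuts_start[keep] + 1L, cuts_end[keep])
    tibble(id = paste0(x$id[i], "_", seq_along(segs)), seq = segs)
  })
  out <- bind_rows(out)
  if (!nrow(out)) out <- tibble(id = character(), seq = character())
  out
}

#' Compute the N50 statistic
#'
#' The largest length L such that contigs of length >= L together cover at
#' least half the total (ties resolved with >=; the comparison `2 * cumsum >=
#' total` is exact in integer arithmetic).
#'
#' @param lengths Positive contig lengths in bp.
#' @return N50 in bp.
#' @examples
#' compute_n50(c(5, 4, 3, 2, 1)) # 4
#' @export
compute_n50 <- function(lengths) {
  if (!length(lengths)) abort("`lengths` must be non-empty")
  if (any(lengths < 1)) abort("`lengths` must all be >= 1")
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  total <- sum(lengths)
  lengths[which(2 * cumsum(lengths) >= total)[1]]
}

#' Assembly statistics for a genome
#'
#' Contigs are the [split_at_gaps()] segments over all records; gap fields
#' come from [find_gaps()]. When `min_run > 1` the raw (min_run = 1) gap
#' counts are reported alongside the filtered ones.
#'
#' @param genome Sequence tibble (`id`, `seq`).
#' @param min_run Minimum N-run length that counts as a gap.
#' @return An `assembly_stats` object with fields `n_contigs`, `n50`,
#'   `n_gaps`, `total_gap_length`, `total_length`, plus `n_gaps_raw` /
#'   `total_gap_length_raw` and the contig length vector (for Nx curves).
#' @export
assembly_stats <- function(genome, min_run = 1L) {
  assert_genome_tbl(genome)
  contigs <- suppressWarnings(split_at_gaps(genome, min_run))
  gaps <- find_gaps(genome, min_run)
  raw <- if (min_run > 1) find_gaps(genome, 1L) else gaps
  lens <- nchar(contigs$seq)
  structure(
    list(
      n_contigs = nrow(contigs),
      n50 = if (nrow(contigs)) compute_n50(lens) else 0,
      n_gaps = nrow(gaps),
      total_gap_length = sum(gaps$length),
      total_length = sum(nchar(genome$seq)),
      n_gaps_raw = nrow(raw),
      total_gap_length_raw = sum(raw$length),
      min_run = as.integer(min_run),
      contig_lengths = as.integer(lens)
    ),
    class = "assembly_stats"
  )
}

#' Construct assembly statistics from known totals
#'
#' For accounting over published summaries (no sequences at hand).
#'
#' @param n_contigs,n50,n_gaps,total_gap_length,total_length Summary fields;
#'   unknown fields may be `NA`.
#' @return An `assembly_stats` object.
#' @export
as_assembly_stats <- function(n_contigs = NA, n50 = NA, n_gaps = NA,
                              total_gap_length = NA, total_length = NA) {
  structure(
    list(n_contigs = n_contigs, n50 = n50, n_gaps = n_gaps,
         total_gap_length = total_gap_length, total_length = total_length,
         n_gaps_raw = n_gaps, total_gap_length_raw = total_gap_length,
         min_run = 1L, contig_lengths = integer()),
    class = "assembly_stats"
  )
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("<assembly_stats>\n")
  cat(sprintf("  contigs: %s  N50: %s bp\n",
              format(x$n_contigs, big.mark = ","),
              format(x$n50, big.mark = ",")))
  cat(sprintf("  gaps: %s  total gap length: %s bp (min_run = %d)\n",
              format(x$n_gaps, big.mark = ","),
              format(x$total_gap_length, big.mark = ","), x$min_run))
  cat(sprintf("  total length: %s bp\n", format(x$total_length, big.mark = ",")))
  invisible(x)
}

#' Account for filled gaps in assembly statistics
#'
#' Subtracts the filled gaps recorded in a gap-fill ledger from a draft's gap
#' totals, giving the remaining gap count and length.
#'
#' @param draft `assembly_stats` of the draft genome.
#' @param ledger Either a gap-fill ledger tibble (columns `status`, `length`,
#'   one row per draft gap) or a list/one-row data frame with `n_filled` and
#'   `filled_length`.
#' @return An `assembly_stats` object with updated `n_gaps` and
#'   `total_gap_length` (other fields carried over as `NA` where unknown).
#' @examples
#' draft <- as_assembly_stats(n_gaps = 187214, total_gap_length = 162452744)
#' gap_accounting(draft, list(n_filled = 65384, filled_length = 32773613))
#' @export
gap_accounting <- function(draft, ledger) {
  stopifnot(inherits(draft, "assembly_stats"))
  if (is.data.frame(ledger) && all(c("status", "length") %in% names(ledger))) {
    if (!is.na(draft$n_gaps) && nrow(ledger) != draft$n_gaps) {
      abort(sprintf("ledger has %d rows but the draft reports %d gaps",
                    nrow(ledger), draft$n_gaps))
    }
    n_filled <- sum(ledger$status == "filled")
    filled_length <- sum(ledger$length[ledger$status == "filled"])
  } else {
    n_filled <- ledger$n_filled
    filled_length <- ledger$filled_length
  }
  if (n_filled > draft$n_gaps || filled_length > draft$total_gap_length) {
    abort("filled totals exceed the draft's gap totals")
  }
  as_assembly_stats(
    n_contigs = NA, n50 = NA,
    n_gaps = draft$n_gaps - n_filled,
    total_gap_length = draft$total_gap_length - filled_length,
    total_length = draft$total_length
  )
}

#' Compare two assemblies
#'
#' @param a,b `assembly_stats` for the draft and the improved assembly.
#' @return Tibble with one row: `contigs_merged` (a minus b), `n50_ratio`
#'   (b over a, 2 decimals), `gap_count_delta` and `gap_length_delta`
#'   (b minus a).
#' @examples
#' compare_assemblies(as_assembly_stats(n_contigs = 201371, n50 = 29273),
#'                    as_assembly_stats(n_contigs = 104312, n50 = 61143))
#' @export
compare_assemblies <- function(a, b) {
  stopifnot(inherits(a, "assembly_stats"), inherits(b, "assembly_stats"))
  tibble(
    contigs_merged = a$n_contigs - b$n_contigs,
    n50_ratio = round(b$n50 / a$n50, 2),
    gap_count_delta = b$n_gaps - a$n_gaps,
    gap_length_delta = b$total_gap_length - a$total_gap_length
  )
}
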