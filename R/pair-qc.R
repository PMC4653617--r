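# Clone-end (BAC-end) pair validation: a pair is proper iff both ends map to
# the same chromosome, the leftmost/rightmost ends point towards each other
# or away (forward-reverse or reverse-forward, i.e. opposite strands), and
# the insert size stays within the library bound (350 kb by default).

#' Outermost-span insert size of an end pair
#'
#' Fragment-length convention: the distance from the leftmost start to the
#' rightmost end of the two placements.
#'
#' @param e1,e2 One-row end-placement tibbles (columns `chrom`, `start`,
#'   `end`), same chromosome.
#' @return Insert size in bp.
#' @export
insert_size <- function(e1, e2) {
  if (e1$chrom != e2$chrom) abort("ends are on different chromosomes")
  max(e1$end, e2$end) - min(e1$start, e2$start)
}

#' Classify one clone-end pair
#'
#' @param e1,e2 One-row end-placement tibbles: `clone_id`, `end_label`
#'   (`"F"`/`"R"`), `chrom`, `start`, `end` (0-based half-open), `strand`.
#' @param max_insert Maximum allowed insert size in bp (default 350000).
#' @return One-row verdict tibble: `clone_id`, `proper`, `reasons` (list
#'   column, subset of `diff_chrom`, `orientation`, `insert`; empty iff
#'   proper), `insert_size` (`NA` unless both ends share a chromosome).
#' @export
classify_pair <- function(e1, e2, max_insert = 350000) {
  if (e1$clone_id != e2$clone_id) abort("ends belong to different clones")
  if (e1$end_label == e2$end_label) {
    abort(sprintf("clone %s: end label %s supplied twice",
                  e1$clone_id, e1$end_label))
  }
  reasons <- character()
  ins <- NA_real_
  if (e1$chrom != e2$chrom) {
    reasons <- "diff_chrom"
  } else {
    left <- if (e1$start <= e2$start) e1 else e2
    right <- if (e1$start <= e2$start) e2 else e1
    if (left$strand == right$strand) reasons <- c(reasons, "orientation")
    ins <- insert_size(e1, e2)
    if (ins > max_insert) reasons <- c(reasons, "insert")
  }
  tibble(clone_id = e1$clone_id, proper = length(reasons) == 0,
         reasons = list(reasons), insert_size = ins)
}

#' Classify all clone-end pairs in a placement table
#'
#' When several placements exist for one end, the single best by `matches` is
#' kept (ties broken by leftmost chromosome then start); an end whose best
#' score is tied across different chromosomes is ambiguous and the clone is
#' marked `unpaired`, as is a clone with fewer than two ends.
#'
#' @param placements End-placement tibble (`clone_id`, `end_label`, `chrom`,
#'   `start`, `end`, `strand`, optional `matches`).
#' @param max_insert Maximum allowed insert size in bp.
#' @return Verdict tibble, one row per clone, as in [classify_pair()] with
#'   `unpaired` as an additional possible reason.
#' @export
pair_verdicts <- function(placements, max_insert = 350000) {
  if (!"matches" %in% names(placements)) placements$matches <- 0L
  best_end <- function(rows) {
    rows <- arrange(rows, desc(.data$matches), .data$chrom, .data$start)
    top <- rows$matches == rows$matches[1]
    if (sum(top) > 1 && length(unique(rows$chrom[top])) > 1) {
      return(NULL) # ambiguous across chromosomes
    }
    rows[1, ]
  }
  out <- map(split(placements, placements$clone_id), function(cl) {
    ends <- split(cl, cl$end_label)
    if (length(ends) < 2) {
      return(tibble(clone_id = cl$clone_id[1], proper = FALSE,
                    reasons = list("unpaired"), insert_size = NA_real_))
    }
    e1 <- best_end(ends[[1]]); e2 <- best_end(ends[[2]])
    if (is.null(e1) || is.null(e2)) {
      return(tibble(clone_id = cl$clone_id[1], proper = FALSE,
                    reasons = list("unpaired"), insert_size = NA_real_))
    }
    classify_pair(e1, e2, max_insert)
  })
  bind_rows(out)
}

#' Summarise pair verdicts
#'
#' @param verdicts Verdict tibble from [classify_pair()]/[pair_verdicts()].
#' @param bin_width Insert-size histogram bin width in bp (default 10000).
#' @return A `pair_summary`: proper count, total, mapping rate (percent, two
#'   decimals), per-reason failure counts, and an insert-size histogram over
#'   proper pairs.
#' @export
pair_summary <- function(verdicts, bin_width = 10000) {
  total <- nrow(verdicts)
  proper <- sum(verdicts$proper)
  rate <- if (total > 0) round(100 * proper / total, 2) else 0
  reasons <- unlist(verdicts$reasons)
  reason_counts <- as_tibble(as.data.frame(table(reason = reasons),
                                           stringsAsFactors = FALSE))
  if (!nrow(reason_counts)) {
    reason_counts <- tibble(reason = character(), Freq = integer())
  }
  names(reason_counts) <- c("reason", "n")
  ins <- verdicts$insert_size[verdicts$proper]
  ins <- ins[!is.na(ins)]
  hist <- if (length(ins)) {
    bin <- floor(ins / bin_width) * bin_width
    h <- as.data.frame(table(bin_start = bin), stringsAsFactors = FALSE)
    tibble(bin_start = as.numeric(h$bin_start),
           bin_end = as.numeric(h$bin_start) + bin_width,
           n = as.integer(h$Freq))
  } else {
    tibble(bin_start = numeric(), bin_end = numeric(), n = integer())
  }
  structure(
    list(n_proper = proper, n_total = total, rate = rate,
         reason_counts = reason_counts, histogram = hist,
         bin_width = bin_width),
    class = "pair_summary"
  )
}

#' @export
print.pair_summary <- function(x, ...) {
  cat(sprintf("<pair_summary> %d / %d pairs proper (mapping rate: %.2f%%)\n",
              x$n_proper, x$n_total, x$rate))
  if (nrow(x$reason_counts)) {
    cat("  failures:",
        paste(sprintf("%s=%d", x$reason_counts$reason, x$reason_counts$n),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parse clone id and end label from alignment query names
#'
#' Default pattern: names ending in `/F` or `/R`.
#'
#' @param alignments Alignment tibble from [read_alignments()].
#' @param pattern Regular expression with two capture groups (clone id, end
#'   label).
#' @return End-placement tibble suitable for [pair_verdicts()], using each
#'   alignment's outer target interval.
#' @export
end_placements <- function(alignments, pattern = "^(.*)/([FR])$") {
  m <- regmatches(alignments$query_id, regexec(pattern, alignments$query_id))
  bad <- lengths(m) != 3
  if (any(bad)) {
    abort(sprintf("query name does not match the clone/end pattern: %s",
                  alignments$query_id[bad][1]))
  }
  pl <- bind_rows(map(seq_len(nrow(alignments)), function(i) {
    placement_from_alignment(alignments[i, ])
  }))
  tibble(
    clone_id = map_chr(m, function(g) g[2]),
    end_label = map_chr(m, function(g) g[3]),
    chrom = pl$chrom, start = pl$target_start, end = pl$target_end,
    strand = pl$strand,
    matches = alignments$matches
  )
}
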