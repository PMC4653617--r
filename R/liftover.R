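# Coordinate conversion through chains, transcript lift classification, and
# novelty labelling of cDNA alignments against filled gaps.

chain_for <- function(chains, chrom) {
  if (inherits(chains, "coord_chain")) {
    if (chains$source_id == chrom) return(chains) else return(NULL)
  }
  ids <- map_chr(chains, function(ch) ch$source_id)
  i <- match(chrom, ids)
  if (is.na(i)) NULL else chains[[i]]
}

#' Lift an interval through a chain
#'
#' Maps a 0-based half-open source interval through the chain's aligned
#' blocks. Bases falling in source-only (deleted) segments are unmapped.
#'
#' @param chains A [coord_chain] or list of them (matched by source id).
#' @param chrom Source sequence name.
#' @param start,end 0-based half-open interval.
#' @return A list of class `lift_result`: `parts` (tibble of mapped target
#'   sub-intervals, merged when contiguous), `status` (`"full"` if every base
#'   maps, `"failed"` if none does — including an unknown chromosome —
#'   else `"partial"`), and `mapped` (base count).
#' @export
lift_interval <- function(chains, chrom, start, end) {
  if (end <= start) abort("`end` must be > `start`")
  ch <- chain_for(chains, chrom)
  empty <- tibble(start = integer(), end = integer())
  if (is.null(ch)) {
    return(structure(list(parts = empty, status = "failed", mapped = 0L,
                          reason = sprintf("no chain for %s", chrom)),
                     class = "lift_result"))
  }
  if (ch$target_strand != "+") {
    abort("only plus-strand chains are supported")
  }
  b <- ch$blocks
  s <- ch$source_start; t <- ch$target_start
  parts <- list()
  for (i in seq_len(nrow(b))) {
    bs <- s; be <- s + b[i, "size"]
    lo <- max(start, bs); hi <- min(end, be)
    if (lo < hi) {
      parts[[length(parts) + 1L]] <- c(t + (lo - bs), t + (hi - bs))
    }
    s <- be + b[i, "dsource"]
    t <- t + b[i, "size"] + b[i, "dtarget"]
  }
  if (!length(parts)) {
    return(structure(list(parts = empty, status = "failed", mapped = 0L,
                          reason = "interval falls entirely in unmapped sequence"),
                     class = "lift_result"))
  }
  m <- do.call(rbind, parts)
  # merge contiguous parts
  merged <- list(m[1, ])
  for (i in seq_len(nrow(m))[-1]) {
    last <- merged[[length(merged)]]
    if (m[i, 1] == last[2]) {
      merged[[length(merged)]][2] <- m[i, 2]
    } else {
      merged[[length(merged) + 1L]] <- m[i, ]
    }
  }
  m <- do.call(rbind, merged)
  mapped <- sum(m[, 2] - m[, 1])
  structure(
    list(parts = tibble(start = as.integer(m[, 1]), end = as.integer(m[, 2])),
         status = if (mapped == end - start) "full" else "partial",
         mapped = as.integer(mapped)),
    class = "lift_result"
  )
}

#' @export
print.lift_result <- function(x, ...) {
  cat(sprintf("<lift_result> %s, %d base(s) mapped in %d part(s)\n",
              x$status, x$mapped, nrow(x$parts)))
  invisible(x)
}

#' Invert a chain
#'
#' Swaps source and target so that lifted coordinates can be mapped back.
#'
#' @param chain A plus-strand [coord_chain].
#' @return The inverse [coord_chain].
#' @export
invert_chain <- function(chain) {
  stopifnot(inherits(chain, "coord_chain"))
  if (chain$target_strand != "+") abort("only plus-strand chains can be inverted")
  b <- chain$blocks
  coord_chain(chain$target_id, chain$target_len, chain$target_start,
              chain$target_end, chain$source_id, chain$source_len,
              chain$source_start, chain$source_end,
              cbind(b[, "size"], b[, "dtarget"], b[, "dsource"]),
              score = chain$score)
}

#' Lift one transcript's features through a chain
#'
#' Exons lift independently; the transcript is `"full"` iff every base of
#' every exon maps, `"failed"` iff no base maps (e.g. a chromosome absent
#' from the chain set), else `"partial"`. Partially lifted transcripts keep
#' their per-exon fragments rather than being dropped.
#'
#' @param chains A [coord_chain] or list of them.
#' @param features GTF-convention tibble (1-based inclusive) of one
#'   transcript's exon features.
#' @return A list of class `transcript_update`: `transcript_id`, `gene_id`,
#'   `status`, `features` (lifted exons, 1-based; unmapped exons get `NA`
#'   coordinates and per-base fragments in the `parts` list column),
#'   `draft_span` and `lifted_span` (0-based half-open genomic spans).
#' @export
lift_transcript <- function(chains, features) {
  ex <- features[features$feature_type == "exon", , drop = FALSE]
  if (!nrow(ex)) abort("transcript has no exon features")
  if (length(unique(ex$transcript_id)) != 1) {
    abort("features must belong to a single transcript")
  }
  ex <- arrange(ex, .data$start)
  lifts <- map(seq_len(nrow(ex)), function(i) {
    lift_interval(chains, ex$chrom[i], ex$start[i] - 1L, ex$end[i])
  })
  mapped <- map_int(lifts, function(l) l$mapped)
  total <- sum(ex$end - ex$start + 1L)
  status <- if (sum(mapped) == total) "full" else if (sum(mapped) == 0) "failed" else "partial"
  lifted <- ex
  lifted$start <- map_int(lifts, function(l) {
    if (nrow(l$parts)) as.integer(min(l$parts$start) + 1L) else NA_integer_
  })
  lifted$end <- map_int(lifts, function(l) {
    if (nrow(l$parts)) as.integer(max(l$parts$end)) else NA_integer_
  })
  lifted$parts <- map(lifts, function(l) l$parts)
  draft_span <- c(min(ex$start) - 1L, max(ex$end))
  lifted_span <- if (status == "failed") c(NA_integer_, NA_integer_) else {
    c(min(lifted$start, na.rm = TRUE) - 1L, max(lifted$end, na.rm = TRUE))
  }
  structure(
    list(transcript_id = ex$transcript_id[1],
         gene_id = ex$gene_id[1] %||% NA_character_,
         status = status, features = lifted,
         chrom = ex$chrom[1],
         draft_span = draft_span, lifted_span = lifted_span),
    class = "transcript_update"
  )
}

#' @export
print.transcript_update <- function(x, ...) {
  cat(sprintf("<transcript_update> %s: %s (%d exon(s))\n",
              x$transcript_id, x$status, nrow(x$features)))
  invisible(x)
}

#' Lift all transcripts in an annotation set
#'
#' @param chains A [coord_chain] or list of them.
#' @param features GTF-convention feature tibble (from [read_annotations()]).
#' @return List with `updates` (list of [lift_transcript()] results) and
#'   `report` (tibble: `transcript_id`, `gene_id`, `status`).
#' @export
lift_annotations <- function(chains, features) {
  ex <- features[features$feature_type == "exon", , drop = FALSE]
  ids <- unique(ex$transcript_id)
  updates <- map(ids, function(id) {
    lift_transcript(chains, ex[ex$transcript_id == id, , drop = FALSE])
  })
  names(updates) <- ids
  report <- tibble(
    transcript_id = ids,
    gene_id = map_chr(updates, function(u) u$gene_id %||% NA_character_),
    status = map_chr(updates, function(u) u$status)
  )
  list(updates = updates, report = report)
}

#' Was a gap-containing transcript completely filled?
#'
#' TRUE iff the transcript lifted fully, its draft genomic span (introns
#' included) overlapped at least one draft gap, and its lifted span in the
#' patched genome contains no N.
#'
#' @param update A `transcript_update` from [lift_transcript()].
#' @param draft_gaps Gap tibble from [find_gaps()] on the draft.
#' @param patched_genome Patched sequence tibble (`id`, `seq`).
#' @param exon_only Intersect gaps with exons only instead of the genomic
#'   span (default FALSE).
#' @return Logical flag.
#' @export
classify_filled <- function(update, draft_gaps, patched_genome,
                            exon_only = FALSE) {
  stopifnot(inherits(update, "transcript_update"))
  if (update$status != "full") return(FALSE)
  g <- draft_gaps[draft_gaps$chrom == update$chrom, , drop = FALSE]
  if (!nrow(g)) return(FALSE)
  if (exon_only) {
    ex <- update$features
    hit <- any(map_lgl(seq_len(nrow(ex)), function(i) {
      any(g$start < ex$end[i] & (ex$start[i] - 1L) < g$end)
    }))
  } else {
    hit <- any(g$start < update$draft_span[2] & update$draft_span[1] < g$end)
  }
  if (!hit) return(FALSE)
  pseq <- genome_seq(patched_genome, update$chrom)
  slice <- substr(pseq, update$lifted_span[1] + 1L, update$lifted_span[2])
  !grepl("N", slice, fixed = TRUE)
}

#' Label query alignments as novel and/or located in filled gaps
#'
#' `novel` means zero-base overlap (strand-ignorant by default) with every
#' reference alignment; `in_filled_gap` means the query interval intersects
#' the patched-coordinate image of a ledger-filled gap.
#'
#' @param query_alignments,reference_alignments Interval tibbles with columns
#'   `id`, `chrom`, `start`, `end` (0-based half-open, on the patched
#'   genome), or alignment tibbles from [read_alignments()] (outer target
#'   intervals are used).
#' @param filled_gap_images Tibble with `chrom`, `start`, `end` of filled-gap
#'   images in patched coordinates (e.g. ledger columns `patched_start`,
#'   `patched_end`).
#' @param strand_aware Restrict overlap to equal strands (requires a `strand`
#'   column in both alignment sets; default FALSE).
#' @return Tibble: `id`, `novel`, `in_filled_gap`, one row per query.
#' @export
classify_novel <- function(query_alignments, reference_alignments,
                           filled_gap_images, strand_aware = FALSE) {
  as_intervals <- function(x, what) {
    if (all(c("blocks", "target_id") %in% names(x))) {
      pl <- bind_rows(map(seq_len(nrow(x)), function(i) {
        placement_from_alignment(x[i, ])
      }))
      tibble(id = pl$contig_id, chrom = pl$chrom,
             start = pl$target_start, end = pl$target_end,
             strand = pl$strand)
    } else {
      if (!all(c("chrom", "start", "end") %in% names(x))) {
        abort(sprintf("`%s` needs columns chrom, start, end", what))
      }
      x$id <- x$id %||% as.character(seq_len(nrow(x)))
      x
    }
  }
  q <- as_intervals(query_alignments, "query_alignments")
  r <- as_intervals(reference_alignments, "reference_alignments")
  hits <- interval_overlaps(q$chrom, q$start, q$end, r$chrom, r$start, r$end)
  if (strand_aware && nrow(hits)) {
    hits <- hits[q$strand[hits$query] == r$strand[hits$subject], , drop = FALSE]
  }
  novel <- !(seq_len(nrow(q)) %in% hits$query)
  fg <- filled_gap_images[!is.na(filled_gap_images$start) &
                            !is.na(filled_gap_images$end), , drop = FALSE]
  ghits <- interval_overlaps(q$chrom, q$start, q$end, fg$chrom, fg$start, fg$end)
  tibble(id = q$id, novel = novel,
         in_filled_gap = seq_len(nrow(q)) %in% ghits$query)
}
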