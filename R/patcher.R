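# Reference-guided patching: turn contig-to-draft alignments into a
# non-overlapping patch plan, rebuild each chromosome by splicing accepted
# contigs over their aligned spans (so contig interiors fill the draft gaps
# they bridge), and emit a UCSC-style chain mapping draft to patched
# coordinates.

placement_from_alignment <- function(aln_row) {
  b <- aln_row$blocks[[1]]
  n <- nrow(b)
  tibble(
    contig_id = aln_row$query_id,
    chrom = aln_row$target_id,
    strand = aln_row$strand,
    target_start = b[1, "tstart"],
    target_end = b[n, "tstart"] + b[n, "len"],
    query_start = b[1, "qstart"],
    query_end = b[n, "qstart"] + b[n, "len"],
    query_len = aln_row$query_len,
    target_len = aln_row$target_len,
    identity = aln_row$matches / (aln_row$matches + aln_row$mismatches),
    aligned_len = sum(b[, "len"]),
    blocks = list(b)
  )
}

#' Select a non-overlapping set of contig placements
#'
#' Candidates are scored by `aligned_len * identity`. For a contig with
#' several candidate placements only the best-scoring one is eligible (others
#' rejected as `"secondary"`, preventing sequence duplication); candidates
#' below the identity or length thresholds are rejected with that reason;
#' the rest are accepted greedily in descending score order (ties broken by
#' contig id, then target start), rejecting any candidate whose target
#' interval overlaps an already accepted one (`"overlap"`).
#'
#' @param alignments Alignment tibble from [read_alignments()].
#' @param min_identity Minimum fraction of matching bases (default 0.95).
#' @param min_aligned_len Minimum total aligned length in bp (default 500).
#' @return A `patch_plan`: list with `accepted` (placements sorted by
#'   chromosome and target start) and `rejected` (with a `reason` column).
#' @export
select_placements <- function(alignments, min_identity = 0.95,
                              min_aligned_len = 500) {
  cand <- bind_rows(map(seq_len(nrow(alignments)), function(i) {
    placement_from_alignment(alignments[i, ])
  }))
  empty <- cand[0, ]
  if (!nrow(cand)) {
    return(structure(list(accepted = empty,
                          rejected = mutate(empty, reason = character())),
                     class = "patch_plan"))
  }
  cand$score <- cand$aligned_len * cand$identity
  rejected <- list()
  # one placement per contig
  cand <- arrange(cand, desc(.data$score), .data$contig_id, .data$target_start)
  dup <- duplicated(cand$contig_id)
  rejected$secondary <- mutate(cand[dup, ], reason = "secondary")
  cand <- cand[!dup, ]
  bad_id <- cand$identity < min_identity
  rejected$identity <- mutate(cand[bad_id, ], reason = "identity")
  cand <- cand[!bad_id, ]
  bad_len <- cand$aligned_len < min_aligned_len
  rejected$aligned_len <- mutate(cand[bad_len, ], reason = "aligned_len")
  cand <- cand[!bad_len, ]
  accepted_idx <- integer()
  taken <- list() # per chrom: matrix of accepted [start,end)
  overlap_idx <- integer()
  for (i in seq_len(nrow(cand))) {
    ch <- cand$chrom[i]
    iv <- taken[[ch]]
    s <- cand$target_start[i]; e <- cand$target_end[i]
    clash <- !is.null(iv) && any(iv[, 1] < e & s < iv[, 2])
    if (clash) {
      overlap_idx <- c(overlap_idx, i)
    } else {
      accepted_idx <- c(accepted_idx, i)
      taken[[ch]] <- rbind(iv, c(s, e))
    }
  }
  rejected$overlap <- mutate(cand[overlap_idx, ], reason = "overlap")
  accepted <- arrange(cand[accepted_idx, ], .data$chrom, .data$target_start)
  rej <- bind_rows(rejected)
  if (!nrow(rej)) rej <- mutate(empty, reason = character())
  structure(list(accepted = accepted, rejected = rej), class = "patch_plan")
}

#' @export
print.patch_plan <- function(x, ...) {
  cat(sprintf("<patch_plan> %d accepted, %d rejected placement(s)\n",
              nrow(x$accepted), nrow(x$rejected)))
  if (nrow(x$rejected)) {
    tab <- table(x$rejected$reason)
    cat("  rejected:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Identify draft gaps spanned by accepted placements
#'
#' A gap is fillable when a single accepted placement has one alignment block
#' ending within `flank_tol` bp upstream of the gap start and another block
#' starting within `flank_tol` bp downstream of the gap end, and the contig's
#' unaligned interior between those blocks is non-empty (or the blocks abut
#' the gap exactly). Flanking blocks from two different contigs never fill a
#' gap.
#'
#' @param plan A `patch_plan` from [select_placements()].
#' @param gaps Gap tibble from [find_gaps()] on the draft.
#' @param flank_tol Maximum distance in bp between a flanking block and the
#'   gap edge (default 1000).
#' @return A gap-fill ledger tibble: `chrom`, `gap_start`, `gap_end`,
#'   `length`, `status` (`"filled"`/`"open"`), `filler` (contig id or `NA`),
#'   and the contig-interior query interval used for the fill.
#' @export
detect_gap_spans <- function(plan, gaps, flank_tol = 1000) {
  stopifnot(inherits(plan, "patch_plan"), flank_tol >= 0)
  acc <- plan$accepted
  out <- map(seq_len(nrow(gaps)), function(g) {
    row <- tibble(chrom = gaps$chrom[g], gap_start = gaps$start[g],
                  gap_end = gaps$end[g], length = gaps$length[g],
                  status = "open", filler = NA_character_,
                  q_fill_start = NA_integer_, q_fill_end = NA_integer_)
    pl <- acc[acc$chrom == gaps$chrom[g], , drop = FALSE]
    for (p in seq_len(nrow(pl))) {
      b <- pl$blocks[[p]]
      tend <- b[, "tstart"] + b[, "len"]
      up <- which(tend <= gaps$start[g] & tend >= gaps$start[g] - flank_tol)
      down <- which(b[, "tstart"] >= gaps$end[g] &
                      b[, "tstart"] <= gaps$end[g] + flank_tol)
      if (!length(up) || !length(down)) next
      up <- up[which.max(tend[up])]
      down <- down[which.min(b[down, "tstart"])]
      if (up >= down) next
      qi_start <- b[up, "qstart"] + b[up, "len"]
      qi_end <- b[down, "qstart"]
      abuts <- tend[up] == gaps$start[g] && b[down, "tstart"] == gaps$end[g]
      if (qi_end > qi_start || abuts) {
        row$status <- "filled"
        row$filler <- pl$contig_id[p]
        row$q_fill_start <- as.integer(qi_start)
        row$q_fill_end <- as.integer(qi_end)
        break
      }
    }
    row
  })
  out <- bind_rows(out)
  if (!nrow(out)) {
    out <- tibble(chrom = character(), gap_start = integer(),
                  gap_end = integer(), length = integer(), status = character(),
                  filler = character(), q_fill_start = integer(),
                  q_fill_end = integer())
  }
  out
}

# Chain geometry for one chromosome given its accepted placements (sorted by
# target start). Returns the block triples, patched length, and for each
# placement the patched coordinate of its outer query start.
chain_from_placements <- function(chrom_len, placements) {
  sizes <- integer(); dss <- integer(); dts <- integer()
  pending <- 0L # open match run
  add_match <- function(n) {
    if (n > 0) pending <<- pending + as.integer(n)
  }
  add_gap <- function(ds, dt) {
    if (ds == 0 && dt == 0) return()
    if (pending == 0L) abort("chain gap with no preceding aligned block")
    sizes <<- c(sizes, pending); dss <<- c(dss, as.integer(ds))
    dts <<- c(dts, as.integer(dt)); pending <<- 0L
  }
  cursor <- 0L
  patched_at <- 0L
  piece_starts <- integer(nrow(placements))
  for (p in seq_len(nrow(placements))) {
    ts <- placements$target_start[p]; te <- placements$target_end[p]
    if (te > chrom_len) {
      abort(sprintf("placement of %s exceeds chromosome bounds (%d > %d)",
                    placements$contig_id[p], te, chrom_len))
    }
    if (ts < cursor) abort("accepted placements overlap")
    add_match(ts - cursor)
    patched_at <- patched_at + (ts - cursor)
    piece_starts[p] <- patched_at
    b <- placements$blocks[[p]]
    for (i in seq_len(nrow(b))) {
      add_match(b[i, "len"])
      if (i < nrow(b)) {
        add_gap(b[i + 1, "tstart"] - (b[i, "tstart"] + b[i, "len"]),
                b[i + 1, "qstart"] - (b[i, "qstart"] + b[i, "len"]))
      }
    }
    patched_at <- patched_at +
      (placements$query_end[p] - placements$query_start[p])
    cursor <- te
  }
  add_match(chrom_len - cursor)
  patched_at <- patched_at + (chrom_len - cursor)
  if (pending > 0L) {
    sizes <- c(sizes, pending); dss <- c(dss, 0L); dts <- c(dts, 0L)
  } else if (length(sizes)) {
    # chain must end on a match; guaranteed because placements end on a block
    dss[length(dss)] <- dss[length(dss)]
  }
  list(blocks = cbind(size = sizes, dsource = dss, dtarget = dts),
       patched_len = patched_at, piece_starts = piece_starts)
}

#' Apply a patch plan to the draft genome
#'
#' For each accepted placement the draft bases in the placement's outer
#' target interval are replaced by the contig subsequence spanning its outer
#' query interval (reverse-complemented for minus-strand placements);
#' untouched regions are copied verbatim. A chain records every kept and
#' replaced segment, and ledger statuses are recomputed on the patched
#' sequence: a gap whose replacing contig interior still contains N is marked
#' open (the contig's own Ns are kept).
#'
#' @param draft Draft genome tibble (`id`, `seq`).
#' @param plan `patch_plan` from [select_placements()].
#' @param contigs Contig sequence tibble (`id`, `seq`).
#' @param ledger Optional gap-fill ledger from [detect_gap_spans()]; when
#'   supplied, fill statuses are re-checked against the patched sequence and
#'   the patched-coordinate image of each filled gap is recorded.
#' @return A `patch_result`: list with `genome` (patched sequence tibble),
#'   `chains` (named list of [coord_chain], one per draft sequence) and
#'   `ledger` (with `patched_start`/`patched_end` columns).
#' @export
apply_patches <- function(draft, plan, contigs, ledger = NULL) {
  assert_genome_tbl(draft, "draft")
  assert_genome_tbl(contigs, "contigs")
  stopifnot(inherits(plan, "patch_plan"))
  if (is.null(ledger)) {
    ledger <- detect_gap_spans(plan, find_gaps(draft))
  }
  missing_ids <- setdiff(plan$accepted$contig_id, contigs$id)
  if (length(missing_ids)) {
    abort(sprintf("contig id missing from contig set: %s", missing_ids[1]))
  }
  ledger$patched_start <- NA_integer_
  ledger$patched_end <- NA_integer_
  patched <- character(nrow(draft))
  chains <- list()
  for (ci in seq_len(nrow(draft))) {
    chrom <- draft$id[ci]
    dseq <- draft$seq[ci]
    L <- nchar(dseq)
    pl <- plan$accepted[plan$accepted$chrom == chrom, , drop = FALSE]
    geo <- chain_from_placements(L, pl)
    pieces <- character(2 * nrow(pl) + 1)
    cursor <- 0L
    for (p in seq_len(nrow(pl))) {
      pieces[2 * p - 1] <- substr(dseq, cursor + 1L, pl$target_start[p])
      cs <- genome_seq(contigs, pl$contig_id[p])
      if (nchar(cs) != pl$query_len[p]) {
        abort(sprintf("contig %s length (%d) disagrees with alignment (%d)",
                      pl$contig_id[p], nchar(cs), pl$query_len[p]))
      }
      if (pl$strand[p] == "-") cs <- revcomp(cs)
      pieces[2 * p] <- substr(cs, pl$query_start[p] + 1L, pl$query_end[p])
      cursor <- pl$target_end[p]
    }
    pieces[2 * nrow(pl) + 1] <- substr(dseq, cursor + 1L, L)
    pseq <- paste(pieces, collapse = "")
    stopifnot(nchar(pseq) == geo$patched_len)
    patched[ci] <- pseq
    chains[[chrom]] <- coord_chain(
      chrom, L, 0L, L, chrom, geo$patched_len, 0L, geo$patched_len,
      geo$blocks
    )
    # recompute ledger statuses on the patched sequence
    li <- which(ledger$chrom == chrom & ledger$status == "filled")
    for (g in li) {
      p <- which(pl$contig_id == ledger$filler[g])
      if (!length(p)) { ledger$status[g] <- "open"; next }
      p <- p[1]
      fs <- geo$piece_starts[p] + (ledger$q_fill_start[g] - pl$query_start[p])
      fe <- geo$piece_starts[p] + (ledger$q_fill_end[g] - pl$query_start[p])
      slice <- substr(pseq, fs + 1L, fe)
      if (grepl("N", slice, fixed = TRUE)) {
        ledger$status[g] <- "open"
      } else {
        ledger$patched_start[g] <- as.integer(fs)
        ledger$patched_end[g] <- as.integer(fe)
      }
    }
  }
  structure(
    list(genome = tibble(id = draft$id, seq = patched),
         chains = chains, ledger = ledger),
    class = "patch_result"
  )
}

#' @export
print.patch_result <- function(x, ...) {
  cat(sprintf("<patch_result> %d sequence(s), %d gap(s) filled of %d\n",
              nrow(x$genome), sum(x$ledger$status == "filled"),
              nrow(x$ledger)))
  invisible(x)
}

#' Build the draft-to-patched chain for one chromosome
#'
#' Recomputes, from the plan alone, the chain that [apply_patches()] emits
#' for one chromosome, and checks it against the patched sequence length.
#'
#' @param draft_record,patched_record One-row sequence tibbles for the same
#'   chromosome before and after patching.
#' @param plan The `patch_plan` used to produce `patched_record`.
#' @return A [coord_chain].
#' @export
build_chain <- function(draft_record, patched_record, plan) {
  chrom <- draft_record$id[1]
  L <- nchar(draft_record$seq[1])
  pl <- plan$accepted[plan$accepted$chrom == chrom, , drop = FALSE]
  geo <- chain_from_placements(L, pl)
  if (geo$patched_len != nchar(patched_record$seq[1])) {
    abort(sprintf("plan yields %d bp but patched sequence has %d bp",
                  geo$patched_len, nchar(patched_record$seq[1])))
  }
  coord_chain(chrom, L, 0L, L, chrom, geo$patched_len, 0L, geo$patched_len,
              geo$blocks)
}
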