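#' Read pairwise alignments (PSL or generic tab dialect)
#'
#' Parses BLAT-style PSL (21 columns, 0-based half-open) into one alignment
#' record per row with a block list. Blocks are kept in target-forward order;
#' for minus-strand records the per-block query starts follow the PSL
#' convention of coordinates on the reverse-complemented query, so block
#' query starts increase with target position for both strands. Header lines
#' (`psLayout`, separators) are skipped.
#'
#' Repeat matches and N bases (PSL columns 3-4) are folded into `matches` so
#' that `matches + mismatches` always equals the total aligned block length.
#'
#' @param path Path to the alignment file.
#' @param dialect `"psl"` (default) or `"tab12"`, a minimal 12-column generic
#'   dialect: score, query_id, query_len, strand, target_id, target_len,
#'   matches, mismatches, block_count, blockSizes, qStarts, tStarts.
#' @return Tibble with columns `query_id`, `query_len`, `strand`, `target_id`,
#'   `target_len`, `matches`, `mismatches`, and `blocks` (list of matrices with
#'   columns `qstart`, `tstart`, `len`).
#' @export
read_alignments <- function(path, dialect = c("psl", "tab12")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- grepl("^\\d", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(tibble(query_id = character(), query_len = integer(),
                  strand = character(), target_id = character(),
                  target_len = integer(), matches = integer(),
                  mismatches = integer(), blocks = list()))
  }
  parse_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t")[[1]]
    if (dialect == "psl") {
      if (length(f) < 21) {
        abort(sprintf("line %d: expected 21 PSL columns, found %d",
                      lineno[k], length(f)))
      }
      matches <- as.integer(f[1]) + as.integer(f[3]) + as.integer(f[4])
      mism <- as.integer(f[2])
      strand <- f[9]; qname <- f[10]; qsize <- as.integer(f[11])
      tname <- f[14]; tsize <- as.integer(f[15])
      bcount <- as.integer(f[18])
      sizes <- parse_ints(f[19]); qst <- parse_ints(f[20]); tst <- parse_ints(f[21])
    } else {
      if (length(f) < 12) {
        abort(sprintf("line %d: expected 12 columns, found %d",
                      lineno[k], length(f)))
      }
      qname <- f[2]; qsize <- as.integer(f[3]); strand <- f[4]
      tname <- f[5]; tsize <- as.integer(f[6])
      matches <- as.integer(f[7]); mism <- as.integer(f[8])
      bcount <- as.integer(f[9])
      sizes <- parse_ints(f[10]); qst <- parse_ints(f[11]); tst <- parse_ints(f[12])
    }
    if (is.na(bcount) || anyNA(sizes) || anyNA(qst) || anyNA(tst)) {
      abort(sprintf("line %d: malformed block lists", lineno[k]))
    }
    if (length(sizes) != bcount || length(qst) != bcount || length(tst) != bcount) {
      abort(sprintf("line %d: block list lengths disagree with block count %d",
                    lineno[k], bcount))
    }
    blocks <- cbind(qstart = qst, tstart = tst, len = sizes)
    validate_blocks(blocks, qsize, tsize, matches, mism, lineno[k])
    rows[[k]] <- tibble(query_id = qname, query_len = qsize, strand = strand,
                        target_id = tname, target_len = tsize,
                        matches = matches, mismatches = mism,
                        blocks = list(blocks))
  }
  bind_rows(rows)
}

validate_blocks <- function(blocks, qsize, tsize, matches, mism, lineno = NA) {
  where <- if (is.na(lineno)) "" else sprintf("line %s: ", lineno)
  tstart <- blocks[, "tstart"]; len <- blocks[, "len"]; qstart <- blocks[, "qstart"]
  if (nrow(blocks) > 1 &&
      any(tstart[-1] < (tstart + len)[-nrow(blocks)])) {
    abort(paste0(where, "blocks overlap or are not increasing in target"))
  }
  if (any(tstart < 0) || any(tstart + len > tsize)) {
    abort(paste0(where, "block outside target bounds"))
  }
  if (any(qstart < 0) || any(qstart + len > qsize)) {
    abort(paste0(where, "block outside query bounds"))
  }
  if (matches + mism != sum(len)) {
    abort(paste0(where, "matches + mismatches does not equal total block length"))
  }
  invisible(blocks)
}

#' Write alignments in PSL format
#'
#' Inverse of [read_alignments()] for the fields the record models; repeat
#' match and N-count columns are written as zero.
#'
#' @param x Alignment tibble as returned by [read_alignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(x, path) {
  lines <- character(nrow(x))
  for (k in seq_len(nrow(x))) {
    b <- x$blocks[[k]]
    sizes <- b[, "len"]; qst <- b[, "qstart"]; tst <- b[, "tstart"]
    qgaps <- if (nrow(b) > 1) qst[-1] - (qst + sizes)[-nrow(b)] else integer()
    tgaps <- if (nrow(b) > 1) tst[-1] - (tst + sizes)[-nrow(b)] else integer()
    q_lo <- qst[1]; q_hi <- qst[nrow(b)] + sizes[nrow(b)]
    if (x$strand[k] == "-") {
      qstart_plus <- x$query_len[k] - q_hi
      qend_plus <- x$query_len[k] - q_lo
    } else {
      qstart_plus <- q_lo; qend_plus <- q_hi
    }
    lines[k] <- paste(
      x$matches[k], x$mismatches[k], 0L, 0L,
      sum(qgaps > 0), sum(qgaps), sum(tgaps > 0), sum(tgaps),
      x$strand[k], x$query_id[k], x$query_len[k], qstart_plus, qend_plus,
      x$target_id[k], x$target_len[k], tst[1], tst[nrow(b)] + sizes[nrow(b)],
      nrow(b),
      paste0(paste(sizes, collapse = ","), ","),
      paste0(paste(qst, collapse = ","), ","),
      paste0(paste(tst, collapse = ","), ","),
      sep = "\t"
    )
  }
  writeLines(lines, path)
  invisible(path)
}
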