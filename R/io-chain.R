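# UCSC chain semantics: a chain maps a source (reference / draft) interval
# onto a target (patched) interval through an ordered list of aligned blocks
# separated by gaps. Blocks are (size, dsource, dtarget) triples: `size`
# aligned bases, then `dsource` source-only bases and `dtarget` target-only
# bases before the next block. The final triple has both gaps equal to zero
# (serialized as a bare size, per the UCSC text format).

#' Construct a coordinate chain
#'
#' @param source_id,source_len,source_start,source_end Source sequence name,
#'   length and mapped span (0-based half-open).
#' @param target_id,target_len,target_start,target_end Target counterpart.
#' @param blocks Matrix with columns `size`, `dsource`, `dtarget`.
#' @param score Numeric chain score (sum of aligned block sizes by default).
#' @param target_strand `"+"` or `"-"` (the toolkit only emits `"+"`).
#' @return An object of class `coord_chain`.
#' @export
coord_chain <- function(source_id, source_len, source_start, source_end,
                        target_id, target_len, target_start, target_end,
                        blocks, score = NULL, target_strand = "+") {
  blocks <- as.matrix(blocks)
  colnames(blocks) <- c("size", "dsource", "dtarget")
  storage.mode(blocks) <- "integer"
  ch <- structure(
    list(score = score %||% sum(blocks[, "size"]),
         source_id = source_id, source_len = as.integer(source_len),
         source_start = as.integer(source_start),
         source_end = as.integer(source_end),
         target_id = target_id, target_len = as.integer(target_len),
         target_start = as.integer(target_start),
         target_end = as.integer(target_end),
         target_strand = target_strand, blocks = blocks),
    class = "coord_chain"
  )
  validate_chain(ch)
}

validate_chain <- function(ch) {
  b <- ch$blocks
  if (any(b < 0)) abort("chain blocks must be non-negative")
  if (any(b[, "size"] == 0)) abort("chain block sizes must be positive")
  if (b[nrow(b), "dsource"] != 0 || b[nrow(b), "dtarget"] != 0) {
    abort("final chain triple must have zero gaps")
  }
  s_span <- sum(b[, "size"]) + sum(b[, "dsource"])
  t_span <- sum(b[, "size"]) + sum(b[, "dtarget"])
  if (s_span != ch$source_end - ch$source_start) {
    abort(sprintf("chain %s: block sums (%d) disagree with source span (%d)",
                  ch$source_id, s_span, ch$source_end - ch$source_start))
  }
  if (t_span != ch$target_end - ch$target_start) {
    abort(sprintf("chain %s: block sums (%d) disagree with target span (%d)",
                  ch$source_id, t_span, ch$target_end - ch$target_start))
  }
  ch
}

#' @export
print.coord_chain <- function(x, ...) {
  cat(sprintf("<coord_chain> %s:%d-%d -> %s:%d-%d (%s), %d block(s)\n",
              x$source_id, x$source_start, x$source_end,
              x$target_id, x$target_start, x$target_end,
              x$target_strand, nrow(x$blocks)))
  invisible(x)
}

#' Identity chain over a sequence
#'
#' @param id Sequence name (used for both source and target).
#' @param len Sequence length in bp.
#' @return A single-block `coord_chain` mapping every position to itself.
#' @export
identity_chain <- function(id, len) {
  coord_chain(id, len, 0L, len, id, len, 0L, len,
              cbind(size = as.integer(len), dsource = 0L, dtarget = 0L))
}

#' Read a UCSC chain file
#'
#' @param path Path to a chain-format text file.
#' @return A list of [coord_chain] objects; invariant sums are enforced on
#'   read (block sums must match the declared source and target spans).
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (f[1] != "chain" || length(f) < 12) {
      abort(sprintf("line %d: expected a chain header", i))
    }
    hdr <- suppressWarnings(as.integer(f[c(2, 4, 6, 7, 9, 11, 12)]))
    if (anyNA(hdr)) abort(sprintf("line %d: malformed chain header", i))
    triples <- list(); i <- i + 1L
    repeat {
      if (i > length(lines) || !nzchar(trimws(lines[i]))) break
      g <- suppressWarnings(as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]]))
      if (anyNA(g)) abort(sprintf("line %d: malformed chain block", i))
      if (length(g) == 1) {
        triples[[length(triples) + 1L]] <- c(g, 0L, 0L); i <- i + 1L; break
      } else if (length(g) == 3) {
        triples[[length(triples) + 1L]] <- g; i <- i + 1L
      } else {
        abort(sprintf("line %d: chain block must have 1 or 3 fields", i))
      }
    }
    if (!length(triples)) abort("chain with no blocks")
    blocks <- do.call(rbind, triples)
    chains[[length(chains) + 1L]] <- coord_chain(
      source_id = f[3], source_len = hdr[2],
      source_start = hdr[3], source_end = hdr[4],
      target_id = f[8], target_len = hdr[5],
      target_start = hdr[6], target_end = hdr[7],
      blocks = blocks, score = as.numeric(f[2]), target_strand = f[10]
    )
  }
  chains
}

#' Write chains in UCSC chain format
#'
#' @param chains A `coord_chain` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  if (inherits(chains, "coord_chain")) chains <- list(chains)
  out <- character()
  for (k in seq_along(chains)) {
    ch <- chains[[k]]
    out <- c(out, paste(
      "chain", format(ch$score, scientific = FALSE),
      ch$source_id, ch$source_len, "+", ch$source_start, ch$source_end,
      ch$target_id, ch$target_len, ch$target_strand,
      ch$target_start, ch$target_end, k
    ))
    b <- ch$blocks
    if (nrow(b) > 1) {
      body <- paste(b[-nrow(b), "size"], b[-nrow(b), "dsource"],
                    b[-nrow(b), "dtarget"])
      out <- c(out, body)
    }
    out <- c(out, as.character(b[nrow(b), "size"]), "")
  }
  writeLines(out, path)
  invisible(path)
}
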