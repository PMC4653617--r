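#' Read GTF gene annotations
#'
#' Coordinates are kept 1-based inclusive at this boundary, as in the file;
#' internal liftover converts to 0-based half-open on entry.
#'
#' @param path Path to a GTF file.
#' @return Tibble with columns `chrom`, `source`, `feature_type`, `start`,
#'   `end`, `strand`, `transcript_id`, `gene_id`, in file order.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  getcol <- function(nm) {
    if (nm %in% names(mc)) as.character(mc[[nm]]) else rep(NA_character_, length(gr))
  }
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    source = getcol("source"),
    feature_type = getcol("type"),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    transcript_id = getcol("transcript_id"),
    gene_id = getcol("gene_id")
  )
  if (any(out$end < out$start)) {
    abort("feature with end < start")
  }
  bad <- out$feature_type == "exon" & (is.na(out$transcript_id) | out$transcript_id == "")
  if (any(bad)) {
    abort(sprintf("exon without transcript_id (row %d)", which(bad)[1]))
  }
  out
}

#' Write annotations in GTF format
#'
#' Inverse of [read_annotations()]: coordinate columns round-trip
#' byte-identically.
#'
#' @param features Tibble as returned by [read_annotations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(features, path) {
  if (any(features$end < features$start)) abort("feature with end < start")
  attrs <- sprintf('transcript_id "%s"; gene_id "%s";',
                   features$transcript_id, features$gene_id)
  lines <- paste(
    features$chrom,
    ifelse(is.na(features$source), "draftpatch", features$source),
    features$feature_type, features$start, features$end, ".",
    ifelse(is.na(features$strand) | features$strand == "*", ".", features$strand),
    ".", attrs,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}
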