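#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased and IUPAC ambiguity codes other than N are
#' converted to N (the gap logic downstream is defined on N only); the number
#' of converted bases is reported with a message. Any residual symbol outside
#' \{A, C, G, T, N\} is a hard error naming the record and offset.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header) and `seq` (uppercase ACGTN string), one row per record, in file
#'   order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTNNNNACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (any(ids == "")) abort("empty FASTA header")
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate FASTA id: %s", ids[duplicated(ids)][1]))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0)) {
    abort(sprintf("empty sequence for record: %s", ids[nchar(seqs) == 0][1]))
  }
  iupac <- "RYSWKMBDHV"
  n_amb <- sum(vapply(seqs, function(s) {
    sum(charToRaw(s) %in% charToRaw(iupac))
  }, numeric(1)))
  if (n_amb > 0) {
    seqs <- chartr(iupac, strrep("N", nchar(iupac)), seqs)
    inform(sprintf("read_fasta: converted %d IUPAC ambiguity base(s) to N", n_amb))
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    abort(sprintf("non-nucleotide symbol '%s' in record %s at position %d",
                  substr(seqs[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  tibble(id = unname(ids), seq = unname(seqs))
}

#' Write a sequence tibble to FASTA
#'
#' Round-trips with [read_fasta()]: reading the written file reproduces the
#' ids and sequences exactly.
#'
#' @param x Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param line_width Bases per sequence line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, line_width = 60L) {
  assert_genome_tbl(x, "x")
  if (line_width < 1) abort("`line_width` must be >= 1")
  ss <- Biostrings::BStringSet(setNames(as.character(x$seq), x$id))
  Biostrings::writeXStringSet(ss, path, width = as.integer(line_width))
  invisible(path)
}

#' Extract unmapped reads from a SAM file
#'
#' Selects exactly the records whose FLAG has bit 0x4 (segment unmapped) set,
#' the same contract as `samtools view -f 4`. Conversion and flag filtering
#' are delegated to Rsamtools.
#'
#' @param sam_path Path to a SAM file with a valid header.
#' @return Tibble with columns `qname`, `flag`, `seq`, one row per unmapped
#'   record, names and sequences preserved.
#' @export
extract_unmapped <- function(sam_path) {
  if (!file.exists(sam_path)) abort(sprintf("file not found: %s", sam_path))
  bam <- Rsamtools::asBam(sam_path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE),
    what = c("qname", "flag", "seq")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  tibble(
    qname = res$qname,
    flag = as.integer(res$flag),
    seq = as.character(res$seq)
  )
}
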