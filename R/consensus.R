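# Variant filtering and substitution into the patched genome: the
# chimera-fix stage. Map-quality filtering (the external caller's -q 20) is
# a property of the upstream pileup and is carried only as a recorded
# parameter; the toolkit does not realign reads.

#' Variant filter parameters
#'
#' @param max_depth Drop records with read depth above this (default 100,
#'   mirroring a `varFilter -D100`-style depth cap).
#' @param require_biallelic Drop records with more than one alternate allele
#'   (default TRUE).
#' @param min_qual Minimum QUAL to keep (default 0).
#' @param min_mapq Recorded map-quality cutoff of the upstream pileup
#'   (default 20); informational only.
#' @return A list of class `variant_filter_params`.
#' @export
variant_filter_params <- function(max_depth = 100, require_biallelic = TRUE,
                                  min_qual = 0, min_mapq = 20) {
  if (max_depth < 1) abort("`max_depth` must be >= 1")
  structure(list(max_depth = max_depth,
                 require_biallelic = require_biallelic,
                 min_qual = min_qual, min_mapq = min_mapq),
            class = "variant_filter_params")
}

#' Filter variant records
#'
#' Drops records with depth above `max_depth`, multi-allelic records when
#' `require_biallelic`, and records below `min_qual`. Order is preserved;
#' records with missing depth or QUAL are kept (no evidence against them).
#'
#' @param records Variant tibble from [read_variants()].
#' @param params [variant_filter_params()].
#' @return The kept subset, in input order.
#' @export
filter_variants <- function(records, params = variant_filter_params()) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(records$depth)) {
    keep <- keep & (is.na(records$depth) | records$depth <= params$max_depth)
  }
  if (params$require_biallelic) {
    n_alt <- map_int(records$alt, length)
    keep <- keep & n_alt == 1L
  }
  if (params$min_qual > 0 && !is.null(records$qual)) {
    keep <- keep & (is.na(records$qual) | records$qual >= params$min_qual)
  }
  records[keep, , drop = FALSE]
}

#' Substitute variants into a genome
#'
#' SNPs are substituted in place; insertions and deletions (VCF left-anchored
#' convention) are applied right-to-left per chromosome so earlier
#' coordinates stay valid. Each variant's REF must match the genome at its
#' position. The returned chains map pre- to post-substitution coordinates:
#' length-preserving variants leave the map untouched; an indel contributes a
#' gap of `len(ref) - p` source and `len(alt) - p` target bases after the
#' common prefix `p = min(len(ref), len(alt))`.
#'
#' @param genome Sequence tibble (`id`, `seq`).
#' @param variants Variant tibble (single alternate allele per record;
#'   filter first).
#' @return List of class `consensus_result` with `genome` (substituted
#'   sequences) and `chains` (named list of [coord_chain], one per
#'   chromosome).
#' @export
apply_variants <- function(genome, variants) {
  assert_genome_tbl(genome)
  alt1 <- map_chr(variants$alt, function(a) {
    if (length(a) != 1) abort("apply_variants requires exactly one alt allele per record; filter first")
    a
  })
  out_seq <- genome$seq
  chains <- list()
  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$id[ci]
    v <- variants[variants$chrom == chrom, , drop = FALSE]
    va <- alt1[variants$chrom == chrom]
    s <- genome$seq[ci]
    L <- nchar(s)
    if (!nrow(v)) {
      chains[[chrom]] <- identity_chain(chrom, L)
      next
    }
    ord <- order(v$pos)
    v <- v[ord, , drop = FALSE]; va <- va[ord]
    rlen <- nchar(v$ref); alen <- nchar(va)
    ends <- v$pos + rlen - 1L
    if (any(v$pos[-1] <= ends[-length(ends)])) {
      i <- which(v$pos[-1] <= ends[-length(ends)])[1]
      abort(sprintf("overlapping variants at %s:%d and %s:%d",
                    chrom, v$pos[i], chrom, v$pos[i + 1]))
    }
    if (any(ends > L)) abort(sprintf("variant at %s:%d runs past the sequence end",
                                     chrom, v$pos[which(ends > L)[1]]))
    found <- substring(s, v$pos, ends)
    bad <- found != v$ref
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("REF mismatch at %s:%d: expected %s, found %s",
                    chrom, v$pos[i], v$ref[i], found[i]))
    }
    # right-to-left application
    for (i in rev(seq_len(nrow(v)))) {
      s <- paste0(substr(s, 1L, v$pos[i] - 1L), va[i],
                  substr(s, v$pos[i] + rlen[i], nchar(s)))
    }
    out_seq[ci] <- s
    # chain, left to right
    p <- pmin(rlen, alen)
    sizes <- integer(); dss <- integer(); dts <- integer()
    cursor <- 0L; pending <- 0L
    for (i in seq_len(nrow(v))) {
      if (rlen[i] == alen[i]) next # in-place substitution: identity map
      pending <- (v$pos[i] - 1L + p[i]) - cursor
      sizes <- c(sizes, pending)
      dss <- c(dss, rlen[i] - p[i]); dts <- c(dts, alen[i] - p[i])
      cursor <- v$pos[i] - 1L + rlen[i]
    }
    src_end <- L; tgt_end <- nchar(s)
    if (L - cursor > 0 || !length(sizes)) {
      sizes <- c(sizes, L - cursor); dss <- c(dss, 0L); dts <- c(dts, 0L)
    } else {
      # an indel consumed the sequence end: the chain span stops at the last
      # mapped base (a chain cannot end on a gap)
      k <- length(dss)
      src_end <- L - dss[k]; tgt_end <- nchar(s) - dts[k]
      dss[k] <- 0L; dts[k] <- 0L
    }
    chains[[chrom]] <- coord_chain(chrom, L, 0L, src_end, chrom, nchar(s), 0L,
                                   tgt_end, cbind(sizes, dss, dts))
  }
  structure(list(genome = tibble(id = genome$id, seq = out_seq),
                 chains = chains),
            class = "consensus_result")
}

#' Call SNPs from base-count pileups by majority vote
#'
#' Desk-scale caller over per-site base counts: a site yields a SNP when its
#' depth reaches `min_depth` and the most frequent non-reference base makes
#' up at least `min_fraction` of the depth. Heterozygous sites therefore
#' resolve to the majority allele (single-haplotype output).
#'
#' @param pileup_rows Tibble with columns `chrom`, `pos` (1-based), `ref` and
#'   base counts `A`, `C`, `G`, `T`.
#' @param min_depth Minimum site depth (default 5).
#' @param min_fraction Majority fraction in (0.5, 1] (default 0.8).
#' @return Variant tibble (`chrom`, `pos`, `ref`, `alt` list column, `depth`,
#'   `qual` = 100 x majority fraction).
#' @export
majority_call <- function(pileup_rows, min_depth = 5, min_fraction = 0.8) {
  if (min_depth < 1) abort("`min_depth` must be >= 1")
  if (min_fraction <= 0.5 || min_fraction > 1) {
    abort("`min_fraction` must be in (0.5, 1]")
  }
  bases <- c("A", "C", "G", "T")
  counts <- as.matrix(pileup_rows[, bases])
  depth <- rowSums(counts)
  ref_idx <- match(pileup_rows$ref, bases)
  nonref <- counts
  nonref[cbind(seq_len(nrow(counts)), ref_idx)] <- -1L
  best <- max.col(nonref, ties.method = "first")
  best_count <- nonref[cbind(seq_len(nrow(counts)), best)]
  frac <- ifelse(depth > 0, best_count / depth, 0)
  call <- depth >= min_depth & frac >= min_fraction
  tibble(
    chrom = pileup_rows$chrom[call],
    pos = pileup_rows$pos[call],
    ref = pileup_rows$ref[call],
    alt = as.list(bases[best[call]]),
    depth = as.integer(depth[call]),
    qual = round(100 * frac[call], 2)
  )
}
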