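# Seeded fixture generators: a truth genome, its gapped draft, patch-ready
# contigs with their true placements, annotations with a known
# completely-filled set, clone-end pairs with planted verdicts, pileups over
# planted SNPs, and structured genotype matrices. Every generator is a pure
# function of the config: the global seed expands into per-generator
# substreams keyed by fixed labels, so adding a generator never perturbs
# existing fixtures.

#' Simulation configuration
#'
#' Defaults describe the standard fixture: 2 chromosomes x 100 kb with 10
#' gaps of 200-2000 bp (large enough to exercise window logic, small enough
#' for sub-second tests), 500 bp of true flanking sequence per patch contig,
#' clone-end pairs on megabase-scale chromosomes (BAC inserts are 100-200
#' kb), and a 3-population genotype panel of 15 samples x 2000 SNPs at
#' divergence 0.2.
#'
#' @param seed Mandatory integer seed.
#' @param n_chroms,chrom_len Number and length (bp) of truth chromosomes.
#' @param n_gaps Total masked intervals across the genome.
#' @param gap_len Length range (bp) of masked intervals.
#' @param contig_flank True flanking bases on each side of a patch contig.
#' @param rc_fraction Fraction of patch contigs emitted reverse-complemented.
#' @param n_transcripts Total transcripts; `n_filled_transcripts` of them are
#'   drawn across masked intervals (gap in an intron).
#' @param n_filled_transcripts Transcripts deliberately spanning gaps.
#' @param n_pairs Clone-end pairs to simulate.
#' @param violation_mix Named fractions for `proper`, `diff_chrom`,
#'   `orientation`, `insert`; must sum to 1.
#' @param pair_chrom_len,pair_insert Chromosome length and proper insert-size
#'   range (bp) for the clone-end fixture.
#' @param max_insert Insert-size bound violated by `insert` pairs.
#' @param n_pops,samples_per_pop,n_snps Genotype panel shape.
#' @param divergence Balding-Nichols Fst-like divergence in (0, 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chroms = 2, chrom_len = 100000,
                       n_gaps = 10, gap_len = c(200, 2000),
                       contig_flank = 500, rc_fraction = 0.5,
                       n_transcripts = 30, n_filled_transcripts = 8,
                       n_pairs = 1000,
                       violation_mix = c(proper = 0.7, diff_chrom = 0.1,
                                         orientation = 0.1, insert = 0.1),
                       pair_chrom_len = 1e6,
                       pair_insert = c(80000, 250000),
                       max_insert = 350000,
                       n_pops = 3, samples_per_pop = 5, n_snps = 2000,
                       divergence = 0.2) {
  if (missing(seed)) abort("`seed` is mandatory")
  if (abs(sum(violation_mix) - 1) > 1e-9) abort("`violation_mix` must sum to 1")
  nm <- c("proper", "diff_chrom", "orientation", "insert")
  if (!all(nm %in% names(violation_mix))) {
    abort("`violation_mix` needs fractions for proper, diff_chrom, orientation, insert")
  }
  if (divergence <= 0 || divergence >= 1) abort("`divergence` must be in (0, 1)")
  structure(mget(names(formals()), envir = environment()), class = "sim_config")
}

#' Generate a truth genome
#'
#' Uniform random A/C/G/T sequences, reproducible per seed.
#'
#' @param config A [sim_config()].
#' @return Sequence tibble (`id`, `seq`) with `n_chroms` records named
#'   `chr1`, `chr2`, ...
#' @export
make_truth_genome <- function(config) {
  with_seed(substream_seed(config$seed, "truth"), {
    tibble(
      id = paste0("chr", seq_len(config$n_chroms)),
      seq = vapply(seq_len(config$n_chroms), function(i) {
        paste(sample(c("A", "C", "G", "T"), config$chrom_len, replace = TRUE),
              collapse = "")
      }, character(1))
    )
  })
}

# Sample n non-overlapping intervals with the configured lengths, each at
# least `margin` from the sequence ends and pairwise separated by `sep` bp.
sample_intervals <- function(chrom_len, lens, margin, sep) {
  placed <- matrix(numeric(0), ncol = 2)
  for (len in lens) {
    ok <- FALSE
    for (try in 1:2000) {
      s <- sample(seq.int(margin, chrom_len - margin - len), 1)
      e <- s + len
      if (!nrow(placed) ||
          all(placed[, 1] - sep >= e | s >= placed[, 2] + sep)) {
        placed <- rbind(placed, c(s, e)); ok <- TRUE; break
      }
    }
    if (!ok) abort("infeasible gap packing; reduce n_gaps or gap lengths")
  }
  placed[order(placed[, 1]), , drop = FALSE]
}

#' Mask a truth genome into a gapped draft
#'
#' Writes `n_gaps` non-overlapping intervals as N, each at least
#' `contig_flank` bp from chromosome ends and separated from its neighbours
#' by at least `2 * contig_flank + 10` bp so that per-gap patch contigs never
#' overlap.
#'
#' @param truth Truth genome from [make_truth_genome()].
#' @param config A [sim_config()].
#' @return List with `draft` (sequence tibble) and `gaps` (tibble `chrom`,
#'   `start`, `end`, `length`, equal to `find_gaps(draft)`).
#' @export
mask_to_draft <- function(truth, config) {
  with_seed(substream_seed(config$seed, "gaps"), {
    chrom_of <- sort(sample(seq_len(nrow(truth)), config$n_gaps, replace = TRUE))
    lens <- sample(seq.int(config$gap_len[1], config$gap_len[2]),
                   config$n_gaps, replace = TRUE)
    draft <- truth
    gaps <- list()
    for (ci in seq_len(nrow(truth))) {
      here <- which(chrom_of == ci)
      if (!length(here)) next
      iv <- sample_intervals(nchar(truth$seq[ci]), lens[here],
                             margin = config$contig_flank,
                             sep = 2 * config$contig_flank + 10)
      s <- draft$seq[ci]
      for (r in seq_len(nrow(iv))) {
        substr(s, iv[r, 1] + 1, iv[r, 2]) <- strrep("N", iv[r, 2] - iv[r, 1])
      }
      draft$seq[ci] <- s
      gaps[[ci]] <- tibble(chrom = truth$id[ci],
                           start = as.integer(iv[, 1]),
                           end = as.integer(iv[, 2]),
                           length = as.integer(iv[, 2] - iv[, 1]))
    }
    gaps <- bind_rows(gaps)
    if (!nrow(gaps)) {
      gaps <- tibble(chrom = character(), start = integer(),
                     end = integer(), length = integer())
    }
    list(draft = draft, gaps = gaps)
  })
}

#' Shred the truth genome into patch-ready contigs
#'
#' One contig per masked interval, spanning it plus `contig_flank` true bases
#' on each side; a `rc_fraction` share is emitted reverse-complemented with
#' minus-strand alignments. The emitted alignments are the true flank
#' placements (two blocks around the masked interior).
#'
#' @param truth Truth genome.
#' @param gaps Masked intervals from [mask_to_draft()].
#' @param config A [sim_config()].
#' @return List with `contigs` (sequence tibble) and `alignments` (tibble as
#'   from [read_alignments()]).
#' @export
shred_contigs <- function(truth, gaps, config) {
  with_seed(substream_seed(config$seed, "contigs"), {
    fl <- config$contig_flank
    n <- nrow(gaps)
    rc <- runif(n) < config$rc_fraction
    rows <- vector("list", n)
    ctg <- character(n)
    ids <- sprintf("ctg_%03d", seq_len(n))
    for (i in seq_len(n)) {
      tseq <- genome_seq(truth, gaps$chrom[i])
      cs <- substr(tseq, gaps$start[i] - fl + 1, gaps$end[i] + fl)
      qlen <- nchar(cs)
      if (rc[i]) cs <- revcomp(cs)
      ctg[i] <- cs
      blocks <- cbind(qstart = c(0L, as.integer(fl + gaps$length[i])),
                      tstart = c(as.integer(gaps$start[i] - fl),
                                 as.integer(gaps$end[i])),
                      len = c(fl, fl))
      rows[[i]] <- tibble(
        query_id = ids[i], query_len = qlen,
        strand = if (rc[i]) "-" else "+",
        target_id = gaps$chrom[i],
        target_len = nchar(tseq),
        matches = 2L * as.integer(fl), mismatches = 0L,
        blocks = list(blocks)
      )
    }
    list(contigs = tibble(id = ids, seq = ctg), alignments = bind_rows(rows))
  })
}

#' Generate annotations with a known completely-filled set
#'
#' `n_filled_transcripts` two-exon transcripts are drawn across distinct
#' masked intervals (the gap falls in the intron, exons on true sequence);
#' the remainder avoid all masked intervals entirely. Exons never overlap
#' any masked interval, so every transcript lifts fully through the patch
#' chain and exactly the gap-spanning ones classify as completely filled.
#'
#' @param truth Truth genome.
#' @param gaps Masked intervals from [mask_to_draft()].
#' @param config A [sim_config()].
#' @return List with `features` (GTF-convention tibble) and `expected_filled`
#'   (character vector of transcript ids).
#' @export
make_annotations <- function(truth, gaps, config) {
  with_seed(substream_seed(config$seed, "annot"), {
    fl <- config$contig_flank
    n_fill <- min(config$n_filled_transcripts, nrow(gaps))
    fill_gaps <- if (n_fill > 0) sort(sample(seq_len(nrow(gaps)), n_fill)) else integer()
    feats <- list()
    mk <- function(tid, gid, chrom, exons, strand) {
      storage.mode(exons) <- "integer"
      bind_rows(
        tibble(chrom = chrom, source = "sim", feature_type = "transcript",
               start = min(exons[, 1]), end = max(exons[, 2]), strand = strand,
               transcript_id = tid, gene_id = gid),
        tibble(chrom = chrom, source = "sim", feature_type = "exon",
               start = exons[, 1], end = exons[, 2], strand = strand,
               transcript_id = tid, gene_id = gid)
      )
    }
    for (k in seq_along(fill_gaps)) {
      g <- gaps[fill_gaps[k], ]
      e1_len <- sample(80:200, 1); e2_len <- sample(80:200, 1)
      off1 <- sample(5:80, 1); off2 <- sample(5:80, 1)
      exons <- cbind(c(g$start - off1 - e1_len + 1, g$end + off2 + 1),
                     c(g$start - off1, g$end + off2 + e2_len))
      tid <- sprintf("tx_fill_%02d", k)
      feats[[length(feats) + 1L]] <- mk(tid, paste0("gene_", tid), g$chrom,
                                        exons, sample(c("+", "-"), 1))
    }
    n_bg <- max(config$n_transcripts - length(fill_gaps), 0)
    for (k in seq_len(n_bg)) {
      repeat {
        ci <- sample(nrow(truth), 1)
        chrom <- truth$id[ci]
        L <- nchar(truth$seq[ci])
        span <- sample(500:1500, 1)
        s0 <- sample(seq.int(1, L - span), 1) # 1-based span start
        g <- gaps[gaps$chrom == chrom, , drop = FALSE]
        clash <- nrow(g) && any(g$start < (s0 + span - 1) & (s0 - 1) < g$end)
        if (!clash) break
      }
      e1_len <- sample(80:200, 1); e2_len <- sample(80:200, 1)
      exons <- cbind(c(s0, s0 + span - e2_len),
                     c(s0 + e1_len - 1, s0 + span - 1))
      tid <- sprintf("tx_bg_%02d", k)
      feats[[length(feats) + 1L]] <- mk(tid, paste0("gene_", tid), chrom,
                                        exons, sample(c("+", "-"), 1))
    }
    list(features = bind_rows(feats),
         expected_filled = sprintf("tx_fill_%02d", seq_along(fill_gaps)))
  })
}

#' Generate clone-end pairs with planted verdicts
#'
#' Pairs are planted per `violation_mix` using exact counts (fraction times
#' `n_pairs`, largest-remainder rounding): proper pairs get opposite-strand
#' ends within the insert range; `diff_chrom` pairs straddle two
#' chromosomes; `orientation` pairs share a strand; `insert` pairs exceed
#' `max_insert`.
#'
#' @param genome Either a sequence tibble or a named vector of chromosome
#'   lengths; defaults to `config$n_chroms` chromosomes of
#'   `config$pair_chrom_len` bp.
#' @param config A [sim_config()].
#' @return List with `placements` (end-placement tibble) and `planted`
#'   (tibble `clone_id`, `verdict`).
#' @export
make_clone_pairs <- function(genome = NULL, config) {
  with_seed(substream_seed(config$seed, "pairs"), {
    lens <- if (is.null(genome)) {
      setNames(rep(config$pair_chrom_len, max(config$n_chroms, 2)),
               paste0("pchr", seq_len(max(config$n_chroms, 2))))
    } else if (is.data.frame(genome)) {
      setNames(nchar(genome$seq), genome$id)
    } else {
      genome
    }
    if (length(lens) < 2) abort("clone-end fixture needs >= 2 chromosomes")
    mix <- config$violation_mix[c("proper", "diff_chrom", "orientation", "insert")]
    counts <- floor(mix * config$n_pairs)
    rem <- config$n_pairs - sum(counts)
    if (rem > 0) {
      extra <- order(mix * config$n_pairs - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1
    }
    if (counts[["insert"]] > 0 && max(lens) <= config$max_insert + 2000) {
      abort("chromosomes too short to plant insert-size violations")
    }
    verdicts <- rep(names(counts), counts)
    verdicts <- sample(verdicts) # shuffle clone order
    n <- length(verdicts)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      clone <- sprintf("clone_%05d", i)
      v <- verdicts[i]
      l1 <- sample(400:900, 1); l2 <- sample(400:900, 1)
      if (v == "diff_chrom") {
        chs <- sample(names(lens), 2)
        s1 <- sample.int(lens[[chs[1]]] - l1, 1) - 1
        s2 <- sample.int(lens[[chs[2]]] - l2, 1) - 1
        p <- tibble(clone_id = clone, end_label = c("F", "R"),
                    chrom = chs, start = c(s1, s2),
                    end = c(s1 + l1, s2 + l2),
                    strand = sample(c("+", "-"), 2, replace = TRUE))
      } else {
        ch <- sample(names(lens), 1)
        L <- lens[[ch]]
        ins <- if (v == "insert") {
          sample.int(L - config$max_insert - 1000, 1) + config$max_insert + 999
        } else {
          sample(seq.int(config$pair_insert[1], config$pair_insert[2]), 1)
        }
        s1 <- sample.int(L - ins, 1) - 1
        e2_end <- s1 + ins
        strands <- if (v == "orientation") {
          st <- sample(c("+", "-"), 1); c(st, st)
        } else {
          c("+", "-")
        }
        p <- tibble(clone_id = clone, end_label = sample(c("F", "R")),
                    chrom = ch,
                    start = c(s1, e2_end - l2),
                    end = c(s1 + l1, e2_end),
                    strand = strands)
      }
      rows[[i]] <- p
    }
    list(placements = bind_rows(rows),
         planted = tibble(clone_id = sprintf("clone_%05d", seq_len(n)),
                          verdict = verdicts))
  })
}

#' Plant SNPs into a genome
#'
#' @param genome Sequence tibble.
#' @param n Number of SNPs to plant at distinct non-N positions.
#' @param seed Integer seed.
#' @return Variant tibble (`chrom`, `pos`, `ref`, `alt`, `depth` = NA,
#'   `qual` = NA) with ref taken from the genome and a random different base
#'   as alt.
#' @export
plant_snps <- function(genome, n, seed) {
  assert_genome_tbl(genome)
  with_seed(substream_seed(seed, "plant_snps"), {
    lens <- nchar(genome$seq)
    rows <- list()
    taken <- list()
    bases <- c("A", "C", "G", "T")
    while (length(rows) < n) {
      ci <- sample(nrow(genome), 1)
      pos <- sample.int(lens[ci], 1)
      key <- paste(ci, pos)
      if (!is.null(taken[[key]])) next
      ref <- substr(genome$seq[ci], pos, pos)
      if (ref == "N") next
      taken[[key]] <- TRUE
      rows[[length(rows) + 1L]] <- tibble(
        chrom = genome$id[ci], pos = as.integer(pos), ref = ref,
        alt = list(sample(setdiff(bases, ref), 1)),
        depth = NA_integer_, qual = NA_real_
      )
    }
    arrange(bind_rows(rows), .data$chrom, .data$pos)
  })
}

#' Simulate base-count pileups over planted SNPs
#'
#' Variant sites draw their alternate-allele count from
#' `Binomial(depth, alt_fraction)` with the remainder on the reference;
#' `n_ref_sites` additional reference-majority sites exercise the no-call
#' path.
#'
#' @param genome Sequence tibble (the pre-substitution genome).
#' @param variants Planted SNP tibble from [plant_snps()].
#' @param depth Simulated read depth per site (default 30).
#' @param alt_fraction Expected alternate-allele fraction at variant sites
#'   (default 0.97).
#' @param n_ref_sites Reference-only decoy sites (default 20).
#' @param seed Integer seed.
#' @return Pileup tibble (`chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`).
#' @export
make_pileups <- function(genome, variants, depth = 30, alt_fraction = 0.97,
                         n_ref_sites = 20, seed) {
  with_seed(substream_seed(seed, "pileups"), {
    bases <- c("A", "C", "G", "T")
    mk_row <- function(chrom, pos, ref, alt_base, alt_n, dp) {
      counts <- setNames(rep(0L, 4), bases)
      counts[ref] <- dp - alt_n
      if (!is.null(alt_base)) counts[alt_base] <- counts[alt_base] + alt_n
      tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
             A = counts[["A"]], C = counts[["C"]],
             G = counts[["G"]], T = counts[["T"]])
    }
    rows <- map(seq_len(nrow(variants)), function(i) {
      alt_n <- rbinom(1, depth, alt_fraction)
      mk_row(variants$chrom[i], variants$pos[i], variants$ref[i],
             variants$alt[[i]][1], alt_n, depth)
    })
    taken <- paste(variants$chrom, variants$pos)
    decoys <- list()
    lens <- nchar(genome$seq)
    while (length(decoys) < n_ref_sites) {
      ci <- sample(nrow(genome), 1)
      pos <- sample.int(lens[ci], 1)
      if (paste(genome$id[ci], pos) %in% taken) next
      ref <- substr(genome$seq[ci], pos, pos)
      if (ref == "N") next
      err <- rbinom(1, depth, 0.02)
      alt_base <- sample(setdiff(bases, ref), 1)
      decoys[[length(decoys) + 1L]] <- mk_row(genome$id[ci], pos, ref,
                                              alt_base, err, depth)
    }
    arrange(bind_rows(c(rows, decoys)), .data$chrom, .data$pos)
  })
}

#' Generate a structured genotype matrix
#'
#' Balding-Nichols model: ancestral allele frequencies uniform on
#' (0.05, 0.95); each population draws its frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F = divergence`; sample
#' dosages are `Binomial(2, population frequency)`. Positions are strictly
#' increasing on a single chromosome.
#'
#' @param config A [sim_config()].
#' @return A [genotype_matrix] with population labels in `$pops`.
#' @export
make_genotypes <- function(config) {
  with_seed(substream_seed(config$seed, "geno"), {
    m <- config$n_snps
    n_pop <- config$n_pops
    spp <- config$samples_per_pop
    f <- config$divergence
    p_anc <- runif(m, 0.05, 0.95)
    pos <- cumsum(sample(100:5000, m, replace = TRUE))
    pop_freq <- vapply(seq_len(n_pop), function(k) {
      rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }, numeric(m))
    pop_freq <- pmin(pmax(pop_freq, 1e-4), 1 - 1e-4)
    dos <- matrix(NA_real_, n_pop * spp, m)
    pops <- rep(paste0("pop", seq_len(n_pop)), each = spp)
    for (i in seq_len(nrow(dos))) {
      k <- (i - 1) %/% spp + 1
      dos[i, ] <- rbinom(m, 2, pop_freq[, k])
    }
    genotype_matrix(dos, chrom = rep("chr1", m), pos = pos,
                    samples = paste0(pops, "_s", rep(seq_len(spp), n_pop)),
                    pops = pops)
  })
}
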