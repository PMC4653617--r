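# Dosage-based LD pruning, allele-sharing distance, and classical scaling
# (PCoA) for population structure from biallelic SNP genotypes.

#' Construct a genotype matrix
#'
#' @param dosages Numeric matrix, samples x SNPs, values 0/1/2 or `NA`.
#' @param chrom,pos SNP chromosome and 1-based position vectors (positions
#'   strictly increasing within chromosome).
#' @param samples Sample ids (default from rownames).
#' @param pops Optional population labels per sample.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, chrom, pos, samples = rownames(dosages),
                            pops = NULL) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != length(chrom) || length(chrom) != length(pos)) {
    abort("`chrom`/`pos` must have one entry per dosage column")
  }
  if (is.null(samples)) samples <- paste0("sample", seq_len(nrow(dosages)))
  ok <- is.na(dosages) | (dosages >= 0 & dosages <= 2)
  if (!all(ok)) abort("dosages must be 0, 1, 2 or NA")
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0)) {
      abort(sprintf("positions not strictly increasing on %s", ch))
    }
  }
  rownames(dosages) <- samples
  structure(
    list(dosages = dosages,
         snps = tibble(chrom = chrom, pos = as.integer(pos)),
         samples = samples, pops = pops),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sample(s) x %d SNP(s)\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Squared dosage correlation (composite LD) between two SNPs
#'
#' Squared Pearson correlation of the dosage vectors over pairwise-complete
#' entries. Undefined (returns `NA`) when fewer than two complete pairs
#' remain or either vector is constant on the complete set; such SNPs are
#' prune-ineligible.
#'
#' @param x,y Dosage vectors of equal length.
#' @return r-squared in \[0, 1\], or `NA` when undefined.
#' @examples
#' dosage_r2(c(0, 0, 2, 2), c(0, 2, 0, 2)) # 0
#' @export
dosage_r2 <- function(x, y) {
  if (length(x) != length(y)) abort("vectors must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Sliding-window LD pruning
#'
#' Single left-to-right pass per chromosome: a SNP is kept iff its r-squared
#' against every already-kept SNP within `window_bp` upstream is at most
#' `r2_max`. Monomorphic SNPs (r-squared undefined) are always kept and
#' flagged.
#'
#' @param gm A [genotype_matrix].
#' @param window_bp Window size in bp (default 500000).
#' @param r2_max Pruning threshold (default 0.2): SNPs with r-squared above
#'   this against a kept neighbour are removed.
#' @return List with `kept` (column indices) and `report` (tibble: `index`,
#'   `chrom`, `pos`, `kept`, `monomorphic`).
#' @export
ld_prune <- function(gm, window_bp = 500000, r2_max = 0.2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (window_bp < 1) abort("`window_bp` must be >= 1")
  if (r2_max < 0 || r2_max > 1) abort("`r2_max` must be in [0, 1]")
  m <- ncol(gm$dosages)
  kept <- logical(m)
  mono <- logical(m)
  for (ch in unique(gm$snps$chrom)) {
    idx <- which(gm$snps$chrom == ch)
    kept_here <- integer()
    for (j in idx) {
      cand <- gm$dosages[, j]
      if (length(unique(cand[!is.na(cand)])) < 2) {
        mono[j] <- TRUE; kept[j] <- TRUE
        next
      }
      in_win <- kept_here[gm$snps$pos[j] - gm$snps$pos[kept_here] <= window_bp]
      drop <- FALSE
      for (k in rev(in_win)) {
        r2 <- dosage_r2(cand, gm$dosages[, k])
        if (!is.na(r2) && r2 > r2_max) { drop <- TRUE; break }
      }
      if (!drop) {
        kept[j] <- TRUE
        kept_here <- c(kept_here, j)
      }
    }
  }
  list(kept = which(kept),
       report = tibble(index = seq_len(m), chrom = gm$snps$chrom,
                       pos = gm$snps$pos, kept = kept, monomorphic = mono))
}

#' Pairwise allele-sharing distance matrix
#'
#' For samples i and j over the `m_ij` SNPs typed in both,
#' `d(i, j) = 1 - (1 / (2 m_ij)) * sum(2 - |g_i - g_j|)`, i.e. one minus
#' half the mean number of shared alleles (1 - IBS/2), which simplifies to
#' half the mean absolute dosage difference.
#'
#' @param gm A [genotype_matrix].
#' @return Symmetric numeric matrix with zero diagonal and entries in
#'   \[0, 1\], sample ids as dimnames.
#' @export
allele_sharing_dist <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g <- gm$dosages
  n <- nrow(g)
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- abs(g[i, ] - g[j, ])
      ok <- !is.na(diffs)
      if (!any(ok)) {
        abort(sprintf("samples %s and %s share no typed SNPs",
                      gm$samples[i], gm$samples[j]))
      }
      d[i, j] <- d[j, i] <- sum(diffs[ok]) / (2 * sum(ok))
    }
  }
  d
}

#' Classical scaling (PCoA) of a distance matrix
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes (via [stats::cmdscale()]),
#' and scales eigenvectors by the square root of their eigenvalues. Axes are
#' ordered by eigenvalue; negative eigenvalues are excluded from the
#' coordinates and from the contribution-rate denominator, so the returned
#' coordinate matrix may have fewer than `k` axes.
#'
#' @param d Symmetric distance matrix (or `dist`).
#' @param k Number of axes requested (1 <= k < n).
#' @return A `pcoa_result`: `coords` (tibble: `sample`, `PC1`, ...),
#'   `eigenvalues` (all n), `contribution` (percent per returned axis).
#' @export
pcoa <- function(d, k = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n || k < 1) abort("`k` must satisfy 1 <= k < n")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    abort("`d` must be symmetric with zero diagonal")
  }
  fit <- suppressWarnings(cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  eig <- fit$eig
  pos <- sum(eig > 1e-12)
  n_axes <- min(k, max(pos, 0L))
  pts <- pts[, seq_len(n_axes), drop = FALSE]
  contribution <- 100 * eig[seq_len(n_axes)] / sum(eig[eig > 1e-12])
  coords <- as_tibble(pts, .name_repair = "minimal")
  names(coords) <- paste0("PC", seq_len(n_axes))
  coords <- bind_cols(tibble(sample = rownames(d) %||%
                               paste0("sample", seq_len(n))), coords)
  structure(
    list(coords = coords, eigenvalues = eig,
         contribution = contribution, k = n_axes),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d sample(s), %d axis/axes\n",
              nrow(x$coords), x$k))
  cat("  contribution rates (%):",
      paste(sprintf("%.2f", x$contribution), collapse = ", "), "\n")
  invisible(x)
}
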