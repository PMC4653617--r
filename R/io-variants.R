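#' Read variant records from a VCF file
#'
#' Parsing is delegated to vcfR. Read depth is taken from the `DP` key of the
#' INFO column when present, otherwise from the `DP` FORMAT field of the
#' first sample; missing depth becomes `NA`. Multi-allelic records are kept
#' (filtering is a later, explicit step — see [filter_variants()]).
#'
#' @param path Path to a VCF 4.x file.
#' @return Tibble in file order with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (list column of alternate allele character vectors), `depth`,
#'   `qual`.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(v@fix) == 0) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = list(), depth = integer(), qual = double()))
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(pos) || any(pos < 1)) {
    abort(sprintf("malformed POS at data row %d (%s)",
                  which(is.na(pos) | pos < 1)[1],
                  fix$CHROM[which(is.na(pos) | pos < 1)[1]]))
  }
  if (any(is.na(fix$REF) | fix$REF == "")) {
    abort(sprintf("empty REF at data row %d", which(is.na(fix$REF) | fix$REF == "")[1]))
  }
  info <- ifelse(is.na(fix$INFO), "", fix$INFO)
  has_info_dp <- grepl("(^|;)DP=\\d+", info)
  depth <- rep(NA_integer_, nrow(fix))
  depth[has_info_dp] <- as.integer(sub(".*(^|;)DP=(\\d+).*", "\\2",
                                       info[has_info_dp]))
  if (any(is.na(depth)) && ncol(v@gt) >= 2) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    if (!is.null(dp)) {
      take <- is.na(depth) & !is.na(dp[, 1])
      depth[take] <- as.integer(dp[take, 1])
    }
  }
  tibble(
    chrom = fix$CHROM,
    pos = pos,
    ref = fix$REF,
    alt = strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE),
    depth = depth,
    qual = suppressWarnings(as.numeric(fix$QUAL))
  )
}

#' Read a multi-sample genotype matrix from a VCF file
#'
#' Extracts GT fields with vcfR and converts them to alternate-allele dosages
#' (0, 1, 2; `NA` for missing). Only biallelic records are kept, matching the
#' biallelic-SNP input the distance and pruning steps expect.
#'
#' @param path Path to a multi-sample VCF.
#' @return A [genotype_matrix] (samples x SNPs).
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT %||% "")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  dos <- apply(gt, 2, function(col) {
    a <- gsub("\\|", "/", col)
    vapply(strsplit(a, "/", fixed = TRUE), function(al) {
      al <- al[al != "."]
      if (!length(al)) return(NA_real_)
      sum(al != "0")
    }, numeric(1))
  })
  genotype_matrix(
    dosages = t(dos),
    chrom = fix$CHROM[biallelic],
    pos = as.integer(fix$POS[biallelic]),
    samples = colnames(gt)
  )
}
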