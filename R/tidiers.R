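# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @rdname assembly_stats
#' @param x An `assembly_stats` object.
#' @param ... Unused.
#' @method tidy assembly_stats
#' @export
tidy.assembly_stats <- function(x, ...) {
  tibble(n_contigs = x$n_contigs, n50 = x$n50, n_gaps = x$n_gaps,
         total_gap_length = x$total_gap_length, total_length = x$total_length,
         min_run = x$min_run)
}

#' @rdname assembly_stats
#' @method glance assembly_stats
#' @export
glance.assembly_stats <- function(x, ...) tidy.assembly_stats(x)

#' Nx curve for an assembly
#'
#' Cumulative contig-length curve (largest first) with the N50 marked.
#'
#' @param object An `assembly_stats` object built from sequences.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot assembly_stats
#' @export
autoplot.assembly_stats <- function(object, ...) {
  if (!length(object$contig_lengths)) {
    abort("no contig lengths recorded (stats built from totals only)")
  }
  lens <- sort(object$contig_lengths, decreasing = TRUE)
  df <- tibble(frac = cumsum(as.numeric(lens)) / sum(as.numeric(lens)) * 100,
               len = lens)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frac, y = .data$len)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$n50, linetype = "dashed") +
    ggplot2::labs(x = "cumulative assembly fraction (%)",
                  y = "contig length (bp)",
                  title = sprintf("Nx curve (N50 = %s bp)",
                                  format(object$n50, big.mark = ","))) +
    ggplot2::theme_minimal()
}

#' @rdname apply_patches
#' @param x A `patch_result`.
#' @param ... Unused.
#' @method tidy patch_result
#' @export
tidy.patch_result <- function(x, ...) {
  select(x$ledger, "chrom", "gap_start", "gap_end", "length", "status",
         "filler", "patched_start", "patched_end")
}

#' @rdname apply_patches
#' @method glance patch_result
#' @export
glance.patch_result <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$genome),
    n_gaps = nrow(x$ledger),
    n_filled = sum(x$ledger$status == "filled"),
    filled_length = sum(x$ledger$length[x$ledger$status == "filled"]),
    patched_length = sum(nchar(x$genome$seq))
  )
}

#' Gap-fill outcome plot
#'
#' Filled vs open gap counts per chromosome.
#'
#' @param object A `patch_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot patch_result
#' @export
autoplot.patch_result <- function(object, ...) {
  ggplot2::ggplot(object$ledger,
                  ggplot2::aes(x = .data$chrom, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "gaps", fill = "status",
                  title = "Gap-fill ledger") +
    ggplot2::theme_minimal()
}

#' @rdname pair_summary
#' @param x A `pair_summary`.
#' @param ... Unused.
#' @method tidy pair_summary
#' @export
tidy.pair_summary <- function(x, ...) x$histogram

#' @rdname pair_summary
#' @method glance pair_summary
#' @export
glance.pair_summary <- function(x, ...) {
  tibble(n_proper = x$n_proper, n_total = x$n_total, rate = x$rate)
}

#' Insert-size histogram plot
#'
#' @param object A `pair_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pair_summary
#' @export
autoplot.pair_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$bin_start + object$bin_width / 2,
                               y = .data$n)) +
    ggplot2::geom_col(width = object$bin_width) +
    ggplot2::labs(x = "insert size (bp)", y = "proper pairs",
                  title = sprintf("Insert sizes (mapping rate %.2f%%)",
                                  object$rate)) +
    ggplot2::theme_minimal()
}

#' @rdname pcoa
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @method tidy pcoa_result
#' @export
tidy.pcoa_result <- function(x, ...) x$coords

#' @rdname pcoa
#' @method glance pcoa_result
#' @export
glance.pcoa_result <- function(x, ...) {
  tibble(axis = seq_len(x$k),
         eigenvalue = x$eigenvalues[seq_len(x$k)],
         contribution = x$contribution)
}

#' Ordination scatter plot
#'
#' First two axes with per-axis contribution rates in the labels.
#'
#' @param object A `pcoa_result` with at least two axes.
#' @param colour Optional grouping vector (e.g. population labels).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pcoa_result
#' @export
autoplot.pcoa_result <- function(object, colour = NULL, ...) {
  if (object$k < 2) abort("need at least two axes to plot")
  df <- object$coords
  if (!is.null(colour)) df$group <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.2f%%)", object$contribution[1]),
      y = sprintf("PC2 (%.2f%%)", object$contribution[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
}
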