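#' Assembly contiguity statistics (thresholded counts, N50, L50)
#'
#' Computes the standard contiguity panel of an assembly report: contig
#' counts and total lengths at minimum-length thresholds, plus N50 and L50.
#' N50 uses the cumulative-sum convention (QUAST-compatible): sort lengths
#' descending; N50 is the length of the contig at which the running total
#' first reaches at least half the assembly length, and L50 is that
#' contig's 1-based rank. When the running total hits exactly half, that
#' contig is the N50 contig.
#'
#' @param contigs Contig tibble with a `length` column (see [read_fasta()]),
#'   or a bare numeric vector of contig lengths.
#' @param thresholds Ascending integer length thresholds in bp
#'   (default `c(0, 25000, 50000)`).
#' @return An `assembly_stats` object: list with `by_threshold` (tibble:
#'   `threshold`, `n_contigs`, `total_length`), `n50`, `l50`,
#'   `total_length`, `longest`, `n_contigs`. `tidy()` returns a long
#'   metric/value table; `glance()` a one-row summary.
#' @examples
#' contiguity_stats(c(8, 5, 4, 2, 1))
#' @export
contiguity_stats <- function(contigs, thresholds = c(0, 25000, 50000)) {
  lengths <- if (is.data.frame(contigs)) {
    check_contigs(contigs)
    contigs$length
  } else {
    contigs
  }
  if (length(lengths) == 0) {
    abort("N50/L50 are undefined for an empty assembly")
  }
  if (any(lengths <= 0) || anyNA(lengths)) {
    abort("Contig lengths must be positive")
  }
  if (is.unsorted(thresholds)) {
    abort("`thresholds` must be sorted ascending")
  }
  lengths <- as.numeric(lengths)
  by_threshold <- tibble(
    threshold = as.integer(thresholds),
    n_contigs = vapply(thresholds, function(t) sum(lengths >= t), numeric(1)),
    total_length = vapply(thresholds, function(t) sum(lengths[lengths >= t]), numeric(1))
  )
  sorted <- sort(lengths, decreasing = TRUE)
  csum <- cumsum(sorted)
  total <- csum[length(csum)]
  i <- which(csum >= total / 2)[1]
  structure(
    list(
      by_threshold = by_threshold,
      n50 = sorted[i],
      l50 = i,
      total_length = total,
      longest = sorted[1],
      n_contigs = length(lengths)
    ),
    class = "assembly_stats"
  )
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(
    "Assembly: ", x$n_contigs, " contigs, ",
    format(x$total_length, big.mark = ","), " bp, N50 ",
    format(x$n50, big.mark = ","), ", L50 ", x$l50, "\n",
    sep = ""
  )
  print(x$by_threshold)
  invisible(x)
}

#' @exportS3Method
tidy.assembly_stats <- function(x, ...) {
  bt <- x$by_threshold
  tibble(
    metric = c(
      paste0("n_contigs_ge_", bt$threshold),
      paste0("total_length_ge_", bt$threshold),
      "n50", "l50"
    ),
    value = c(bt$n_contigs, bt$total_length, x$n50, x$l50)
  )
}

#' @exportS3Method
glance.assembly_stats <- function(x, ...) {
  tibble(
    n_contigs = x$n_contigs,
    total_length = x$total_length,
    longest = x$longest,
    n50 = x$n50,
    l50 = x$l50
  )
}

#' Plot the cumulative length curve of an assembly
#'
#' Descending-sorted cumulative contig length with the N50/L50 point
#' marked.
#'
#' @param object An `assembly_stats` object.
#' @param lengths Optional raw lengths; when omitted the curve is rebuilt
#'   from the stored summary and requires only N50/L50 to annotate.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.assembly_stats <- function(object, lengths = NULL, ...) {
  if (is.null(lengths)) {
    abort("autoplot.assembly_stats needs the raw `lengths` vector")
  }
  sorted <- sort(as.numeric(lengths), decreasing = TRUE)
  d <- tibble(rank = seq_along(sorted), cumulative = cumsum(sorted))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$cumulative)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = object$total_length / 2, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$l50, linetype = "dotted") +
    ggplot2::annotate(
      "point", x = object$l50, y = d$cumulative[object$l50], colour = "red"
    ) +
    ggplot2::labs(
      x = "contig rank (descending length)", y = "cumulative length (bp)",
      title = paste0("N50 ", format(object$n50, big.mark = ","), ", L50 ", object$l50)
    ) +
    ggplot2::theme_minimal()
}
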