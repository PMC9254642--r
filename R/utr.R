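#' Parameters of the distance-gated 3' UTR extension
#'
#' @param extension_bp Constant extension length in bp (default 1,000).
#' @param min_gap_bp Minimum distance to the next annotated feature for the
#'   extension to apply, in bp (default 3,000). Must exceed `extension_bp`,
#'   which guarantees every extension leaves a positive gap
#'   (`min_gap_bp - extension_bp`, 2,000 bp at the defaults) and so can
#'   never create an overlap with a pre-existing feature.
#' @return An `extension_params` object (validated list).
#' @seealso [extend_annotation()]
#' @export
extension_params <- function(extension_bp = 1000, min_gap_bp = 3000) {
  if (extension_bp < 1 || min_gap_bp < 1) {
    abort("extension_bp and min_gap_bp must be positive")
  }
  if (extension_bp >= min_gap_bp) {
    abort("extension_bp must be smaller than min_gap_bp")
  }
  structure(
    list(extension_bp = as.integer(extension_bp), min_gap_bp = as.integer(min_gap_bp)),
    class = "extension_params"
  )
}

#' Distance from each transcript's 3' end to the next annotated feature
#'
#' For every transcript, measures the gap between its 3' end and the nearest
#' gene-locus span beginning strictly 3' of it on the same contig, on either
#' strand, excluding the transcript's own gene. On the plus strand the gap is
#' `next_span_start - three_prime_end - 1`; on the minus strand the mirror
#' (leftward) distance. When no feature lies 3' of the transcript the
#' distance to the contig end is reported with `bounded = TRUE`.
#'
#' @param ann Annotation tibble (see [read_annotation()]).
#' @param genome Contig tibble (sequence not required; `length` is used for
#'   contig bounds).
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `seqid`, `strand`, `three_prime_end`, `gap` (bp), `bounded` (`TRUE`
#'   when the gap runs to the contig end rather than to a feature).
#' @export
downstream_gaps <- function(ann, genome) {
  check_contigs(genome, arg = "genome")
  tt <- transcript_table(ann)
  if (nrow(tt) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(), seqid = character(),
      strand = character(), three_prime_end = integer(), gap = integer(),
      bounded = logical()
    ))
  }
  unknown <- setdiff(tt$seqid, genome$id)
  if (length(unknown) > 0) {
    abort(paste0(
      "Annotation references contig(s) absent from the genome: ",
      paste(head(unknown, 3), collapse = ", ")
    ))
  }
  gt <- gene_table(ann)
  len_of <- setNames(genome$length, genome$id)
  res <- purrr::map(seq_len(nrow(tt)), function(i) {
    t <- tt[i, ]
    tp_end <- if (t$strand == "+") t$end else t$start
    others <- gt[gt$seqid == t$seqid & gt$gene_id != t$gene_id, , drop = FALSE]
    if (t$strand == "+") {
      cand <- others$start[others$start > tp_end]
      if (length(cand) > 0) {
        gap <- min(cand) - tp_end - 1L
        bounded <- FALSE
      } else {
        gap <- len_of[[t$seqid]] - tp_end
        bounded <- TRUE
      }
    } else {
      cand <- others$end[others$end < tp_end]
      if (length(cand) > 0) {
        gap <- tp_end - max(cand) - 1L
        bounded <- FALSE
      } else {
        gap <- tp_end - 1L
        bounded <- TRUE
      }
    }
    tibble(
      transcript_id = t$transcript_id, gene_id = t$gene_id, seqid = t$seqid,
      strand = t$strand, three_prime_end = as.integer(tp_end),
      gap = as.integer(gap), bounded = bounded
    )
  })
  bind_rows(res)
}

#' Extend one transcript's 3'-terminal exon
#'
#' Applies the extension rule to a single transcript given its precomputed
#' downstream gap: when the gap reaches `min_gap_bp` — or when no downstream
#' feature exists (`bounded = TRUE`), in which case only the contig end
#' limits the extension — the 3'-terminal exon end (plus strand) or start
#' (minus strand) moves outward by `extension_bp`, clamped to the contig
#' bounds. CDS rows, exon count and strand are never touched.
#'
#' @param tx Annotation rows of one transcript.
#' @param gap Downstream gap in bp (see [downstream_gaps()]).
#' @param params An [extension_params()].
#' @param contig_length Length of the transcript's contig in bp.
#' @param bounded Whether `gap` runs to the contig end rather than a feature.
#' @return The (possibly) modified transcript rows, with an
#'   `extension_applied` attribute giving the bp actually added.
#' @export
extend_three_prime_utr <- function(tx, gap, params = extension_params(),
                                   contig_length, bounded = FALSE) {
  applied <- 0L
  eligible <- bounded || gap >= params$min_gap_bp
  if (eligible) {
    ex <- which(tx$feature == "exon")
    if (tx$strand[1] == "+") {
      i <- ex[which.max(tx$end[ex])]
      room <- contig_length - tx$end[i]
      applied <- as.integer(min(params$extension_bp, room))
      tx$end[i] <- tx$end[i] + applied
    } else {
      i <- ex[which.min(tx$start[ex])]
      room <- tx$start[i] - 1L
      applied <- as.integer(min(params$extension_bp, room))
      tx$start[i] <- tx$start[i] - applied
    }
  }
  attr(tx, "extension_applied") <- applied
  tx
}

#' Extend annotated 3' UTRs by a constant, distance-gated amount
#'
#' Implements the post-curation UTR lengthening used to improve read
#' assignment in 3'-biased sequencing: every transcript whose distance to
#' the next annotated feature (same or opposite strand) is at least
#' `min_gap_bp` has its 3'-terminal exon extended outward by a constant
#' `extension_bp`, clamped at contig ends. All gaps are computed once
#' against the pre-extension annotation and then applied, so the result is
#' independent of gene order and no extension can cascade into another.
#' Because `extension_bp < min_gap_bp`, extensions can never create an
#' overlap with a pre-existing feature.
#'
#' @param ann Curated annotation tibble.
#' @param genome Contig tibble (lengths used for clamping).
#' @param params An [extension_params()].
#' @return A `utr_extension` object: list with `annotation` (modified
#'   table), `log` (per-transcript tibble: `transcript_id`, `gap`,
#'   `bounded`, `extended`, `extension_applied`, `clamped`) and `params`.
#'   `tidy()` returns the log, `glance()` the summary.
#' @export
extend_annotation <- function(ann, genome, params = extension_params()) {
  check_annotation(ann)
  gaps <- downstream_gaps(ann, genome)
  len_of <- setNames(genome$length, genome$id)
  pieces <- list()
  log <- list()
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    tx <- ann[ann$transcript_id == g$transcript_id, , drop = FALSE]
    new_tx <- extend_three_prime_utr(
      tx, g$gap, params, len_of[[g$seqid]],
      bounded = g$bounded
    )
    applied <- attr(new_tx, "extension_applied")
    attr(new_tx, "extension_applied") <- NULL
    pieces[[i]] <- new_tx
    log[[i]] <- tibble(
      transcript_id = g$transcript_id, gene_id = g$gene_id,
      seqid = g$seqid, strand = g$strand,
      gap = g$gap, bounded = g$bounded,
      extended = applied > 0L,
      extension_applied = applied,
      clamped = (g$bounded || g$gap >= params$min_gap_bp) &
        applied < params$extension_bp
    )
  }
  out <- if (length(pieces) > 0) bind_rows(pieces) else ann
  check_annotation(out)
  structure(
    list(annotation = out, log = bind_rows(log), params = params),
    class = "utr_extension"
  )
}

#' @export
print.utr_extension <- function(x, ...) {
  g <- glance(x)
  cat(
    "3' UTR extension: ", g$n_extended, "/", g$n_transcripts,
    " transcripts extended by <= ", x$params$extension_bp, " bp (",
    g$n_clamped, " clamped at contig ends)\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method
tidy.utr_extension <- function(x, ...) {
  x$log
}

#' @exportS3Method
glance.utr_extension <- function(x, ...) {
  tibble(
    n_transcripts = nrow(x$log),
    n_extended = sum(x$log$extended),
    n_clamped = sum(x$log$clamped),
    total_bp_added = sum(x$log$extension_applied),
    extension_bp = x$params$extension_bp,
    min_gap_bp = x$params$min_gap_bp
  )
}

#' Plot downstream gaps against the extension gate
#'
#' Histogram of per-transcript downstream gaps with the `min_gap_bp` gate
#' marked; extended transcripts are coloured.
#'
#' @param object A `utr_extension` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.utr_extension <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$gap, fill = .data$extended)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::geom_vline(
      xintercept = object$params$min_gap_bp, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "downstream gap (bp)", y = "transcripts",
      title = "3' UTR extension gating"
    ) +
    ggplot2::theme_minimal()
}

#' Quantify the effect of UTR extension on read assignment
#'
#' Compares per-gene read-assignment counts before and after an annotation
#' change: the percent change in total assigned reads, the number of newly
#' detected genes (zero reads before, any read after) and the number of
#' genes whose counts grew by at least `gain_threshold` (default 20%).
#'
#' @param counts_before,counts_after Tibbles with `gene_id` and `count`
#'   columns; genes missing from one table count as zero there.
#' @param gain_threshold Relative gain counted as a meaningful increase
#'   (default `0.2`, i.e. at least 20%; the boundary is inclusive).
#' @return An `assignment_delta` object: one-row tibble with
#'   `percent_total_increase`, `newly_detected_genes`,
#'   `genes_gaining_ge_threshold`, `gain_threshold`, `total_before`,
#'   `total_after`.
#' @examples
#' before <- tibble::tibble(gene_id = c("g1", "g2"), count = c(100, 0))
#' after <- tibble::tibble(gene_id = c("g1", "g2"), count = c(125, 10))
#' quantify_extension_effect(before, after)
#' @export
quantify_extension_effect <- function(counts_before, counts_after,
                                      gain_threshold = 0.2) {
  chk <- function(x, arg) {
    if (!all(c("gene_id", "count") %in% names(x))) {
      abort(paste0("`", arg, "` must have columns gene_id, count"))
    }
    if (anyDuplicated(x$gene_id)) {
      abort(paste0("`", arg, "` has duplicated gene ids"))
    }
  }
  chk(counts_before, "counts_before")
  chk(counts_after, "counts_after")
  merged <- full_join(
    counts_before %>% select("gene_id", before = "count"),
    counts_after %>% select("gene_id", after = "count"),
    by = "gene_id"
  ) %>%
    mutate(
      before = tidyr::replace_na(.data$before, 0),
      after = tidyr::replace_na(.data$after, 0)
    )
  total_before <- sum(merged$before)
  total_after <- sum(merged$after)
  if (total_before == 0) {
    abort("Total count before is zero; percent increase is undefined")
  }
  # inclusive >= threshold boundary; epsilon guards binary-fraction rounding
  gaining <- merged$before > 0 &
    merged$after > merged$before &
    merged$after >= merged$before * (1 + gain_threshold) - 1e-9
  out <- tibble(
    percent_total_increase = 100 * (total_after - total_before) / total_before,
    newly_detected_genes = sum(merged$before == 0 & merged$after > 0),
    genes_gaining_ge_threshold = sum(gaining),
    gain_threshold = gain_threshold,
    total_before = total_before,
    total_after = total_after
  )
  class(out) <- c("assignment_delta", class(out))
  out
}
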