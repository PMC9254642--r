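## Five-rule curation pipeline for homology-predicted gene annotations.
## Each rule takes and returns the tidy exon-level annotation table and
## appends its actions to the `curation_log` attribute, so rules compose with
## the pipe and curate() can report a full audit trail.

empty_curation_log <- function() {
  tibble(
    rule = character(), entity_id = character(),
    action = character(), detail = character()
  )
}

curation_log_of <- function(ann) {
  lg <- attr(ann, "curation_log", exact = TRUE)
  if (is.null(lg)) empty_curation_log() else lg
}

append_curation_log <- function(ann, entries) {
  attr(ann, "curation_log") <- bind_rows(curation_log_of(ann), entries)
  ann
}

set_curation_log <- function(ann, lg) {
  attr(ann, "curation_log") <- lg
  ann
}

drop_transcripts <- function(ann, tx_ids) {
  lg <- curation_log_of(ann)
  out <- ann[!ann$transcript_id %in% tx_ids, , drop = FALSE]
  set_curation_log(out, lg)
}

#' Keep only transcripts matching each locus's top-scoring gene name
#'
#' When the transcripts predicted at a single locus carry different source
#' gene names, only those sharing the gene name of the locus's
#' highest-scoring transcript are retained. The top transcript itself always
#' survives, so a locus is never emptied. A tie in the top score keeps the
#' name of the tied transcript occurring first in input order.
#'
#' @param ann Annotation tibble (see [read_annotation()]).
#' @return The filtered annotation, with actions appended to its
#'   `curation_log` attribute.
#' @family curation rules
#' @export
resolve_locus_gene_names <- function(ann) {
  if (nrow(ann) == 0) {
    return(append_curation_log(ann, NULL))
  }
  tt <- transcript_table(ann)
  entries <- list()
  doomed <- character()
  for (g in split(tt, tt$gene_id)[unique(tt$gene_id)]) {
    top <- which.max(g$score) # first max = first in input order on ties
    top_name <- g$gene_name[top]
    same <- if (is.na(top_name)) is.na(g$gene_name) else {
      !is.na(g$gene_name) & g$gene_name == top_name
    }
    if (all(same)) next
    bad <- g$transcript_id[!same]
    doomed <- c(doomed, bad)
    entries[[length(entries) + 1]] <- tibble(
      rule = "resolve_gene_names", entity_id = bad,
      action = "removed_transcript",
      detail = paste0(
        "gene_name '", g$gene_name[!same], "' != top-scoring '",
        ifelse(is.na(top_name), "<none>", top_name), "' at locus ", g$gene_id[1]
      )
    )
  }
  append_curation_log(drop_transcripts(ann, doomed), bind_rows(entries))
}

#' Deduplicate gene loci sharing the same gene name
#'
#' When one gene name is associated with several annotated loci, only the
#' locus whose top transcript score is highest survives. Unnamed loci are
#' never removed. Ties break to the locus with the smaller leftmost
#' coordinate, then to the lexicographically smaller locus id.
#'
#' @inheritParams resolve_locus_gene_names
#' @return The filtered annotation with updated `curation_log`.
#' @family curation rules
#' @export
dedupe_named_loci <- function(ann) {
  if (nrow(ann) == 0) {
    return(append_curation_log(ann, NULL))
  }
  gt <- gene_table(ann)
  named <- gt[!is.na(gt$gene_name), , drop = FALSE]
  entries <- list()
  doomed_genes <- character()
  for (grp in split(named, named$gene_name)) {
    if (nrow(grp) < 2) next
    keep <- order(-grp$top_score, grp$start, grp$gene_id)[1]
    lose <- grp$gene_id[-keep]
    doomed_genes <- c(doomed_genes, lose)
    entries[[length(entries) + 1]] <- tibble(
      rule = "dedupe_named_loci", entity_id = lose,
      action = "removed_locus",
      detail = paste0(
        "gene_name '", grp$gene_name[1], "' kept at locus ", grp$gene_id[keep],
        " (top score ", grp$top_score[keep], ")"
      )
    )
  }
  doomed_tx <- unique(ann$transcript_id[ann$gene_id %in% doomed_genes])
  append_curation_log(drop_transcripts(ann, doomed_tx), bind_rows(entries))
}

#' Remove exons shared between different gene loci
#'
#' An exon interval (identical seqid, start, end and strand) present in
#' transcripts of two or more *different* genes marks a gene-fusion artifact
#' (typically from UTR inference): the exon is trimmed from every owning
#' transcript. Exons shared only between isoforms of the same gene are
#' untouched. CDS intervals lying inside a trimmed exon are removed with it;
#' a transcript losing all its exons is removed.
#'
#' @inheritParams resolve_locus_gene_names
#' @return The trimmed annotation with updated `curation_log`.
#' @family curation rules
#' @export
strip_shared_exons <- function(ann) {
  if (nrow(ann) == 0) {
    return(append_curation_log(ann, NULL))
  }
  ex <- ann[ann$feature == "exon", , drop = FALSE]
  key <- paste(ex$seqid, ex$start, ex$end, ex$strand, sep = ":")
  n_genes <- tapply(ex$gene_id, key, function(g) length(unique(g)))
  shared <- names(n_genes)[n_genes > 1]
  if (length(shared) == 0) {
    return(append_curation_log(ann, NULL))
  }
  lg <- curation_log_of(ann)
  entries <- list()
  out <- ann
  for (k in shared) {
    owners <- ex[key == k, , drop = FALSE]
    # drop the exon rows and any CDS rows contained in the interval, in
    # every owning transcript
    s <- owners$start[1]
    e <- owners$end[1]
    in_owner <- out$transcript_id %in% owners$transcript_id
    drop_exon <- in_owner & out$feature == "exon" & out$start == s & out$end == e
    drop_cds <- in_owner & out$feature == "cds" & out$start >= s & out$end <= e
    had_cds <- any(drop_cds)
    out <- out[!(drop_exon | drop_cds), , drop = FALSE]
    entries[[length(entries) + 1]] <- tibble(
      rule = "strip_shared_exons", entity_id = k, action = "trimmed_exon",
      detail = paste0(
        "shared by ", length(unique(owners$gene_id)), " genes; trimmed from ",
        nrow(owners), " transcript(s)",
        if (had_cds) "; contained CDS removed" else ""
      )
    )
  }
  emptied <- setdiff(
    unique(ann$transcript_id),
    unique(out$transcript_id[out$feature == "exon"])
  )
  if (length(emptied) > 0) {
    out <- out[!out$transcript_id %in% emptied, , drop = FALSE]
    entries[[length(entries) + 1]] <- tibble(
      rule = "strip_shared_exons", entity_id = emptied,
      action = "removed_transcript", detail = "all exons were shared"
    )
  }
  set_curation_log(out, bind_rows(lg, bind_rows(entries)))
}

reverse_complement <- function(x) {
  chartr(
    "ACGTacgt", "TGCAtgca",
    vapply(x, function(s) {
      paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  )
}

# Donor-acceptor dinucleotide pairs of a transcript's introns, read in
# transcript orientation ("GT-AG" etc.); zero/short introns yield "--".
intron_consensus <- function(exons_sorted, strand, seq) {
  n <- nrow(exons_sorted)
  if (n < 2) {
    return(character(0))
  }
  istart <- exons_sorted$end[-n] + 1L
  iend <- exons_sorted$start[-1] - 1L
  vapply(seq_len(n - 1), function(i) {
    if (iend[i] - istart[i] + 1L < 4L) {
      return("--")
    }
    left <- substr(seq, istart[i], istart[i] + 1L)
    right <- substr(seq, iend[i] - 1L, iend[i])
    if (strand == "+") {
      paste0(left, "-", right)
    } else {
      paste0(reverse_complement(right), "-", reverse_complement(left))
    }
  }, character(1))
}

#' Remove transcripts with short exons or noncanonical splice sites
#'
#' Eliminates any transcript that has an exon shorter than `min_exon_len`
#' ("shorter than" is strict: a 15 bp exon survives the 15 bp default) or an
#' intron whose donor/acceptor dinucleotides — read in transcript
#' orientation, i.e. reverse-complemented on the minus strand — are not in
#' the allowed consensus set. A locus whose transcripts are all eliminated
#' disappears. Introns shorter than 4 bp cannot host both dinucleotides and
#' are treated as noncanonical.
#'
#' @inheritParams resolve_locus_gene_names
#' @param genome Contig tibble with sequences (see [read_fasta()]).
#' @param min_exon_len Minimum exon length in bp (default 15).
#' @param splice_canon Character vector of allowed `"donor-acceptor"` pairs;
#'   default `"GT-AG"`. Add `"GC-AG"` and/or `"AT-AC"` to admit the minor
#'   spliceosomal consensi.
#' @return The filtered annotation with updated `curation_log`.
#' @family curation rules
#' @export
filter_structural <- function(ann, genome, min_exon_len = 15,
                              splice_canon = "GT-AG") {
  if (nrow(ann) == 0) {
    return(append_curation_log(ann, NULL))
  }
  check_contigs(genome, need_sequence = TRUE, arg = "genome")
  seq_of <- setNames(genome$sequence, genome$id)
  len_of <- setNames(genome$length, genome$id)
  entries <- list()
  doomed <- character()
  for (tx in split(ann, ann$transcript_id)[unique(ann$transcript_id)]) {
    id <- tx$transcript_id[1]
    seqid <- tx$seqid[1]
    if (!seqid %in% names(seq_of)) {
      abort(paste0("Transcript ", id, ": seqid '", seqid, "' not in genome"))
    }
    ex <- tx[tx$feature == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (max(ex$end) > len_of[[seqid]]) {
      abort(paste0(
        "Transcript ", id, ": exon end ", max(ex$end),
        " exceeds length of contig ", seqid
      ))
    }
    lens <- ex$end - ex$start + 1L
    if (any(lens < min_exon_len)) {
      doomed <- c(doomed, id)
      entries[[length(entries) + 1]] <- tibble(
        rule = "filter_structural", entity_id = id,
        action = "removed_transcript",
        detail = paste0("exon of ", min(lens), " bp < ", min_exon_len, " bp")
      )
      next
    }
    cons <- intron_consensus(ex, tx$strand[1], seq_of[[seqid]])
    bad <- !cons %in% splice_canon
    if (any(bad)) {
      doomed <- c(doomed, id)
      entries[[length(entries) + 1]] <- tibble(
        rule = "filter_structural", entity_id = id,
        action = "removed_transcript",
        detail = paste0(
          "noncanonical splice consensus ",
          paste(unique(cons[bad]), collapse = ",")
        )
      )
    }
  }
  append_curation_log(drop_transcripts(ann, doomed), bind_rows(entries))
}

#' Deduplicate isoforms with identical exon boundaries
#'
#' Among a gene's transcripts sharing an identical ordered exon boundary
#' list, all but the one with the longest spliced CDS are dropped; ties
#' break to the lexicographically smallest transcript id.
#'
#' @inheritParams resolve_locus_gene_names
#' @return The filtered annotation with updated `curation_log`.
#' @family curation rules
#' @export
dedupe_identical_isoforms <- function(ann) {
  if (nrow(ann) == 0) {
    return(append_curation_log(ann, NULL))
  }
  tt <- transcript_table(ann)
  ex <- ann[ann$feature == "exon", , drop = FALSE]
  sig <- tapply(
    paste0(ex$start, "-", ex$end),
    ex$transcript_id,
    function(p) paste(p[order(as.integer(sub("-.*", "", p)))], collapse = ";")
  )
  tt$signature <- unname(sig[tt$transcript_id])
  entries <- list()
  doomed <- character()
  for (grp in split(tt, paste(tt$gene_id, tt$signature, sep = "\r"))) {
    if (nrow(grp) < 2) next
    keep <- order(-grp$cds_length, grp$transcript_id)[1]
    lose <- grp$transcript_id[-keep]
    doomed <- c(doomed, lose)
    entries[[length(entries) + 1]] <- tibble(
      rule = "dedupe_isoforms", entity_id = lose,
      action = "removed_transcript",
      detail = paste0(
        "identical exon boundaries as ", grp$transcript_id[keep],
        " (CDS ", grp$cds_length[keep], " bp kept)"
      )
    )
  }
  append_curation_log(drop_transcripts(ann, doomed), bind_rows(entries))
}

#' Curate a predicted gene annotation
#'
#' Runs the five cleaning rules as a deterministic pipeline, in this fixed
#' order: [resolve_locus_gene_names()], [dedupe_named_loci()],
#' [strip_shared_exons()], [filter_structural()],
#' [dedupe_identical_isoforms()]. The pipeline is idempotent: curating an
#' already-curated annotation changes nothing.
#'
#' @param ann Annotation tibble (see [read_annotation()]).
#' @param genome Contig tibble with sequences, required by the splice-site
#'   check.
#' @param min_exon_len,splice_canon Passed to [filter_structural()].
#' @return A `curation_result`: list with `annotation` (the cleaned table),
#'   `report` (ordered action log: `rule`, `entity_id`, `action`, `detail`)
#'   and `counts` (per-stage transcript accounting). `tidy()` returns the
#'   report, `glance()` the summary counters.
#' @export
curate <- function(ann, genome, min_exon_len = 15, splice_canon = "GT-AG") {
  check_annotation(ann)
  stages <- list(
    resolve_gene_names = resolve_locus_gene_names,
    dedupe_named_loci = dedupe_named_loci,
    strip_shared_exons = strip_shared_exons,
    filter_structural = function(a) {
      filter_structural(a, genome,
        min_exon_len = min_exon_len,
        splice_canon = splice_canon
      )
    },
    dedupe_isoforms = dedupe_identical_isoforms
  )
  cur <- set_curation_log(ann, empty_curation_log())
  counts <- list()
  for (nm in names(stages)) {
    n_in <- length(unique(cur$transcript_id))
    cur <- stages[[nm]](cur)
    n_out <- length(unique(cur$transcript_id))
    counts[[length(counts) + 1]] <- tibble(
      stage = nm, transcripts_in = n_in, transcripts_out = n_out,
      transcripts_removed = n_in - n_out
    )
  }
  report <- curation_log_of(cur)
  out <- cur
  attr(out, "curation_log") <- NULL
  structure(
    list(annotation = out, report = report, counts = bind_rows(counts)),
    class = "curation_result"
  )
}

#' @export
print.curation_result <- function(x, ...) {
  g <- glance(x)
  cat(
    "Annotation curation: ", g$transcripts_in, " transcripts in, ",
    g$transcripts_out, " out (", g$loci_out, " loci); ",
    g$exons_trimmed, " shared exon(s) trimmed\n",
    sep = ""
  )
  print(x$counts)
  invisible(x)
}

#' @exportS3Method
tidy.curation_result <- function(x, ...) {
  x$report
}

#' @exportS3Method
glance.curation_result <- function(x, ...) {
  cnt <- x$counts
  tibble(
    transcripts_in = cnt$transcripts_in[1],
    transcripts_out = tail(cnt$transcripts_out, 1),
    loci_out = length(unique(x$annotation$gene_id)),
    removed_resolve_gene_names = cnt$transcripts_removed[cnt$stage == "resolve_gene_names"],
    removed_dedupe_named_loci = cnt$transcripts_removed[cnt$stage == "dedupe_named_loci"],
    removed_strip_shared_exons = cnt$transcripts_removed[cnt$stage == "strip_shared_exons"],
    removed_filter_structural = cnt$transcripts_removed[cnt$stage == "filter_structural"],
    removed_dedupe_isoforms = cnt$transcripts_removed[cnt$stage == "dedupe_isoforms"],
    exons_trimmed = sum(x$report$action == "trimmed_exon")
  )
}

#' Plot curation actions per rule
#'
#' @param object A `curation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.curation_result <- function(object, ...) {
  d <- dplyr::count(object$report, .data$rule, .data$action)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rule, y = .data$n, fill = .data$action)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "actions", title = "Curation actions by rule"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
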