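#' Read a gene annotation (GFF3 or GTF) into a tidy exon-level table
#'
#' Parses a gene/mRNA/exon/CDS feature hierarchy — linked by `ID`/`Parent`
#' attributes (GFF3) or by `gene_id`/`transcript_id` (GTF) — into one tibble
#' row per exon or CDS interval. All coordinates are 1-based inclusive, the
#' native convention of both dialects; exon length is `end - start + 1`.
#'
#' The per-transcript prediction score (e.g. the confidence emitted by a
#' homology-based predictor such as GeMoMa) is taken from the GFF score
#' column of the mRNA/transcript feature, falling back to the attribute named
#' by `score_attr`. The source-reference gene symbol is read from the
#' attribute named by `gene_name_attr`.
#'
#' @param path Path to the annotation file.
#' @param dialect `"gff3"` or `"gtf"`.
#' @param score_attr Optional attribute key holding the prediction score when
#'   the score column is empty.
#' @param gene_name_attr Attribute key holding the source gene symbol
#'   (default `"gene_name"`).
#' @return A tibble with columns `seqid`, `feature` (`"exon"` or `"cds"`),
#'   `start`, `end`, `strand` (`"+"`/`"-"`), `gene_id`, `transcript_id`,
#'   `gene_name` (may be `NA`) and `score`. Transcript input order is
#'   preserved; within a transcript, exons come before CDS rows, each sorted
#'   by `start`.
#' @seealso [write_annotation()], [curate()], [extend_annotation()]
#' @export
read_annotation <- function(path, dialect = c("gff3", "gtf"),
                            score_attr = NULL, gene_name_attr = "gene_name") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("Annotation file not found: ", path))
  }
  gr <- rtracklayer::import(path, format = dialect)
  mc <- as.data.frame(gr)
  mc$type <- as.character(mc$type)
  mc$strand <- as.character(mc$strand)
  mc$seqnames <- as.character(mc$seqnames)

  attr_or_na <- function(df, key) {
    if (key %in% names(df)) as.character(df[[key]]) else rep(NA_character_, nrow(df))
  }

  if (dialect == "gff3") {
    # Parent is a CharacterList; our models have single parents.
    parent <- vapply(
      as.list(mc$Parent),
      function(p) if (length(p) == 0) NA_character_ else p[[1]],
      character(1)
    )
    id <- attr_or_na(mc, "ID")
    is_gene <- mc$type == "gene"
    is_tx <- mc$type %in% c("mRNA", "transcript")
    is_part <- mc$type %in% c("exon", "CDS")
    gene_ids <- id[is_gene]
    tx <- mc[is_tx, , drop = FALSE]
    tx_id <- id[is_tx]
    tx_parent <- parent[is_tx]
    if (anyNA(tx_id)) {
      abort(paste0("Annotation '", path, "': mRNA feature without ID"))
    }
    orphan <- !tx_parent %in% gene_ids
    if (any(orphan)) {
      abort(paste0(
        "Annotation '", path, "': transcript(s) with missing gene parent: ",
        paste(head(tx_id[orphan], 3), collapse = ", ")
      ))
    }
    part <- mc[is_part, , drop = FALSE]
    part_parent <- parent[is_part]
    orphan <- is.na(part_parent) | !part_parent %in% tx_id
    if (any(orphan)) {
      abort(paste0(
        "Annotation '", path, "': exon/CDS feature(s) whose Parent is not a ",
        "known transcript: ",
        paste(head(unique(part_parent[orphan]), 3), collapse = ", ")
      ))
    }
    tx_gene <- setNames(tx_parent, tx_id)
    score <- tx$score
    if (!is.null(score_attr)) {
      fb <- suppressWarnings(as.numeric(attr_or_na(tx, score_attr)))
      score <- ifelse(is.na(score), fb, score)
    }
    gname <- attr_or_na(tx, gene_name_attr)
    tx_info <- tibble(
      transcript_id = tx_id,
      gene_id = unname(tx_gene[tx_id]),
      gene_name = gname,
      score = as.numeric(score),
      tx_start = tx$start, tx_end = tx$end
    )
    out <- tibble(
      seqid = part$seqnames,
      feature = ifelse(part$type == "CDS", "cds", "exon"),
      start = part$start, end = part$end,
      strand = part$strand,
      transcript_id = part_parent
    ) %>% left_join(tx_info, by = "transcript_id")
    # exon outside the declared transcript span is a structural error
    bad <- out$feature == "exon" &
      (out$start < out$tx_start | out$end > out$tx_end)
    if (any(bad)) {
      abort(paste0(
        "Annotation '", path, "': exon outside its transcript's span in ",
        paste(head(unique(out$transcript_id[bad]), 3), collapse = ", ")
      ))
    }
    out$tx_start <- out$tx_end <- NULL
  } else {
    need <- c("gene_id", "transcript_id")
    if (!all(need %in% names(mc))) {
      abort(paste0("Annotation '", path, "': GTF lacks gene_id/transcript_id"))
    }
    is_tx <- mc$type == "transcript"
    is_part <- mc$type %in% c("exon", "CDS")
    part <- mc[is_part, , drop = FALSE]
    if (any(is.na(part$transcript_id) | is.na(part$gene_id))) {
      abort(paste0(
        "Annotation '", path, "': exon/CDS row without transcript_id/gene_id"
      ))
    }
    tx <- mc[is_tx, , drop = FALSE]
    score_of <- function(txid) {
      i <- match(txid, tx$transcript_id)
      s <- tx$score[i]
      if (!is.null(score_attr)) {
        fb <- suppressWarnings(as.numeric(attr_or_na(tx, score_attr)))[i]
        s <- ifelse(is.na(s), fb, s)
      }
      as.numeric(s)
    }
    name_of <- function(txid) attr_or_na(tx, gene_name_attr)[match(txid, tx$transcript_id)]
    out <- tibble(
      seqid = part$seqnames,
      feature = ifelse(part$type == "CDS", "cds", "exon"),
      start = part$start, end = part$end,
      strand = part$strand,
      gene_id = as.character(part$gene_id),
      transcript_id = as.character(part$transcript_id),
      gene_name = if (nrow(tx) > 0) {
        name_of(part$transcript_id)
      } else {
        attr_or_na(part, gene_name_attr)
      },
      score = if (nrow(tx) > 0) score_of(part$transcript_id) else part$score
    )
  }
  ann <- out %>%
    select(
      "seqid", "feature", "start", "end", "strand",
      "gene_id", "transcript_id", "gene_name", "score"
    ) %>%
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  check_annotation(ann)
  normalise_annotation(ann)
}

# Canonical row order: transcripts in first-appearance order; exon rows
# before cds rows within a transcript, each ascending by start.
normalise_annotation <- function(ann) {
  tx_rank <- match(ann$transcript_id, unique(ann$transcript_id))
  ann[order(tx_rank, match(ann$feature, c("exon", "cds")), ann$start), ]
}

#' Validate the structural invariants of an annotation table
#'
#' Checks, per transcript: a single seqid and strand; exons sorted and
#' non-overlapping; every CDS interval contained in the union of exons;
#' `start <= end` everywhere.
#'
#' @param ann Annotation tibble (see [read_annotation()]).
#' @return `ann`, invisibly; errors describe the first violation found.
#' @export
check_annotation <- function(ann) {
  need <- c(
    "seqid", "feature", "start", "end", "strand",
    "gene_id", "transcript_id", "gene_name", "score"
  )
  missing <- setdiff(need, names(ann))
  if (length(missing) > 0) {
    abort(paste0("Annotation lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(ann) == 0) {
    return(invisible(ann))
  }
  if (any(ann$start < 1) || any(ann$start > ann$end)) {
    abort("Annotation has interval(s) with start < 1 or start > end")
  }
  if (!all(ann$feature %in% c("exon", "cds"))) {
    abort("Annotation feature column must be 'exon' or 'cds'")
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    abort("Annotation strand must be '+' or '-'")
  }
  per_tx <- split(ann, ann$transcript_id)
  for (tx in per_tx) {
    id <- tx$transcript_id[1]
    if (length(unique(tx$strand)) > 1) {
      abort(paste0("Transcript ", id, " mixes strands"))
    }
    if (length(unique(tx$seqid)) > 1) {
      abort(paste0("Transcript ", id, " spans multiple seqids"))
    }
    if (length(unique(tx$gene_id)) > 1) {
      abort(paste0("Transcript ", id, " assigned to multiple genes"))
    }
    ex <- tx[tx$feature == "exon", , drop = FALSE]
    if (nrow(ex) == 0) {
      abort(paste0("Transcript ", id, " has no exons"))
    }
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1 && any(ex$start[-1] <= ex$end[-nrow(ex)])) {
      abort(paste0("Transcript ", id, " has overlapping exons"))
    }
    cds <- tx[tx$feature == "cds", , drop = FALSE]
    if (nrow(cds) > 0) {
      inside <- vapply(seq_len(nrow(cds)), function(i) {
        any(cds$start[i] >= ex$start & cds$end[i] <= ex$end)
      }, logical(1))
      if (!all(inside)) {
        abort(paste0("Transcript ", id, " has CDS outside its exon union"))
      }
    }
  }
  gstr <- tapply(ann$strand, ann$gene_id, function(s) length(unique(s)))
  if (any(gstr > 1)) {
    abort(paste0(
      "Gene(s) mix strands across transcripts: ",
      paste(head(names(gstr)[gstr > 1], 3), collapse = ", ")
    ))
  }
  invisible(ann)
}

#' Summarise an annotation at transcript level
#'
#' @param ann Annotation tibble.
#' @return One row per transcript: `transcript_id`, `gene_id`, `gene_name`,
#'   `seqid`, `strand`, `score`, `start`, `end` (exon-union span), `n_exons`,
#'   `cds_length` (spliced CDS bp, 0 when absent). Transcript input order is
#'   preserved.
#' @export
transcript_table <- function(ann) {
  if (nrow(ann) == 0) {
    return(tibble(
      transcript_id = character(), gene_id = character(),
      gene_name = character(), seqid = character(), strand = character(),
      score = double(), start = integer(), end = integer(),
      n_exons = integer(), cds_length = integer()
    ))
  }
  ord <- unique(ann$transcript_id)
  ann %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id),
      gene_name = first(.data$gene_name),
      seqid = first(.data$seqid),
      strand = first(.data$strand),
      score = first(.data$score),
      start = min(.data$start[.data$feature == "exon"]),
      end = max(.data$end[.data$feature == "exon"]),
      n_exons = sum(.data$feature == "exon"),
      cds_length = sum((.data$end - .data$start + 1L)[.data$feature == "cds"]),
      .groups = "drop"
    ) %>%
    arrange(match(.data$transcript_id, ord))
}

#' Summarise an annotation at gene-locus level
#'
#' @param ann Annotation tibble.
#' @return One row per gene: `gene_id`, `seqid`, `strand`, `start`, `end`
#'   (span over all member transcripts), `n_transcripts`, `top_score`,
#'   `gene_name` of the top-scoring transcript. Gene input order preserved.
#' @export
gene_table <- function(ann) {
  tt <- transcript_table(ann)
  if (nrow(tt) == 0) {
    return(tibble(
      gene_id = character(), seqid = character(), strand = character(),
      start = integer(), end = integer(), n_transcripts = integer(),
      top_score = double(), gene_name = character()
    ))
  }
  ord <- unique(tt$gene_id)
  tt %>%
    group_by(.data$gene_id) %>%
    summarise(
      seqid = first(.data$seqid),
      strand = first(.data$strand),
      start = min(.data$start),
      end = max(.data$end),
      n_transcripts = n(),
      top_score = max(.data$score),
      gene_name = .data$gene_name[which.max(.data$score)],
      .groups = "drop"
    ) %>%
    arrange(match(.data$gene_id, ord))
}

#' Write an annotation table as GFF3
#'
#' Emits a deterministic gene → mRNA → exon/CDS hierarchy: genes sorted by
#' (seqid, start, gene_id), transcripts within a gene by (start,
#' transcript_id). Gene and mRNA spans are recomputed from the exon unions.
#' CDS phase is derived from the cumulative coding length in transcript
#' orientation.
#'
#' @param ann Annotation tibble (see [read_annotation()]).
#' @param path Output path.
#' @param source Value for the GFF source column (default `"gencurate"`).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path, source = "gencurate") {
  check_annotation(ann)
  lines <- "##gff-version 3"
  if (nrow(ann) > 0) {
    tt <- transcript_table(ann)
    gt <- gene_table(ann)
    gt <- gt %>% arrange(.data$seqid, .data$start, .data$gene_id)
    fmt_score <- function(s) ifelse(is.na(s), ".", sprintf("%.6g", s))
    for (gi in seq_len(nrow(gt))) {
      g <- gt[gi, ]
      lines <- c(lines, paste(
        g$seqid, source, "gene", g$start, g$end, ".", g$strand, ".",
        paste0("ID=", g$gene_id),
        sep = "\t"
      ))
      txs <- tt %>%
        filter(.data$gene_id == g$gene_id) %>%
        arrange(.data$start, .data$transcript_id)
      for (ti in seq_len(nrow(txs))) {
        t <- txs[ti, ]
        attrs <- paste0("ID=", t$transcript_id, ";Parent=", g$gene_id)
        if (!is.na(t$gene_name)) {
          attrs <- paste0(attrs, ";gene_name=", t$gene_name)
        }
        lines <- c(lines, paste(
          t$seqid, source, "mRNA", t$start, t$end, fmt_score(t$score),
          t$strand, ".", attrs,
          sep = "\t"
        ))
        rows <- ann %>%
          filter(.data$transcript_id == t$transcript_id) %>%
          arrange(match(.data$feature, c("exon", "cds")), .data$start)
        ex <- rows %>% filter(.data$feature == "exon")
        cds <- rows %>% filter(.data$feature == "cds")
        lines <- c(lines, paste(
          ex$seqid, source, "exon", ex$start, ex$end, ".", ex$strand, ".",
          paste0("Parent=", t$transcript_id),
          sep = "\t"
        ))
        if (nrow(cds) > 0) {
          if (t$strand == "-") cds <- cds[rev(seq_len(nrow(cds))), ]
          len <- cds$end - cds$start + 1L
          before <- cumsum(c(0L, len[-length(len)]))
          phase <- (3L - (before %% 3L)) %% 3L
          lines <- c(lines, paste(
            cds$seqid, source, "CDS", cds$start, cds$end, ".", cds$strand,
            phase, paste0("Parent=", t$transcript_id),
            sep = "\t"
          ))
        }
      }
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}
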