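#' Read tabular BLAST output (outfmt 6 plus subject taxid)
#'
#' Reads the standard 12-column tab-separated BLAST layout (qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore) with the subject taxid (`staxids`) appended as column 13, the
#' format produced by
#' `blastn -outfmt "6 std staxids"`. Multi-taxid cells (semicolon-joined)
#' keep the first taxid with a warning.
#'
#' @param path Path to the tab-separated hit table.
#' @return A tibble with one row per hit: `query_id`, `subject_id`, `pident`,
#'   `align_length`, `mismatches`, `gap_opens`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`, `subject_taxid`. An empty file yields a
#'   zero-row tibble with these columns.
#' @seealso [aggregate_hit_scores()]
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BLAST table not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- tibble(
    query_id = character(), subject_id = character(),
    pident = double(), align_length = integer(), mismatches = integer(),
    gap_opens = integer(), qstart = integer(), qend = integer(),
    sstart = integer(), send = integer(),
    evalue = double(), bitscore = double(), subject_taxid = integer()
  )
  if (length(lines) == 0) {
    return(empty)
  }
  fields <- stringr::str_split(lines, stringr::fixed("\t"))
  nf <- lengths(fields)
  if (any(nf < 13)) {
    bad <- which(nf < 13)[1]
    abort(paste0(
      "BLAST table '", path, "' line ", bad, ": expected >= 13 tab-separated ",
      "columns (12-column outfmt 6 + staxids), found ", nf[bad]
    ))
  }
  m <- do.call(rbind, lapply(fields, function(f) f[1:13]))

  num <- function(col, what, parser) {
    x <- suppressWarnings(parser(m[, col]))
    if (anyNA(x)) {
      bad <- which(is.na(x))[1]
      abort(paste0(
        "BLAST table '", path, "' line ", bad, ": cannot parse ", what,
        " from '", m[bad, col], "'"
      ))
    }
    x
  }
  taxid_raw <- m[, 13]
  multi <- grepl(";", taxid_raw, fixed = TRUE)
  if (any(multi)) {
    warn(paste0(
      sum(multi), " hit(s) carry multiple subject taxids; keeping the first"
    ))
    taxid_raw[multi] <- sub(";.*$", "", taxid_raw[multi])
  }
  m[, 13] <- taxid_raw

  out <- tibble(
    query_id = m[, 1],
    subject_id = m[, 2],
    pident = num(3, "percent identity", as.numeric),
    align_length = num(4, "alignment length", function(x) as.integer(as.numeric(x))),
    mismatches = num(5, "mismatch count", function(x) as.integer(as.numeric(x))),
    gap_opens = num(6, "gap open count", function(x) as.integer(as.numeric(x))),
    qstart = num(7, "query start", function(x) as.integer(as.numeric(x))),
    qend = num(8, "query end", function(x) as.integer(as.numeric(x))),
    sstart = num(9, "subject start", function(x) as.integer(as.numeric(x))),
    send = num(10, "subject end", function(x) as.integer(as.numeric(x))),
    evalue = num(11, "e-value", as.numeric),
    bitscore = num(12, "bitscore", as.numeric),
    subject_taxid = num(13, "subject taxid", function(x) as.integer(as.numeric(x)))
  )
  if (any(out$evalue < 0) || any(out$bitscore < 0)) {
    abort(paste0("BLAST table '", path, "': negative e-value or bitscore"))
  }
  if (any(out$subject_taxid <= 0)) {
    abort(paste0("BLAST table '", path, "': non-positive subject taxid"))
  }
  out
}

#' Write a hit table in tabular BLAST (outfmt 6 + staxids) layout
#'
#' @param hits Tibble as returned by [read_blast_tab()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_blast_tab <- function(hits, path) {
  fmt_e <- ifelse(
    hits$evalue != 0 & hits$evalue < 1e-4,
    sprintf("%.2e", hits$evalue),
    sub("\\.?0+$", "", sprintf("%.6f", hits$evalue))
  )
  lines <- sprintf(
    "%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f\t%d",
    hits$query_id, hits$subject_id, hits$pident, hits$align_length,
    hits$mismatches, hits$gap_opens, hits$qstart, hits$qend, hits$sstart,
    hits$send, fmt_e, hits$bitscore, hits$subject_taxid
  )
  readr::write_lines(lines, path)
  invisible(path)
}
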