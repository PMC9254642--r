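# Small in-code builders for hand-crafted gene models.

# One transcript's annotation rows from exon (and optional CDS) coordinate
# pairs given as list(c(start, end), ...).
mk_tx <- function(tx_id, gene_id, exons, cds = list(), strand = "+",
                  seqid = "chr1", gene_name = NA_character_, score = 1) {
  ex <- do.call(rbind, exons)
  rows <- tibble::tibble(
    seqid = seqid, feature = "exon",
    start = as.integer(ex[, 1]), end = as.integer(ex[, 2]),
    strand = strand, gene_id = gene_id, transcript_id = tx_id,
    gene_name = gene_name, score = score
  )
  if (length(cds) > 0) {
    cd <- do.call(rbind, cds)
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      seqid = seqid, feature = "cds",
      start = as.integer(cd[, 1]), end = as.integer(cd[, 2]),
      strand = strand, gene_id = gene_id, transcript_id = tx_id,
      gene_name = gene_name, score = score
    ))
  }
  rows
}

mk_genome <- function(sequence, id = "chr1") {
  tibble::tibble(id = id, length = nchar(sequence), sequence = sequence)
}

# A genome string of `n` A's with dinucleotides planted at given positions.
mk_seq <- function(n, plant = list()) {
  s <- strrep("A", n)
  for (p in plant) {
    substr(s, p[[1]], p[[1]] + 1L) <- p[[2]]
  }
  s
}

rodentia_lineages <- function() {
  tibble::tibble(
    taxid = rep(c(10090L, 10036L, 9606L), each = 2),
    depth = rep(1:2, 3),
    rank = rep(c("order", "species"), 3),
    name = c(
      "Rodentia", "Mus musculus",
      "Rodentia", "Mesocricetus auratus",
      "Primates", "Homo sapiens"
    )
  )
}

empty_hits <- function() {
  tibble::tibble(
    query_id = character(), subject_id = character(), pident = double(),
    align_length = integer(), mismatches = integer(), gap_opens = integer(),
    qstart = integer(), qend = integer(), sstart = integer(),
    send = integer(), evalue = double(), bitscore = double(),
    subject_taxid = integer()
  )
}

mk_hit <- function(query_id, taxid, bitscore, evalue) {
  tibble::tibble(
    query_id = query_id, subject_id = "acc0000001", pident = 99.0,
    align_length = 500L, mismatches = 1L, gap_opens = 0L,
    qstart = 1L, qend = 500L, sstart = 1L, send = 500L,
    evalue = evalue, bitscore = bitscore, subject_taxid = as.integer(taxid)
  )
}
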