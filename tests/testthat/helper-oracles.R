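# Independent brute-force oracles, deliberately written with base R only so
# they share no code path with the implementation they check.

# Per-contig re-derivation of the screening verdict: filter hits by strict
# e-value, sum bitscores per taxid with tapply, take the argmax (smallest
# taxid on ties) and apply the retained-clade/no-hit rule.
oracle_screen_verdicts <- function(contigs, manifest, hits, lineages,
                                   evalue_max = 1e-25,
                                   retain_rank = "order",
                                   retain_name = "Rodentia") {
  lab <- setNames(manifest$label, manifest$contig_id)
  clade <- lineages$taxid[lineages$rank == retain_rank & lineages$name == retain_name]
  vapply(contigs$id, function(id) {
    l <- lab[[id]]
    if (l %in% c("target_species", "unclassified")) {
      return("retain")
    }
    if (l == "bacteria") {
      return("drop")
    }
    h <- hits[hits$query_id == id & hits$evalue < evalue_max, , drop = FALSE]
    if (nrow(h) == 0) {
      return("retain")
    }
    sums <- tapply(h$bitscore, h$subject_taxid, sum)
    taxids <- as.integer(names(sums))
    best <- taxids[order(-as.numeric(sums), taxids)][1]
    if (best %in% clade) "retain" else "drop"
  }, character(1), USE.NAMES = FALSE)
}

# Quadratic-scan N50/L50: for each rank, recompute the partial sum from
# scratch and stop at the first rank reaching half the total.
oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  total <- sum(s)
  for (i in seq_along(s)) {
    if (sum(s[seq_len(i)]) >= total / 2) {
      return(list(n50 = s[i], l50 = i))
    }
  }
}

# Exhaustive nearest-feature scan for the 3' downstream gap of one
# transcript, given raw exon rows (base R only).
oracle_downstream_gap <- function(ann, tx_id, contig_length) {
  ex <- ann[ann$feature == "exon", , drop = FALSE]
  mine <- ex[ex$transcript_id == tx_id, , drop = FALSE]
  strand <- mine$strand[1]
  seqid <- mine$seqid[1]
  gene <- mine$gene_id[1]
  tp <- if (strand == "+") max(mine$end) else min(mine$start)
  other <- ex[ex$seqid == seqid & ex$gene_id != gene, , drop = FALSE]
  spans <- do.call(rbind, lapply(
    split(other, other$gene_id, drop = TRUE),
    function(g) data.frame(start = min(g$start), end = max(g$end))
  ))
  if (is.null(spans)) spans <- data.frame(start = numeric(0), end = numeric(0))
  if (strand == "+") {
    cand <- spans$start[spans$start > tp]
    if (length(cand) > 0) {
      list(gap = min(cand) - tp - 1, bounded = FALSE)
    } else {
      list(gap = contig_length - tp, bounded = TRUE)
    }
  } else {
    cand <- spans$end[spans$end < tp]
    if (length(cand) > 0) {
      list(gap = tp - max(cand) - 1, bounded = FALSE)
    } else {
      list(gap = tp - 1, bounded = TRUE)
    }
  }
}

# Global postcondition sweep over a curated annotation: every rule's
# postcondition restated as a predicate, checked independently.
check_curation_postconditions <- function(ann, genome, min_exon_len = 15,
                                          splice_canon = "GT-AG") {
  tt <- transcript_table(ann)
  # one gene name per locus
  names_per_locus <- tapply(tt$gene_name, tt$gene_id, function(x) {
    length(unique(ifelse(is.na(x), "<NA>", x)))
  })
  expect_true(all(names_per_locus == 1), label = "one gene name per locus")
  # unique named loci
  gname <- tapply(tt$gene_name, tt$gene_id, function(x) x[1])
  expect_true(!anyDuplicated(gname[!is.na(gname)]), label = "unique named loci")
  # no cross-gene identical exon
  ex <- ann[ann$feature == "exon", , drop = FALSE]
  key <- paste(ex$seqid, ex$start, ex$end, ex$strand)
  expect_true(
    all(tapply(ex$gene_id, key, function(g) length(unique(g))) == 1),
    label = "no exon shared across genes"
  )
  # no short exon
  expect_true(
    all(ex$end - ex$start + 1 >= min_exon_len),
    label = "no exon below the length floor"
  )
  # all introns canonical (read in transcript orientation)
  seqs <- setNames(genome$sequence, genome$id)
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  for (id in unique(ex$transcript_id)) {
    e <- ex[ex$transcript_id == id, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2) next
    seq <- seqs[[e$seqid[1]]]
    for (i in seq_len(nrow(e) - 1)) {
      istart <- e$end[i] + 1
      iend <- e$start[i + 1] - 1
      d <- substr(seq, istart, istart + 1)
      a <- substr(seq, iend - 1, iend)
      pair <- if (e$strand[1] == "+") paste0(d, "-", a) else paste0(rc(a), "-", rc(d))
      expect_true(pair %in% splice_canon, label = paste("canonical intron in", id))
    }
  }
  # no identical-boundary isoform pair within a gene
  sig <- vapply(unique(ex$transcript_id), function(id) {
    e <- ex[ex$transcript_id == id, , drop = FALSE]
    e <- e[order(e$start), ]
    paste(e$start, e$end, collapse = ";")
  }, character(1))
  gene_of <- setNames(tt$gene_id, tt$transcript_id)
  combo <- paste(gene_of[names(sig)], sig)
  expect_true(!anyDuplicated(combo), label = "no identical-boundary isoforms")
  invisible(TRUE)
}
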