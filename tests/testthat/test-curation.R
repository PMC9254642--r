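test_that("gene-name resolution keeps the top-scoring transcript's name", {
  ann <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 200)), gene_name = "A", score = 50),
    mk_tx("t2", "g1", list(c(100, 250)), gene_name = "B", score = 40),
    mk_tx("t3", "g1", list(c(100, 300)), gene_name = "A", score = 30)
  )
  out <- resolve_locus_gene_names(ann)
  expect_setequal(unique(out$transcript_id), c("t1", "t3"))
  # single transcript untouched
  single <- mk_tx("t1", "g1", list(c(100, 200)), gene_name = "A", score = 5)
  expect_equal(nrow(resolve_locus_gene_names(single)), nrow(single))
  # tied top score: the name of the transcript occurring first in input wins
  tied <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 200)), gene_name = "A", score = 50),
    mk_tx("t2", "g1", list(c(100, 250)), gene_name = "B", score = 50)
  )
  out2 <- resolve_locus_gene_names(tied)
  expect_equal(unique(out2$gene_name), "A")
})

test_that("named-locus deduplication keeps the higher top score", {
  ann <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 200)), gene_name = "A", score = 60),
    mk_tx("t2", "g2", list(c(5000, 5200)), gene_name = "A", score = 55)
  )
  out <- dedupe_named_loci(ann)
  expect_equal(unique(out$gene_id), "g1")
  # all-unique names: unchanged
  uniq <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 200)), gene_name = "A", score = 60),
    mk_tx("t2", "g2", list(c(5000, 5200)), gene_name = "B", score = 55)
  )
  expect_equal(nrow(dedupe_named_loci(uniq)), nrow(uniq))
  # unnamed loci are never removed
  unnamed <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 200)), score = 60),
    mk_tx("t2", "g2", list(c(5000, 5200)), score = 55)
  )
  expect_equal(nrow(dedupe_named_loci(unnamed)), nrow(unnamed))
  # equal top scores: smaller leftmost coordinate wins, then smaller id
  tied <- dplyr::bind_rows(
    mk_tx("t1", "g2", list(c(100, 200)), gene_name = "A", score = 60),
    mk_tx("t2", "g1", list(c(5000, 5200)), gene_name = "A", score = 60)
  )
  expect_equal(unique(dedupe_named_loci(tied)$gene_id), "g2")
})

test_that("exons shared across genes are trimmed from every owner", {
  shared <- c(1000, 1119)
  ann <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 200), shared), cds = list(c(150, 200))),
    mk_tx("t2", "g2", list(shared, c(2000, 2200)), cds = list(c(2050, 2200)))
  )
  out <- strip_shared_exons(ann)
  ex <- out[out$feature == "exon", ]
  expect_false(any(ex$start == 1000))
  expect_equal(max(ex$end[ex$transcript_id == "t1"]), 200)
  expect_equal(min(ex$start[ex$transcript_id == "t2"]), 2000)
  lg <- attr(out, "curation_log")
  expect_equal(sum(lg$action == "trimmed_exon"), 1)
  # exon shared by isoforms of the SAME gene is untouched
  same_gene <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 200), shared)),
    mk_tx("t2", "g1", list(shared, c(2000, 2200)))
  )
  expect_equal(nrow(strip_shared_exons(same_gene)), nrow(same_gene))
  # a transcript losing its only exon is removed
  engulfed <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(shared)),
    mk_tx("t2", "g2", list(shared, c(2000, 2200)))
  )
  out2 <- strip_shared_exons(engulfed)
  expect_false("t1" %in% out2$transcript_id)
})

test_that("planted cross-gene shared exons are all trimmed, and only those", {
  for (seed in c(4, 14)) {
    fx <- simulate_annotation(seed, n_genes = 10, defects = list(shared_exon = 2))
    cr <- curate(fx$annotation, fx$genome)
    trims <- cr$report[cr$report$action == "trimmed_exon", ]
    expect_equal(nrow(trims), 2)
    expect_setequal(trims$entity_id, fx$ledger$entity_id[fx$ledger$rule == "strip_shared_exons"])
  }
})

test_that("short exons eliminate their transcript at a strict 15 bp boundary", {
  genome <- mk_genome(mk_seq(5000, list(
    list(201, "GT"), list(299, "AG"), # canonical intron 201..300
    list(415, "GT"), list(499, "AG") # canonical intron 415..500
  )))
  # 14 bp exon: eliminated
  ann14 <- mk_tx("t1", "g1", list(c(100, 200), c(301, 314)))
  out14 <- filter_structural(ann14, genome)
  expect_equal(nrow(out14), 0)
  # 15 bp exon: retained ("shorter than" is strict)
  ann15 <- mk_tx("t1", "g1", list(c(100, 200), c(301, 315)))
  out15 <- filter_structural(ann15, genome)
  expect_equal(sum(out15$feature == "exon"), 2)
})

test_that("splice consensus is read in transcript orientation", {
  # plus strand: GT..AG genomic is canonical
  gplus <- mk_genome(mk_seq(1000, list(list(201, "GT"), list(299, "AG"))))
  plus <- mk_tx("t1", "g1", list(c(100, 200), c(301, 400)))
  expect_equal(sum(filter_structural(plus, gplus)$feature == "exon"), 2)
  # minus strand: genomic CT..AC reads GT-AG in transcript orientation
  gminus <- mk_genome(mk_seq(1000, list(list(201, "CT"), list(299, "AC"))))
  minus <- mk_tx("t1", "g1", list(c(100, 200), c(301, 400)), strand = "-")
  expect_equal(sum(filter_structural(minus, gminus)$feature == "exon"), 2)
  # genomic AT..CC is noncanonical on either strand
  gbad <- mk_genome(mk_seq(1000, list(list(201, "AT"), list(299, "CC"))))
  expect_equal(nrow(filter_structural(minus, gbad)), 0)
  expect_equal(nrow(filter_structural(plus, gbad)), 0)
  # the minor consensi can be admitted explicitly
  ggc <- mk_genome(mk_seq(1000, list(list(201, "GC"), list(299, "AG"))))
  expect_equal(nrow(filter_structural(plus, ggc)), 0)
  expect_equal(
    sum(filter_structural(plus, ggc, splice_canon = c("GT-AG", "GC-AG"))$feature == "exon"),
    2
  )
})

test_that("exon coordinates beyond the contig end are an error", {
  genome <- mk_genome(mk_seq(300))
  ann <- mk_tx("t1", "g1", list(c(100, 400)))
  expect_error(filter_structural(ann, genome), "exceeds")
})

test_that("identical-boundary isoforms keep the longest CDS", {
  ann <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 400), c(500, 800)), cds = list(c(150, 400), c(500, 548))),
    mk_tx("t2", "g1", list(c(100, 400), c(500, 800)), cds = list(c(150, 359)))
  )
  out <- dedupe_identical_isoforms(ann)
  expect_equal(unique(out$transcript_id), "t1")
  # equal CDS length: lexicographically smallest id survives
  tie <- dplyr::bind_rows(
    mk_tx("tB", "g1", list(c(100, 400)), cds = list(c(150, 249))),
    mk_tx("tA", "g1", list(c(100, 400)), cds = list(c(200, 299)))
  )
  expect_equal(unique(dedupe_identical_isoforms(tie)$transcript_id), "tA")
  # one differing boundary: both kept
  diff <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 400)), cds = list(c(150, 249))),
    mk_tx("t2", "g1", list(c(100, 401)), cds = list(c(150, 249)))
  )
  expect_setequal(unique(dedupe_identical_isoforms(diff)$transcript_id), c("t1", "t2"))
})

test_that("a defect-free annotation passes curation unchanged", {
  fx <- simulate_annotation(6, n_genes = 8)
  cr <- curate(fx$annotation, fx$genome)
  expect_equal(nrow(cr$report), 0)
  expect_equal(as.data.frame(cr$annotation), as.data.frame(fx$annotation))
  g <- glance(cr)
  expect_equal(g$transcripts_in, g$transcripts_out)
})

test_that("one planted defect of each kind triggers exactly one action per rule", {
  fx <- simulate_annotation(8,
    n_genes = 12,
    defects = list(
      name_conflict = 1, dup_named_locus = 1, shared_exon = 1,
      short_exon = 1, noncanonical_intron = 1, identical_isoform = 1
    )
  )
  cr <- curate(fx$annotation, fx$genome)
  got <- cr$report[, c("rule", "entity_id", "action")]
  want <- fx$ledger[, c("rule", "entity_id", "action")]
  expect_equal(
    as.data.frame(dplyr::arrange(got, rule, entity_id)),
    as.data.frame(dplyr::arrange(want, rule, entity_id))
  )
})

test_that("curation is idempotent and its postconditions hold globally", {
  for (seed in c(1, 2, 3, 23, 31)) {
    fx <- simulate_annotation(seed,
      n_genes = 10,
      defects = list(name_conflict = 1, shared_exon = 1, noncanonical_intron = 1)
    )
    cr1 <- curate(fx$annotation, fx$genome)
    cr2 <- curate(cr1$annotation, fx$genome)
    expect_equal(as.data.frame(cr2$annotation), as.data.frame(cr1$annotation))
    expect_equal(nrow(cr2$report), 0)
    check_curation_postconditions(cr1$annotation, fx$genome)
  }
})

test_that("transcript counts are conserved across the pipeline", {
  fx <- simulate_annotation(12,
    n_genes = 12,
    defects = list(dup_named_locus = 1, short_exon = 1, identical_isoform = 1)
  )
  cr <- curate(fx$annotation, fx$genome)
  cnt <- cr$counts
  expect_equal(
    cnt$transcripts_in[1],
    dplyr::last(cnt$transcripts_out) + sum(cnt$transcripts_removed)
  )
})
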