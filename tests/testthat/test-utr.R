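test_that("downstream gaps follow the span convention on both strands", {
  genome <- tibble::tibble(id = "chr1", length = 10500L)
  ann <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 1000))),
    mk_tx("t2", "g2", list(c(4001, 5000))) # starts 3,001 positions after t1's end
  )
  gaps <- downstream_gaps(ann, genome)
  expect_equal(gaps$gap[gaps$transcript_id == "t1"], 3000L)
  expect_false(gaps$bounded[gaps$transcript_id == "t1"])
  # t2 has no downstream feature: bounded by the contig end
  expect_equal(gaps$gap[gaps$transcript_id == "t2"], 10500L - 5000L)
  expect_true(gaps$bounded[gaps$transcript_id == "t2"])
  # minus strand measures leftward from the transcript start
  annm <- dplyr::bind_rows(
    mk_tx("t1", "g1", list(c(100, 1000))),
    mk_tx("t2", "g2", list(c(4001, 5000)), strand = "-")
  )
  gm <- downstream_gaps(annm, genome)
  expect_equal(gm$gap[gm$transcript_id == "t2"], 3000L)
})

test_that("downstream gaps equal an exhaustive nearest-feature scan", {
  for (seed in c(3, 17)) {
    fx <- simulate_annotation(seed, n_genes = 20)
    gaps <- downstream_gaps(fx$annotation, fx$genome)
    for (i in seq_len(nrow(gaps))) {
      o <- oracle_downstream_gap(
        fx$annotation, gaps$transcript_id[i], fx$genome$length
      )
      expect_equal(gaps$gap[i], as.integer(o$gap))
      expect_equal(gaps$bounded[i], o$bounded)
    }
  }
})

test_that("the 3,000 bp gate is inclusive and 2,999 is not extended", {
  fx <- simulate_annotation(10, n_genes = 3, gaps = c(2999, 3000), strands = "+", tail_room = 4000)
  ext <- extend_annotation(fx$annotation, fx$genome)
  log <- tidy(ext)
  ids <- fx$layout$gene_id
  expect_equal(log$extension_applied[log$gene_id == ids[1]], 0L)
  expect_equal(log$extension_applied[log$gene_id == ids[2]], 1000L)
})

test_that("extension clamps at the contig end instead of skipping", {
  genome <- tibble::tibble(id = "chr1", length = 1600L)
  ann <- mk_tx("t1", "g1", list(c(100, 1000)))
  ext <- extend_annotation(ann, genome)
  log <- tidy(ext)
  expect_true(log$bounded)
  expect_equal(log$extension_applied, 600L)
  expect_true(log$clamped)
  expect_equal(max(ext$annotation$end), 1600L)
})

test_that("extension changes only the 3'-terminal exon and never the CDS", {
  fx <- simulate_annotation(19, n_genes = 10)
  ext <- extend_annotation(fx$annotation, fx$genome)
  before <- fx$annotation
  after <- ext$annotation
  expect_equal(
    as.data.frame(before[before$feature == "cds", ]),
    as.data.frame(after[after$feature == "cds", ])
  )
  expect_equal(sum(after$feature == "exon"), sum(before$feature == "exon"))
  expect_equal(after$strand, before$strand)
  log <- tidy(ext)
  for (id in unique(before$transcript_id)) {
    b <- before[before$feature == "exon" & before$transcript_id == id, ]
    a <- after[after$feature == "exon" & after$transcript_id == id, ]
    b <- b[order(b$start), ]
    a <- a[order(a$start), ]
    applied <- log$extension_applied[log$transcript_id == id]
    if (b$strand[1] == "+") {
      expect_equal(a$start, b$start)
      expect_equal(a$end, b$end + c(rep(0L, nrow(b) - 1), applied))
    } else {
      expect_equal(a$end, b$end)
      expect_equal(a$start, b$start - c(applied, rep(0L, nrow(b) - 1)))
    }
  }
})

test_that("no extension creates an overlap: the realized gap stays positive", {
  # tandem pair at gap 3,500: both extend, realized gap shrinks to 2,500
  fx <- simulate_annotation(22, n_genes = 2, gaps = 3500, strands = "+", tail_room = 4000)
  ext <- extend_annotation(fx$annotation, fx$genome)
  expect_true(all(tidy(ext)$extension_applied == 1000L))
  post <- downstream_gaps(ext$annotation, fx$genome)
  first <- fx$layout$gene_id[1]
  expect_equal(post$gap[post$gene_id == first], 2500L)
  # generally: each extension leaves >= min_gap - extension to every
  # PRE-extension feature; a convergent neighbour may itself extend, so the
  # mutual post-extension gap is still >= min_gap - 2*extension, and exons of
  # different genes never overlap
  fx2 <- simulate_annotation(24, n_genes = 15)
  ext2 <- extend_annotation(fx2$annotation, fx2$genome)
  log2 <- tidy(ext2)
  gated <- log2[log2$extended & !log2$bounded, ]
  expect_true(all(gated$gap - gated$extension_applied >= 2000L))
  post2 <- downstream_gaps(ext2$annotation, fx2$genome)
  expect_true(all(post2$gap[post2$transcript_id %in% gated$transcript_id] >= 1000L))
  ex <- ext2$annotation[ext2$annotation$feature == "exon", ]
  for (i in seq_len(nrow(ex) - 1)) {
    others <- ex[ex$gene_id != ex$gene_id[i], ]
    expect_false(any(others$start <= ex$end[i] & others$end >= ex$start[i]))
  }
})

test_that("read-assignment deltas match hand computation", {
  identical_tables <- tibble::tibble(gene_id = c("g1", "g2"), count = c(5, 7))
  d0 <- quantify_extension_effect(identical_tables, identical_tables)
  expect_equal(d0$percent_total_increase, 0)
  expect_equal(d0$newly_detected_genes, 0L)
  expect_equal(d0$genes_gaining_ge_threshold, 0L)

  before <- tibble::tibble(gene_id = c("g1", "g2"), count = c(100, 0))
  after <- tibble::tibble(gene_id = c("g1", "g2"), count = c(125, 10))
  d <- quantify_extension_effect(before, after)
  expect_equal(d$percent_total_increase, 35)
  expect_equal(d$newly_detected_genes, 1L)
  expect_equal(d$genes_gaining_ge_threshold, 1L)

  # an exact 20% gain counts ("at least 20%")
  d20 <- quantify_extension_effect(
    tibble::tibble(gene_id = "g1", count = 10),
    tibble::tibble(gene_id = "g1", count = 12)
  )
  expect_equal(d20$genes_gaining_ge_threshold, 1L)

  # a gene absent from one table counts as zero there
  dmiss <- quantify_extension_effect(
    tibble::tibble(gene_id = "g1", count = 10),
    tibble::tibble(gene_id = c("g1", "g2"), count = c(10, 3))
  )
  expect_equal(dmiss$newly_detected_genes, 1L)

  expect_error(
    quantify_extension_effect(
      tibble::tibble(gene_id = "g1", count = 0),
      tibble::tibble(gene_id = "g1", count = 5)
    ),
    "undefined"
  )
})
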