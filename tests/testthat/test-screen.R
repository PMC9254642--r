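test_that("bitscores are summed per taxid over passing hits only", {
  hits <- dplyr::bind_rows(
    mk_hit("c1", 10090, 100, 1e-30),
    mk_hit("c1", 10090, 50, 1e-40),
    mk_hit("c1", 9606, 120, 1e-26)
  )
  agg <- aggregate_hit_scores(hits)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$score[agg$taxid == 10090], 150)
  expect_equal(agg$score[agg$taxid == 9606], 120)
  # no hits at all
  expect_equal(nrow(aggregate_hit_scores(empty_hits())), 0)
})

test_that("the e-value cutoff is a strict 'below'", {
  at_threshold <- mk_hit("c1", 10090, 100, 1e-25)
  expect_equal(nrow(aggregate_hit_scores(at_threshold)), 0)
  above <- mk_hit("c1", 10090, 100, 1e-20)
  expect_equal(nrow(aggregate_hit_scores(above)), 0)
  below <- mk_hit("c1", 10090, 100, 1e-26)
  expect_equal(nrow(aggregate_hit_scores(below)), 1)
})

test_that("taxon assignment is the argmax with smallest-taxid tie-break", {
  expect_equal(assign_contig_taxon(tibble::tibble(taxid = integer(), score = double())), NA_integer_)
  expect_equal(
    assign_contig_taxon(tibble::tibble(taxid = c(10090L, 9606L), score = c(150, 120))),
    10090L
  )
  expect_equal(
    assign_contig_taxon(tibble::tibble(taxid = c(10090L, 9606L), score = c(100, 100))),
    9606L
  )
})

test_that("retention follows the retained-clade / no-passing-hit rule", {
  lin <- rodentia_lineages()
  expect_equal(
    decide_retention(10090L, lin),
    list(verdict = "retain", reason = "adjudicated_lineage_retain")
  )
  expect_equal(
    decide_retention(NA_integer_, lin),
    list(verdict = "retain", reason = "adjudicated_no_hits_retain")
  )
  expect_equal(
    decide_retention(9606L, lin),
    list(verdict = "drop", reason = "adjudicated_drop")
  )
  expect_error(decide_retention(12345L, lin), "absent")
})

test_that("screening accounts for every contig and validates its inputs", {
  fx <- simulate_assembly(21,
    n_target = 15, n_bacteria = 2, n_flagged = 8,
    n_unclassified = 2, n_flagged_retain = 5
  )
  res <- screen_assembly(fx$contigs, fx$manifest, fx$hits, fx$lineages)
  d <- tidy(res)
  expect_equal(nrow(d), nrow(fx$contigs))
  expect_equal(sum(d$verdict == "retain") + sum(d$verdict == "drop"), nrow(fx$contigs))
  expect_equal(res$contigs$id, fx$contigs$id[fx$contigs$id %in% d$contig_id[d$verdict == "retain"]])
  # empty assembly degenerates cleanly
  empty <- screen_assembly(
    tibble::tibble(id = character(), length = integer()),
    tibble::tibble(contig_id = character(), label = character()),
    empty_hits(), fx$lineages
  )
  expect_equal(nrow(empty$contigs), 0)
  expect_equal(nrow(tidy(empty)), 0)
  # contract violations
  expect_error(
    screen_assembly(fx$contigs, fx$manifest[-1, ], fx$hits, fx$lineages),
    "missing from the manifest"
  )
  bad_manifest <- fx$manifest
  bad_manifest$label[1] <- "viral"
  expect_error(
    screen_assembly(fx$contigs, bad_manifest, fx$hits, fx$lineages),
    "outside the policy"
  )
})

test_that("screening equals the per-contig brute-force composition on seeded fixtures", {
  for (seed in 1:20) {
    fx <- simulate_assembly(seed,
      n_target = sample(5:20, 1), n_bacteria = sample(0:3, 1),
      n_flagged = sample(5:25, 1), n_unclassified = sample(0:3, 1),
      n_flagged_retain = 3
    )
    res <- screen_assembly(fx$contigs, fx$manifest, fx$hits, fx$lineages)
    oracle <- oracle_screen_verdicts(fx$contigs, fx$manifest, fx$hits, fx$lineages)
    expect_equal(tidy(res)$verdict, oracle)
  }
})

test_that("hit order never changes a verdict", {
  fx <- simulate_assembly(5, n_target = 5, n_bacteria = 1, n_flagged = 12, n_unclassified = 1, n_flagged_retain = 6)
  res1 <- screen_assembly(fx$contigs, fx$manifest, fx$hits, fx$lineages)
  shuffled <- fx$hits[rev(seq_len(nrow(fx$hits))), ]
  res2 <- screen_assembly(fx$contigs, fx$manifest, shuffled, fx$lineages)
  expect_equal(tidy(res1), tidy(res2))
})

test_that("tightening the e-value cutoff never flips a no-hit retention to drop", {
  fx <- simulate_assembly(9, n_target = 4, n_bacteria = 0, n_flagged = 20, n_unclassified = 0, n_flagged_retain = 10)
  base <- tidy(screen_assembly(fx$contigs, fx$manifest, fx$hits, fx$lineages))
  kept_no_hit <- base$contig_id[base$reason == "adjudicated_no_hits_retain"]
  for (emax in c(1e-30, 1e-50, 1e-100)) {
    tighter <- tidy(screen_assembly(
      fx$contigs, fx$manifest, fx$hits, fx$lineages,
      screen_policy(evalue_max = emax)
    ))
    expect_true(all(tighter$verdict[tighter$contig_id %in% kept_no_hit] == "retain"))
  }
})

test_that("any-hit mode retains on any passing rodent hit", {
  lin <- rodentia_lineages()
  contigs <- tibble::tibble(id = "c1", length = 1000L)
  manifest <- tibble::tibble(contig_id = "c1", label = "flagged")
  # human dominates the summed score, one weak rodent hit passes
  hits <- dplyr::bind_rows(
    mk_hit("c1", 9606, 500, 1e-60),
    mk_hit("c1", 10090, 80, 1e-30)
  )
  strict <- screen_assembly(contigs, manifest, hits, lin)
  expect_equal(tidy(strict)$verdict, "drop")
  lax <- screen_assembly(
    contigs, manifest, hits, lin,
    screen_policy(any_hit_mode = TRUE)
  )
  expect_equal(tidy(lax)$verdict, "retain")
})
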