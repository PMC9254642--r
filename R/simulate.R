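## Seeded fixture generators. Every generator returns, alongside the emitted
## tables, a ledger of planted truths that fully determines the expected
## output of the corresponding pipeline stage, so the screening, curation and
## UTR-extension code can be tested end to end without any external data.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic assembly with planted contaminants
#'
#' Emulates the inputs of a post-assembly contamination screen: a contig
#' set, a prior-classification manifest (as an external k-mer classifier
#' would produce), a BLAST hit table for the flagged contigs and a matching
#' lineage table. The BLAST rows are constructed so that exactly
#' `n_flagged_retain` of the flagged contigs satisfy the
#' retained-clade-or-no-passing-hit adjudication rule: some via rodent
#' top-scores, some via hits that all miss the e-value threshold, some with
#' no hits at all; the remainder adjudicate to drop via dominant primate
#' scores. The same seed always yields identical output.
#'
#' @param seed Integer seed driving all randomness.
#' @param n_target,n_bacteria,n_flagged,n_unclassified Contig counts per
#'   prior category. Defaults mirror a large rodent assembly screen:
#'   2,028 target-species, 3 bacteria, 74 flagged (human-classified),
#'   3 unclassified.
#' @param n_flagged_retain How many flagged contigs must adjudicate to
#'   retain (default 47).
#' @param length_range Contig length range in bp (default 1--50 kb).
#' @param sequences Also generate nucleotide sequences (default `FALSE`;
#'   lengths suffice for screening and statistics).
#' @return An `assembly_fixture`: list with `contigs`, `manifest`, `hits`,
#'   `lineages`, `ledger` (contig_id, category, expected_verdict,
#'   expected_reason) and `seed`.
#' @seealso [screen_assembly()], [write_assembly_fixture()]
#' @export
simulate_assembly <- function(seed,
                              n_target = 2028, n_bacteria = 3,
                              n_flagged = 74, n_unclassified = 3,
                              n_flagged_retain = min(47, n_flagged),
                              length_range = c(1000, 50000),
                              sequences = FALSE) {
  stopifnot(
    n_target >= 0, n_bacteria >= 0, n_flagged >= 0, n_unclassified >= 0,
    n_flagged_retain >= 0, n_flagged_retain <= n_flagged
  )
  with_seed(seed, {
    n <- n_target + n_bacteria + n_flagged + n_unclassified
    ids <- sprintf("ctg%05d", seq_len(n))
    category <- sample(rep(
      c("target_species", "bacteria", "flagged", "unclassified"),
      c(n_target, n_bacteria, n_flagged, n_unclassified)
    ))
    lengths <- sample(length_range[1]:length_range[2], n, replace = TRUE)
    contigs <- tibble(id = ids, length = as.integer(lengths))
    if (sequences) {
      contigs$sequence <- vapply(lengths, random_dna, character(1))
    }
    manifest <- tibble(contig_id = ids, label = category)

    rodent_taxids <- c(10090L, 10036L)
    primate_taxids <- c(9606L, 9598L)
    lineages <- bind_rows(
      lineage_rows(10090L, "Eukaryota", "Mammalia", "Rodentia", "Mus musculus"),
      lineage_rows(10036L, "Eukaryota", "Mammalia", "Rodentia", "Mesocricetus auratus"),
      lineage_rows(9606L, "Eukaryota", "Mammalia", "Primates", "Homo sapiens"),
      lineage_rows(9598L, "Eukaryota", "Mammalia", "Primates", "Pan troglodytes"),
      lineage_rows(562L, "Bacteria", "Gammaproteobacteria", "Enterobacterales", "Escherichia coli")
    )

    flagged_ids <- ids[category == "flagged"]
    # retainers split between rodent-assigned and no-passing-hit contigs;
    # of the latter, half carry sub-threshold hits and half none at all
    n_no_hit <- floor(n_flagged_retain / 3)
    kinds <- rep("drop_primate", n_flagged)
    if (n_flagged_retain > 0) {
      kinds[seq_len(n_flagged_retain)] <-
        c(
          rep("retain_rodent", n_flagged_retain - n_no_hit),
          rep("retain_no_hit", n_no_hit)
        )
    }
    kinds <- sample(kinds)

    hit_rows <- list()
    mk_hits <- function(cid, taxids, bits, evalues) {
      k <- length(taxids)
      tibble(
        query_id = cid,
        subject_id = sprintf("acc%07d", sample.int(1e7, k)),
        pident = round(runif(k, 85, 100), 3),
        align_length = sample(100:5000, k, replace = TRUE),
        mismatches = sample(0:50, k, replace = TRUE),
        gap_opens = sample(0:10, k, replace = TRUE),
        qstart = sample(1:500, k, replace = TRUE),
        qend = sample(501:5000, k, replace = TRUE),
        sstart = sample(1:500, k, replace = TRUE),
        send = sample(501:5000, k, replace = TRUE),
        evalue = evalues,
        bitscore = bits,
        subject_taxid = taxids
      )
    }
    pass_e <- function(k) 10^-runif(k, 26, 180)
    for (i in seq_along(flagged_ids)) {
      cid <- flagged_ids[i]
      kind <- kinds[i]
      if (kind == "retain_rodent") {
        k <- sample(2:4, 1)
        tax <- sample(rodent_taxids, k, replace = TRUE)
        rows <- mk_hits(cid, c(tax, sample(primate_taxids, 1)),
          bits = c(round(runif(k, 200, 500), 1), round(runif(1, 50, 150), 1)),
          evalues = pass_e(k + 1)
        )
      } else if (kind == "retain_no_hit") {
        if (i %% 2 == 0) next # no BLAST rows at all
        rows <- mk_hits(cid, sample(primate_taxids, 2, replace = TRUE),
          bits = round(runif(2, 50, 300), 1),
          evalues = 10^-runif(2, 5, 24) # all miss the strict 1e-25 cutoff
        )
      } else {
        k <- sample(2:3, 1)
        rows <- mk_hits(cid, c(sample(primate_taxids, k, replace = TRUE), 10090L),
          bits = c(round(runif(k, 300, 600), 1), round(runif(1, 30, 100), 1)),
          evalues = pass_e(k + 1)
        )
      }
      hit_rows[[length(hit_rows) + 1]] <- rows
    }
    hits <- if (length(hit_rows) > 0) {
      bind_rows(hit_rows)
    } else {
      tibble(
        query_id = character(), subject_id = character(), pident = double(),
        align_length = integer(), mismatches = integer(), gap_opens = integer(),
        qstart = integer(), qend = integer(), sstart = integer(),
        send = integer(), evalue = double(), bitscore = double(),
        subject_taxid = integer()
      )
    }

    expected <- tibble(
      contig_id = ids, category = category,
      expected_verdict = dplyr::case_match(
        category,
        c("target_species", "unclassified") ~ "retain",
        "bacteria" ~ "drop",
        "flagged" ~ NA_character_
      ),
      expected_reason = dplyr::case_match(
        category,
        c("target_species", "unclassified") ~ "prior_retain",
        "bacteria" ~ "prior_drop",
        "flagged" ~ NA_character_
      )
    )
    flag_kind <- setNames(kinds, flagged_ids)
    fl <- expected$category == "flagged"
    expected$expected_verdict[fl] <- if_else(
      flag_kind[expected$contig_id[fl]] == "drop_primate", "drop", "retain"
    )
    expected$expected_reason[fl] <- dplyr::case_match(
      unname(flag_kind[expected$contig_id[fl]]),
      "retain_rodent" ~ "adjudicated_lineage_retain",
      "retain_no_hit" ~ "adjudicated_no_hits_retain",
      "drop_primate" ~ "adjudicated_drop"
    )

    structure(
      list(
        contigs = contigs, manifest = manifest, hits = hits,
        lineages = lineages, ledger = expected, seed = seed
      ),
      class = "assembly_fixture"
    )
  })
}

lineage_rows <- function(taxid, superkingdom, class, order, species) {
  tibble(
    taxid = taxid, depth = 1:4,
    rank = c("superkingdom", "class", "order", "species"),
    name = c(superkingdom, class, order, species)
  )
}

#' Write an assembly fixture to disk
#'
#' Emits `manifest.tsv`, `blast.tsv` (outfmt 6 + staxids), `lineage.tsv`,
#' `ledger.tsv` and, when the fixture carries sequences, `assembly.fa`.
#' Output is byte-identical for identical fixtures.
#'
#' @param fx An `assembly_fixture` from [simulate_assembly()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assembly_fixture <- function(fx, dir) {
  stopifnot(inherits(fx, "assembly_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(fx$manifest, file.path(dir, "manifest.tsv"))
  write_blast_tab(fx$hits, file.path(dir, "blast.tsv"))
  write_lineage_table(fx$lineages, file.path(dir, "lineage.tsv"))
  readr::write_tsv(fx$ledger, file.path(dir, "ledger.tsv"))
  if ("sequence" %in% names(fx$contigs)) {
    write_fasta(fx$contigs, file.path(dir, "assembly.fa"))
  }
  invisible(dir)
}

#' Generate a synthetic genome and gene annotation with planted defects
#'
#' Lays out protein-coding gene models left to right along one synthetic
#' contig, with canonical (GT--AG, strand-aware) splice sites written into
#' the sequence, then plants the requested annotation defects — each on its
#' own gene(s) so defects never interact:
#'
#' * `name_conflict`: an extra lower-scoring transcript with a different
#'   gene name (removed by [resolve_locus_gene_names()]);
#' * `dup_named_locus`: a second locus reusing an earlier locus's gene name
#'   at a lower top score (removed by [dedupe_named_loci()]);
#' * `shared_exon`: an identical non-coding exon inserted into transcripts
#'   of two adjacent same-strand genes (trimmed by [strip_shared_exons()]);
#' * `short_exon`: an extra 14 bp terminal exon (transcript removed by
#'   [filter_structural()]);
#' * `noncanonical_intron`: a corrupted donor site (transcript removed by
#'   [filter_structural()]);
#' * `identical_isoform`: a duplicate-boundary transcript with a shorter
#'   CDS (removed by [dedupe_identical_isoforms()]).
#'
#' @param seed Integer seed.
#' @param n_genes Number of base gene models (default 12).
#' @param defects Named list of planted defect counts; unnamed kinds
#'   default to zero. Kinds needing two genes (`dup_named_locus`,
#'   `shared_exon`) consume two each; the total demand must not exceed
#'   `n_genes`.
#' @param gaps Optional integer vector (length `n_genes - 1`) of exact
#'   inter-gene span gaps in bp; defaults to draws from `gap_range`.
#' @param gap_range Range inter-gene gaps are drawn from when `gaps` is
#'   `NULL` (default 1,500--6,000 bp, straddling the 3,000 bp extension
#'   gate on both sides).
#' @param strands Strand per gene (`"+"`/`"-"`, recycled), or `NULL` for
#'   random strands.
#' @param contig_id Name of the synthetic contig.
#' @param head_room,tail_room Flanking bp before the first and after the
#'   last gene (defaults 2,000 and 5,000).
#' @return An `annotation_fixture`: list with `genome` (one-contig tibble
#'   with sequence), `annotation`, `ledger` (defect, rule, entity_id,
#'   action), `layout` (per-gene spans and planted gaps), `gaps` and
#'   `seed`.
#' @seealso [curate()], [extend_annotation()]
#' @export
simulate_annotation <- function(seed, n_genes = 12,
                                defects = list(),
                                gaps = NULL,
                                gap_range = c(1500, 6000),
                                strands = NULL,
                                contig_id = "ctgA",
                                head_room = 2000, tail_room = 5000) {
  kinds <- c(
    "name_conflict", "dup_named_locus", "shared_exon", "short_exon",
    "noncanonical_intron", "identical_isoform"
  )
  unknown <- setdiff(names(defects), kinds)
  if (length(unknown) > 0) {
    abort(paste0("Unknown defect kind(s): ", paste(unknown, collapse = ", ")))
  }
  spec <- setNames(rep(0L, length(kinds)), kinds)
  spec[names(defects)] <- as.integer(unlist(defects))
  demand <- sum(spec * c(1L, 2L, 2L, 1L, 1L, 1L)[match(names(spec), kinds)])
  if (demand > n_genes) {
    abort(paste0(
      "Defect spec needs ", demand, " genes but n_genes = ", n_genes
    ))
  }

  with_seed(seed, {
    if (is.null(gaps)) {
      gaps <- if (n_genes > 1) {
        sample(gap_range[1]:gap_range[2], n_genes - 1, replace = TRUE)
      } else {
        integer(0)
      }
    }
    stopifnot(length(gaps) == max(n_genes - 1, 0))
    strand_vec <- if (is.null(strands)) {
      sample(c("+", "-"), n_genes, replace = TRUE)
    } else {
      rep(strands, length.out = n_genes)
    }

    # assign defect instances to distinct genes, front to back
    assign <- rep("clean", n_genes)
    cursor <- 1
    take <- function(k) {
      idx <- cursor:(cursor + k - 1)
      cursor <<- cursor + k
      idx
    }
    defect_genes <- list()
    for (kind in kinds) {
      for (r in seq_len(spec[[kind]])) {
        need <- if (kind %in% c("dup_named_locus", "shared_exon")) 2L else 1L
        idx <- take(need)
        assign[idx] <- kind
        defect_genes[[length(defect_genes) + 1]] <- list(kind = kind, genes = idx)
      }
    }
    # shared exons require a same-strand adjacent pair
    for (d in defect_genes) {
      if (d$kind == "shared_exon") strand_vec[d$genes] <- "+"
    }

    # --- base gene models -------------------------------------------------
    genes <- list()
    pos <- head_room + 1L
    for (i in seq_len(n_genes)) {
      wide <- assign[i] == "identical_isoform"
      n_ex <- sample(2:4, 1)
      ex_len <- sample(if (wide) 150:300 else 80:300, n_ex, replace = TRUE)
      in_len <- sample(200:600, max(n_ex - 1, 0), replace = TRUE)
      starts <- integer(n_ex)
      ends <- integer(n_ex)
      p <- pos
      for (e in seq_len(n_ex)) {
        starts[e] <- p
        ends[e] <- p + ex_len[e] - 1L
        p <- ends[e] + 1L + if (e < n_ex) in_len[e] else 0L
      }
      u5 <- sample(30:60, 1)
      u3 <- sample(30:60, 1)
      trims <- if (strand_vec[i] == "+") c(u5, u3) else c(u3, u5)
      cds_start <- starts
      cds_end <- ends
      cds_start[1] <- starts[1] + trims[1]
      cds_end[n_ex] <- ends[n_ex] - trims[2]
      genes[[i]] <- list(
        gene_id = sprintf("g%03d", i),
        gene_name = sprintf("GENE%03d", i),
        strand = strand_vec[i],
        score = round(runif(1, 10, 100), 2),
        transcripts = list(t1 = list(
          id = sprintf("g%03d.t1", i),
          exon_start = starts, exon_end = ends,
          cds_start = cds_start, cds_end = cds_end
        ))
      )
      next_gap <- if (i < n_genes) gaps[i] else tail_room
      pos <- ends[n_ex] + next_gap + 1L
    }

    # --- plant defects ----------------------------------------------------
    ledger <- list()
    corrupt_introns <- list() # (pos, strand) donors to overwrite
    for (d in defect_genes) {
      i <- d$genes[1]
      g <- genes[[i]]
      t1 <- g$transcripts$t1
      n_ex <- length(t1$exon_start)
      if (d$kind == "name_conflict") {
        t2 <- t1
        t2$id <- sprintf("g%03d.t2", i)
        t2$exon_end[n_ex] <- t2$exon_end[n_ex] - 17L
        t2$cds_end[n_ex] <- min(t2$cds_end[n_ex], t2$exon_end[n_ex] - 5L)
        genes[[i]]$transcripts$t2 <- t2
        genes[[i]]$alt_name_tx <- t2$id
        ledger[[length(ledger) + 1]] <- tibble(
          defect = d$kind, rule = "resolve_gene_names",
          entity_id = t2$id, action = "removed_transcript"
        )
      } else if (d$kind == "dup_named_locus") {
        j <- d$genes[2]
        genes[[j]]$gene_name <- g$gene_name
        genes[[j]]$score <- max(g$score - 1, 1)
        ledger[[length(ledger) + 1]] <- tibble(
          defect = d$kind, rule = "dedupe_named_loci",
          entity_id = genes[[j]]$gene_id, action = "removed_locus"
        )
      } else if (d$kind == "shared_exon") {
        j <- d$genes[2]
        a_end <- max(t1$exon_end)
        sh_start <- a_end + 301L
        sh_end <- sh_start + 119L
        for (gi in c(i, j)) {
          tx <- genes[[gi]]$transcripts$t1
          tx$exon_start <- sort(c(tx$exon_start, sh_start))
          tx$exon_end <- sort(c(tx$exon_end, sh_end))
          genes[[gi]]$transcripts$t1 <- tx
        }
        ledger[[length(ledger) + 1]] <- tibble(
          defect = d$kind, rule = "strip_shared_exons",
          entity_id = paste(contig_id, sh_start, sh_end, "+", sep = ":"),
          action = "trimmed_exon"
        )
      } else if (d$kind == "short_exon") {
        last_end <- max(t1$exon_end)
        t1$exon_start <- c(t1$exon_start, last_end + 201L)
        t1$exon_end <- c(t1$exon_end, last_end + 214L)
        genes[[i]]$transcripts$t1 <- t1
        ledger[[length(ledger) + 1]] <- tibble(
          defect = d$kind, rule = "filter_structural",
          entity_id = t1$id, action = "removed_transcript"
        )
      } else if (d$kind == "noncanonical_intron") {
        istart <- t1$exon_end[1] + 1L
        iend <- t1$exon_start[2] - 1L
        corrupt_introns[[length(corrupt_introns) + 1]] <-
          list(istart = istart, iend = iend, strand = g$strand)
        ledger[[length(ledger) + 1]] <- tibble(
          defect = d$kind, rule = "filter_structural",
          entity_id = t1$id, action = "removed_transcript"
        )
      } else if (d$kind == "identical_isoform") {
        t2 <- t1
        t2$id <- sprintf("g%03d.t2", i)
        # same boundaries, shorter CDS
        if (g$strand == "+") {
          t2$cds_start[1] <- t2$cds_start[1] + 50L
        } else {
          t2$cds_end[length(t2$cds_end)] <- t2$cds_end[length(t2$cds_end)] - 50L
        }
        genes[[i]]$transcripts$t2 <- t2
        ledger[[length(ledger) + 1]] <- tibble(
          defect = d$kind, rule = "dedupe_isoforms",
          entity_id = t2$id, action = "removed_transcript"
        )
      }
    }

    # --- emit annotation table -------------------------------------------
    rows <- list()
    for (i in seq_len(n_genes)) {
      g <- genes[[i]]
      for (tn in names(g$transcripts)) {
        tx <- g$transcripts[[tn]]
        gname <- if (!is.null(g$alt_name_tx) && tx$id == g$alt_name_tx) {
          paste0(g$gene_name, "alt")
        } else {
          g$gene_name
        }
        score <- if (tn == "t1") g$score else max(g$score - 5, 0.5)
        keep_cds <- tx$cds_start <= tx$cds_end
        rows[[length(rows) + 1]] <- bind_rows(
          tibble(
            seqid = contig_id, feature = "exon",
            start = tx$exon_start, end = tx$exon_end,
            strand = g$strand, gene_id = g$gene_id, transcript_id = tx$id,
            gene_name = gname, score = score
          ),
          tibble(
            seqid = contig_id, feature = "cds",
            start = tx$cds_start[keep_cds], end = tx$cds_end[keep_cds],
            strand = g$strand, gene_id = g$gene_id, transcript_id = tx$id,
            gene_name = gname, score = score
          )
        )
      }
    }
    ann <- normalise_annotation(bind_rows(rows))

    # --- genome sequence with planted splice sites -----------------------
    contig_len <- max(ann$end) + tail_room
    seq <- random_dna(contig_len)
    plant <- function(seq, at, dinuc) {
      substr(seq, at, at + 1L) <- dinuc
      seq
    }
    for (tx_id in unique(ann$transcript_id)) {
      tx <- ann[ann$transcript_id == tx_id & ann$feature == "exon", ]
      tx <- tx[order(tx$start), ]
      strand <- tx$strand[1]
      n_ex <- nrow(tx)
      if (n_ex < 2) next
      for (e in seq_len(n_ex - 1)) {
        istart <- tx$end[e] + 1L
        iend <- tx$start[e + 1] - 1L
        if (strand == "+") {
          seq <- plant(seq, istart, "GT")
          seq <- plant(seq, iend - 1L, "AG")
        } else {
          seq <- plant(seq, istart, "CT")
          seq <- plant(seq, iend - 1L, "AC")
        }
      }
    }
    for (ci in corrupt_introns) {
      if (ci$strand == "+") {
        seq <- plant(seq, ci$istart, "AA") # donor GT -> AA
      } else {
        seq <- plant(seq, ci$iend - 1L, "AA") # read as TT in transcript sense
      }
    }
    genome <- tibble(
      id = contig_id, length = contig_len, sequence = seq
    )

    layout <- gene_table(ann) %>%
      mutate(planted_gap = c(
        if (n() > 1) .data$start[-1] - .data$end[-n()] - 1L else integer(0),
        NA_integer_
      ))

    ledger_tbl <- if (length(ledger) > 0) {
      bind_rows(ledger)
    } else {
      tibble(
        defect = character(), rule = character(),
        entity_id = character(), action = character()
      )
    }

    structure(
      list(
        genome = genome, annotation = ann, ledger = ledger_tbl,
        layout = layout, gaps = gaps, seed = seed
      ),
      class = "annotation_fixture"
    )
  })
}

#' Write an annotation fixture to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, `ledger.tsv` and `layout.tsv`.
#'
#' @param fx An `annotation_fixture` from [simulate_annotation()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_annotation_fixture <- function(fx, dir) {
  stopifnot(inherits(fx, "annotation_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(fx$genome, file.path(dir, "genome.fa"))
  write_annotation(fx$annotation, file.path(dir, "annotation.gff3"))
  readr::write_tsv(fx$ledger, file.path(dir, "ledger.tsv"))
  readr::write_tsv(fx$layout, file.path(dir, "layout.tsv"))
  invisible(dir)
}

#' Generate a BUSCO short-summary text file
#'
#' Produces a parseable BUSCO `short_summary` in the labelled-count dialect.
#' By default the arithmetic identities hold (`complete = single +
#' duplicated`, `total = complete + fragmented + missing`); with
#' `inconsistent = TRUE` the stated complete count is off by one, violating
#' exactly the first identity.
#'
#' @param single,duplicated,fragmented,missing Category counts.
#' @param inconsistent Plant a single arithmetic inconsistency
#'   (default `FALSE`).
#' @param path Optional output path; when `NULL` the lines are returned
#'   only.
#' @return The summary lines, invisibly when written to `path`.
#' @export
simulate_busco <- function(single, duplicated, fragmented, missing,
                           inconsistent = FALSE, path = NULL) {
  complete <- single + duplicated + if (inconsistent) 1L else 0L
  total <- complete + fragmented + missing
  pct <- function(x) sprintf("%.1f%%", if (total > 0) 100 * x / total else 0)
  lines <- c(
    "# BUSCO was run in mode: genome",
    "",
    "\t***** Results: *****",
    "",
    sprintf(
      "\tC:%s[S:%s,D:%s],F:%s,M:%s,n:%d",
      pct(complete), pct(single), pct(duplicated), pct(fragmented),
      pct(missing), total
    ),
    sprintf("\t%d\tComplete BUSCOs (C)", complete),
    sprintf("\t%d\tComplete and single-copy BUSCOs (S)", single),
    sprintf("\t%d\tComplete and duplicated BUSCOs (D)", duplicated),
    sprintf("\t%d\tFragmented BUSCOs (F)", fragmented),
    sprintf("\t%d\tMissing BUSCOs (M)", missing),
    sprintf("\t%d\tTotal BUSCO groups searched", total)
  )
  if (!is.null(path)) {
    readr::write_lines(lines, path)
    return(invisible(lines))
  }
  lines
}
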