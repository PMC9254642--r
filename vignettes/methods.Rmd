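---
title: "Methods: contig screening, annotation curation and 3' UTR extension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contig screening, annotation curation and 3' UTR extension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gencurate)
library(dplyr)
```

gencurate implements the bespoke post-assembly computations that sit between
the heavyweight tools of a de novo genome project — assembler, polishers,
k-mer classifier, BLAST, gene predictor, read mappers — and the final
deliverables: a decontaminated contig set, a cleaned gene annotation, an
annotation with usable 3' UTRs, and the summary statistics that describe
them. The heavyweight tools themselves are out of scope; gencurate consumes
their standard outputs (FASTA, outfmt-6 BLAST tables, GFF3/GTF, BUSCO
short summaries) and applies the decision rules.

All coordinates are 1-based and inclusive throughout, the native convention
of GFF3/GTF, so an exon's length is `end - start + 1`. Annotations are held
as a tidy exon-level tibble (one row per exon or CDS interval, with the
transcript's score and source gene name repeated on each row), which lets
every rule be expressed as an ordinary grouped data-frame operation.

## Contamination screening by summed bitscores

The screen models a two-stage decontamination. A prior, per-contig label —
in practice from a k-mer classifier run against a database containing the
target clade, close relatives and common contaminants — partitions contigs
into three disjoint sets:

* **prior retain** (default labels `target_species`, `unclassified`): kept
  outright. Unclassified contigs are retained, not dropped: absence of a
  database match is weak evidence of contamination for a novel genome.
* **prior drop** (default `bacteria`): removed outright.
* **adjudicate** (default `flagged`, e.g. contigs the classifier called
  human): resolved by BLAST taxonomy.

For an adjudicated contig, every BLAST hit with e-value *strictly below*
`evalue_max` (default $10^{-25}$) contributes its bitscore to its subject
taxon; the contig is assigned the taxon with the highest summed bitscore,

$$\hat{t} = \arg\max_t \sum_{h:\ \mathrm{taxid}(h)=t,\ e(h) < 10^{-25}} \mathrm{bitscore}(h),$$

and retained iff the assigned taxon's lineage contains the retained clade
(default rank `order`, name `Rodentia`) **or** no hit passed the threshold.
A flagged contig with rodent-dominated homology is a true target sequence
the k-mer classifier mislabelled; one with no strong hit at all carries no
positive evidence of contamination.

Reading "hits to order Rodentia" as a property of the *assigned* taxon is a
design choice: the alternative — retain if *any* single passing hit is
rodent — is more permissive and is available as `any_hit_mode = TRUE` in
`screen_policy()`. Ties in the summed score break to the smallest taxid so
runs are reproducible; the e-value boundary is strict (a hit at exactly
$10^{-25}$ does not count).

Every contig receives exactly one decision with an explicit reason
(`prior_retain`, `prior_drop`, `adjudicated_lineage_retain`,
`adjudicated_no_hits_retain`, `adjudicated_drop`), so the audit trail in
`tidy(screen_result)` reconstructs the verdict without rerunning anything.

```{r screen-demo}
fx <- simulate_assembly(
  seed = 1, n_target = 2028, n_bacteria = 3,
  n_flagged = 74, n_unclassified = 3, n_flagged_retain = 47
)
res <- screen_assembly(fx$contigs, fx$manifest, fx$hits, fx$lineages)
glance(res)
```

## The five-rule curation pipeline

Homology-based gene predictors produce artifacts with recognisable
signatures: one locus annotated with transcripts lifted from differently
named reference genes, one reference gene name scattered over several loci,
gene fusions introduced by UTR inference, spurious micro-exons, and
redundant isoforms. `curate()` applies five deterministic rules in a fixed
order (the order in which the artifacts are naturally described — name
resolution before locus deduplication, structure filters last):

1. **`resolve_locus_gene_names`** — within a locus, keep only transcripts
   whose source gene name matches that of the locus's top-scoring
   transcript (by predictor score). The top transcript always survives, so
   no locus is emptied. Score ties keep the name of the transcript first in
   input order.
2. **`dedupe_named_loci`** — when one gene name is attached to several
   loci, keep the locus with the highest top score. Unnamed loci are exempt.
   Ties break to the smaller leftmost coordinate, then the smaller locus id.
3. **`strip_shared_exons`** — an exon interval (exact seqid/start/end/strand
   equality, not overlap) owned by transcripts of two *different* genes is a
   fusion artifact; the exon is trimmed from every owning transcript, CDS
   intervals inside it are removed with it, and transcripts emptied of exons
   are dropped. Exact equality rather than overlap is deliberate: the rule
   targets the same predicted exon copied into two gene models, and
   overlap-based merging would sweep in legitimate overlapping genes.
4. **`filter_structural`** — eliminate transcripts with an exon shorter
   than 15 bp (strict: a 15 bp exon survives) or an intron whose
   donor–acceptor dinucleotides, read in transcript orientation
   (reverse-complemented on the minus strand), are not in the canonical set.
   The default set is GT–AG only; the minor spliceosomal consensi GC–AG and
   AT–AC can be admitted via `splice_canon`. Introns shorter than 4 bp
   cannot host both dinucleotides and are treated as noncanonical.
5. **`dedupe_identical_isoforms`** — among a gene's transcripts with an
   identical ordered exon-boundary list, keep the one with the longest
   spliced CDS; ties break to the smallest transcript id.

The pipeline is idempotent (each rule's postcondition is preserved by every
later rule), and the report is a complete action log: transcript counts are
conserved as `in = out + removed` across stages. Rule order matters in
principle — e.g. a structural filter running *before* name resolution could
change which transcript is a locus's top scorer — so the order is fixed and
documented rather than configurable.

## Distance-gated 3' UTR extension

In 3'-biased RNA sequencing (notably droplet scRNA-seq), reads pile up
downstream of annotated transcript ends; if the annotated 3' UTR stops
short, those reads fall outside every feature and are lost to counting. The
remedy implemented here is deliberately conservative: extend each
transcript's 3'-terminal exon outward by a constant `extension_bp`
(default 1,000 bp) only when the distance from the transcript's 3' end to
the next annotated feature — the span of any other gene locus, on either
strand — is at least `min_gap_bp` (default 3,000 bp, inclusive).

Three choices make this provably safe:

* **Gaps are measured against gene-locus spans**, not individual exons, so
  a transcript never gates on its own gene's other isoforms.
* **All gaps are computed once against the pre-extension annotation**, then
  applied. No cascade: the result is independent of iteration order.
* **`extension_bp < min_gap_bp` is enforced**, so an extension leaves at
  least `min_gap_bp - extension_bp` (2,000 bp at defaults) to every
  pre-existing feature. Two convergently transcribed neighbours can both
  extend toward each other, leaving `min_gap_bp - 2 * extension_bp`
  (1,000 bp) — still a positive gap, never an overlap.

A transcript with *no* downstream feature on its contig is extended
regardless of the remaining distance and clamped at the contig end
(extending as far as possible rather than skipping maximises read capture,
which is the point of the rule; clamped cases are flagged in the log).
Only the 3'-terminal exon coordinate moves; exon count, CDS and strand are
untouched, so downstream coding analyses are unaffected.

`quantify_extension_effect()` compares per-gene read-assignment counts
before and after the change: the percent change in total assigned reads,
genes newly detected (zero before, any read after — "any read" because a
detection threshold would be arbitrary here), and genes gaining at least
`gain_threshold` (default 20%, inclusive boundary; the comparison uses a
$10^{-9}$ epsilon so the exact 20% case is never lost to binary rounding of
0.2).

## Contiguity and BUSCO arithmetic

`contiguity_stats()` computes the standard panel: contig counts and summed
lengths at minimum-length thresholds (defaults 0, 25 kb, 50 kb), N50 and
L50 by the cumulative-sum convention — sort lengths descending, N50 is the
length at which the running total first reaches at least half the assembly
total, L50 its 1-based rank; a running total hitting exactly half counts.
N50 is always a member of the input lengths and all outputs are
permutation-invariant.

`read_busco_summary()` parses the labelled counts of a BUSCO short-summary
file and `validate_busco_summary()` checks the two arithmetic identities
$C = S + D$ and $n = C + F + M$, reporting recomputed values rather than
erroring, so a transcription mistake in a report is surfaced with the
corrected sums.

```{r busco-demo}
f <- tempfile()
simulate_busco(single = 12467, duplicated = 225, fragmented = 267, missing = 839, path = f)
validate_busco_summary(read_busco_summary(f))
```

## What the synthetic fixtures emulate — and what they do not

`simulate_assembly()` and `simulate_annotation()` generate every input the
toolkit consumes, with a ledger of planted truths:

* The assembly generator plants the four prior categories, builds flagged
  contigs' BLAST tables so a chosen number adjudicate to retain (via
  dominant rodent scores, via hits that all miss the strict e-value cutoff,
  or via no hits at all) and the rest to drop via dominant primate scores.
  Contig lengths default to 1–50 kb so full-size screens (2,108 contigs)
  run in seconds; sequences are only generated on request since screening
  and statistics need only lengths.
* The annotation generator lays out 2–4-exon gene models (exons 80–300 bp,
  introns 200–600 bp, UTR trims 30–60 bp — small but plausible mammalian
  micro-scale values chosen once for test speed) along one contig, writes
  canonical strand-aware splice dinucleotides into the sequence, and plants
  each requested defect on its own gene(s) so defects cannot interact.
  Inter-gene gaps default to 1,500–6,000 bp, deliberately straddling the
  3,000 bp extension gate; tests of the gate pass exact gaps instead.
* The BUSCO generator emits the short-summary dialect, optionally with
  exactly one arithmetic identity violated.

One integer seed drives each generator; identical seeds give byte-identical
files. The fixtures establish that the *decision rules* are implemented
exactly: every planted defect is acted on, nothing else is touched, and
screening agrees with an independent brute-force re-derivation. They do not
emulate real biological structure — no repeat content, no codon structure,
no realistic score distributions, no multi-contig gene families — so
passing tests say nothing about how noisy real predictor output is, only
that the stated rules are applied to it faithfully.

Problem sizes used by the test suite and the acceptance script (fixtures of
up to ~2,100 contigs for screening, 10–20 genes for curation and extension,
1,000 lengths for contiguity oracles, 20 seeds per property) were chosen so
a full run completes in about a minute on one core.

## Numerical and degenerate-input choices

* E-value threshold: strict `<`; score argmax ties: smallest taxid; name
  ties: first in input order (resolution) / leftmost then smallest id
  (locus dedup) / smallest transcript id (isoform dedup). Every tie-break
  is deterministic on purpose.
* Empty inputs degrade cleanly: empty FASTA/BLAST/lineage files parse to
  empty typed tables; an empty assembly screens to an empty result. N50 of
  an empty length set is an error rather than a sentinel value.
* Multi-taxid BLAST cells (`9606;63221`) keep the first taxid with a
  warning.
* An assigned taxon missing from the lineage table is an error, not a
  silent drop: an unresolvable taxonomy means the inputs are inconsistent.
* The percent-gain boundary uses an epsilon of $10^{-9}$, far below the
  one-read resolution of count data.

## Known limitations

* The screen consumes the prior classifier's manifest; it cannot recover a
  target contig the classifier labelled `bacteria` (prior drops are not
  adjudicated), mirroring the two-stage design it implements.
* `strip_shared_exons` trims exact-duplicate exons only; fusions realised
  as *overlapping but unequal* exons pass through.
* Gap measurement treats every other gene locus span as a feature;
  single-exon repeat annotations or ncRNAs, if present in the input, gate
  extensions like any other gene.
* The UTR extension is constant-length; it does not use read coverage to
  choose an extension size.
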