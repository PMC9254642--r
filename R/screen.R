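#' Screening policy for contig contamination adjudication
#'
#' Bundles the parameters of the contamination screen. Contigs carrying a
#' prior label in `prior_retain_labels` (typically target-species and
#' unclassified contigs from an external k-mer classifier) are kept outright;
#' labels in `prior_drop_labels` (typically bacteria) are removed outright;
#' labels in `adjudicate_labels` (contigs the classifier flagged, e.g. as
#' human) go through BLAST-based taxonomic adjudication: bitscores are summed
#' per subject taxon over hits with e-value strictly below `evalue_max`, the
#' top-scoring taxon is assigned, and the contig is retained when that
#' taxon's lineage contains `retain_name` at `retain_rank` or when no hit
#' passes the threshold.
#'
#' @param evalue_max Strict e-value cutoff for a hit to contribute
#'   (default `1e-25`).
#' @param retain_rank Lineage rank tested for retention (default `"order"`).
#' @param retain_name Name required at that rank (default `"Rodentia"`).
#' @param prior_retain_labels,prior_drop_labels,adjudicate_labels Disjoint
#'   character sets partitioning the manifest labels.
#' @param any_hit_mode If `TRUE`, a flagged contig is retained when *any*
#'   passing hit's taxon lies in the retained clade, rather than requiring
#'   the top-scoring assigned taxon to (default `FALSE`).
#' @return A `screen_policy` object (validated list).
#' @seealso [screen_assembly()]
#' @export
screen_policy <- function(evalue_max = 1e-25,
                          retain_rank = "order",
                          retain_name = "Rodentia",
                          prior_retain_labels = c("target_species", "unclassified"),
                          prior_drop_labels = "bacteria",
                          adjudicate_labels = "flagged",
                          any_hit_mode = FALSE) {
  if (!is.numeric(evalue_max) || length(evalue_max) != 1 || evalue_max <= 0) {
    abort("`evalue_max` must be a single positive number")
  }
  sets <- list(prior_retain_labels, prior_drop_labels, adjudicate_labels)
  all_labels <- unlist(sets)
  if (anyDuplicated(all_labels)) {
    abort("screen_policy label sets must be disjoint")
  }
  structure(
    list(
      evalue_max = evalue_max,
      retain_rank = retain_rank,
      retain_name = retain_name,
      prior_retain_labels = prior_retain_labels,
      prior_drop_labels = prior_drop_labels,
      adjudicate_labels = adjudicate_labels,
      any_hit_mode = isTRUE(any_hit_mode)
    ),
    class = "screen_policy"
  )
}

#' Sum BLAST bitscores per contig and subject taxon
#'
#' Only hits with e-value *strictly below* `evalue_max` contribute. Contigs
#' with no passing hit are absent from the result; summation is
#' order-independent.
#'
#' @param hits Hit tibble (see [read_blast_tab()]); only `query_id`,
#'   `subject_taxid`, `evalue` and `bitscore` are used.
#' @param evalue_max Strict inclusion threshold (default `1e-25`).
#' @return Tibble with one row per (contig, taxon): `contig_id`,
#'   `taxid`, `score` (summed bitscore), sorted by contig then descending
#'   score then taxid.
#' @examples
#' hits <- tibble::tibble(
#'   query_id = "c1", subject_taxid = c(10090L, 10090L, 9606L),
#'   evalue = c(1e-30, 1e-40, 1e-26), bitscore = c(100, 50, 120)
#' )
#' aggregate_hit_scores(hits)
#' @export
aggregate_hit_scores <- function(hits, evalue_max = 1e-25) {
  hits %>%
    filter(.data$evalue < .env$evalue_max) %>%
    group_by(contig_id = .data$query_id, taxid = .data$subject_taxid) %>%
    summarise(score = sum(.data$bitscore), .groups = "drop") %>%
    arrange(.data$contig_id, desc(.data$score), .data$taxid)
}

#' Assign the taxon with the highest summed bitscore
#'
#' @param taxid_scores Tibble with `taxid` and `score` columns for one
#'   contig (e.g. one contig's rows from [aggregate_hit_scores()]).
#' @return The argmax taxid (integer); ties break to the smallest taxid;
#'   `NA` when the table is empty.
#' @export
assign_contig_taxon <- function(taxid_scores) {
  if (nrow(taxid_scores) == 0) {
    return(NA_integer_)
  }
  ord <- order(-taxid_scores$score, taxid_scores$taxid)
  as.integer(taxid_scores$taxid[ord[1]])
}

#' Decide retention of an adjudicated contig
#'
#' Encodes the retention rule for flagged contigs: retain when no hit passed
#' the e-value threshold (`assigned` is `NA`), retain when the assigned
#' taxon's lineage contains the policy's clade (by default order Rodentia),
#' otherwise drop.
#'
#' @param assigned Assigned taxid from [assign_contig_taxon()], or `NA`.
#' @param lineages Long lineage tibble (see [read_lineage_table()]).
#' @param policy A [screen_policy()].
#' @return A list with `verdict` (`"retain"`/`"drop"`) and `reason` (one of
#'   `"adjudicated_no_hits_retain"`, `"adjudicated_lineage_retain"`,
#'   `"adjudicated_drop"`).
#' @export
decide_retention <- function(assigned, lineages, policy = screen_policy()) {
  if (is.na(assigned)) {
    return(list(verdict = "retain", reason = "adjudicated_no_hits_retain"))
  }
  if (!assigned %in% lineages$taxid) {
    abort(paste0(
      "Assigned taxid ", assigned, " is absent from the lineage table"
    ))
  }
  if (lineage_contains(lineages, assigned, policy$retain_rank, policy$retain_name)) {
    list(verdict = "retain", reason = "adjudicated_lineage_retain")
  } else {
    list(verdict = "drop", reason = "adjudicated_drop")
  }
}

#' Screen an assembly for contaminant contigs
#'
#' Applies the full contamination screen: prior labels decide outright
#' retention/removal, and contigs in the policy's adjudication set are
#' resolved by summed-bitscore BLAST taxonomy ([aggregate_hit_scores()] then
#' [assign_contig_taxon()] then [decide_retention()]). Every input contig
#' receives exactly one decision; the retained set preserves input order.
#'
#' @param contigs Contig tibble (see [read_fasta()]).
#' @param manifest Tibble with `contig_id` and `label` columns: the prior
#'   classification of every contig (e.g. from a k-mer classifier).
#' @param hits BLAST hit tibble (see [read_blast_tab()]); hits for
#'   non-adjudicated contigs are ignored.
#' @param lineages Long lineage tibble (see [read_lineage_table()]).
#' @param policy A [screen_policy()].
#' @return A `screen_result`: list with `contigs` (retained rows of the
#'   input, input order), `decisions` (audit tibble: `contig_id`,
#'   `prior_label`, `assigned_taxid`, `top_score`, `verdict`, `reason`) and
#'   `policy`. `tidy()` returns the decisions, `glance()` the counts.
#' @examples
#' contigs <- tibble::tibble(id = c("c1", "c2"), length = c(100L, 200L))
#' manifest <- tibble::tibble(
#'   contig_id = c("c1", "c2"),
#'   label = c("target_species", "bacteria")
#' )
#' hits <- tibble::tibble(
#'   query_id = character(), subject_id = character(),
#'   evalue = double(), bitscore = double(), subject_taxid = integer()
#' )
#' lineages <- tibble::tibble(
#'   taxid = integer(), depth = integer(),
#'   rank = character(), name = character()
#' )
#' res <- screen_assembly(contigs, manifest, hits, lineages)
#' glance(res)
#' @export
screen_assembly <- function(contigs, manifest, hits, lineages,
                            policy = screen_policy()) {
  check_contigs(contigs)
  if (!all(c("contig_id", "label") %in% names(manifest))) {
    abort("`manifest` must have columns contig_id, label")
  }
  missing <- setdiff(contigs$id, manifest$contig_id)
  if (length(missing) > 0) {
    abort(paste0(
      length(missing), " contig(s) missing from the manifest, e.g. ",
      paste(head(missing, 3), collapse = ", ")
    ))
  }
  label <- setNames(manifest$label, manifest$contig_id)[contigs$id]
  known <- c(
    policy$prior_retain_labels, policy$prior_drop_labels,
    policy$adjudicate_labels
  )
  if (!all(label %in% known)) {
    abort(paste0(
      "Manifest label(s) outside the policy's sets: ",
      paste(unique(label[!label %in% known]), collapse = ", ")
    ))
  }

  scores <- aggregate_hit_scores(hits, policy$evalue_max)
  scores_by_contig <- split(scores, scores$contig_id)

  decide_one <- function(id, lab) {
    if (lab %in% policy$prior_retain_labels) {
      return(tibble(
        contig_id = id, prior_label = lab, assigned_taxid = NA_integer_,
        top_score = NA_real_, verdict = "retain", reason = "prior_retain"
      ))
    }
    if (lab %in% policy$prior_drop_labels) {
      return(tibble(
        contig_id = id, prior_label = lab, assigned_taxid = NA_integer_,
        top_score = NA_real_, verdict = "drop", reason = "prior_drop"
      ))
    }
    sc <- scores_by_contig[[id]]
    if (is.null(sc)) {
      sc <- tibble(taxid = integer(), score = double())
    }
    assigned <- assign_contig_taxon(sc)
    if (policy$any_hit_mode && nrow(sc) > 0) {
      any_in <- any(lineage_contains(
        lineages, sc$taxid, policy$retain_rank, policy$retain_name
      ))
      dec <- if (any_in) {
        list(verdict = "retain", reason = "adjudicated_lineage_retain")
      } else {
        list(verdict = "drop", reason = "adjudicated_drop")
      }
    } else {
      dec <- decide_retention(assigned, lineages, policy)
    }
    tibble(
      contig_id = id, prior_label = lab, assigned_taxid = assigned,
      top_score = if (nrow(sc) > 0) max(sc$score) else NA_real_,
      verdict = dec$verdict, reason = dec$reason
    )
  }

  decisions <- purrr::map2(contigs$id, unname(label), decide_one) %>% bind_rows()
  if (nrow(decisions) == 0) {
    decisions <- tibble(
      contig_id = character(), prior_label = character(),
      assigned_taxid = integer(), top_score = double(),
      verdict = character(), reason = character()
    )
  }
  retained <- contigs[contigs$id %in% decisions$contig_id[decisions$verdict == "retain"], ]
  structure(
    list(contigs = retained, decisions = decisions, policy = policy),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  g <- glance(x)
  cat(
    "Contamination screen: ", g$n_input, " contigs -> ", g$n_retained,
    " retained, ", g$n_dropped, " dropped\n",
    sep = ""
  )
  print(dplyr::count(x$decisions, .data$verdict, .data$reason))
  invisible(x)
}

#' @exportS3Method
tidy.screen_result <- function(x, ...) {
  x$decisions
}

#' @exportS3Method
glance.screen_result <- function(x, ...) {
  d <- x$decisions
  tibble(
    n_input = nrow(d),
    n_retained = sum(d$verdict == "retain"),
    n_dropped = sum(d$verdict == "drop"),
    n_prior_retain = sum(d$reason == "prior_retain"),
    n_prior_drop = sum(d$reason == "prior_drop"),
    n_adjudicated_lineage_retain = sum(d$reason == "adjudicated_lineage_retain"),
    n_adjudicated_no_hits_retain = sum(d$reason == "adjudicated_no_hits_retain"),
    n_adjudicated_drop = sum(d$reason == "adjudicated_drop")
  )
}

#' Plot the audit trail of a contamination screen
#'
#' Bar chart of decision reasons, filled by verdict.
#'
#' @param object A `screen_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.screen_result <- function(object, ...) {
  d <- dplyr::count(object$decisions, .data$reason, .data$verdict)
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$reason, -.data$n), y = .data$n, fill = .data$verdict
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "contigs", fill = "verdict",
      title = "Contamination screen decisions"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
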