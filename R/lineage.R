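#' Read a taxid-to-lineage table
#'
#' The interchange format is a two-column TSV: a numeric taxid and a
#' semicolon-joined list of `rank:name` pairs ordered root to leaf, e.g.
#' `10090<TAB>superkingdom:Eukaryota;order:Rodentia;species:Mus musculus`.
#' This file is the only taxonomy input the toolkit needs; it replaces any
#' dependency on the full NCBI taxonomy dump.
#'
#' @param path Path to the lineage TSV.
#' @return A long tibble with columns `taxid` (integer), `depth` (integer,
#'   1 = root-most), `rank` (character) and `name` (character).
#' @seealso [lineage_contains()], [decide_retention()]
#' @export
read_lineage_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Lineage table not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble(
      taxid = integer(), depth = integer(),
      rank = character(), name = character()
    ))
  }
  fields <- stringr::str_split_fixed(lines, stringr::fixed("\t"), 2)
  taxid <- suppressWarnings(as.integer(fields[, 1]))
  if (anyNA(taxid) || any(taxid <= 0)) {
    bad <- which(is.na(taxid) | taxid <= 0)[1]
    abort(paste0(
      "Lineage table '", path, "' line ", bad, ": invalid taxid '",
      fields[bad, 1], "'"
    ))
  }
  if (anyDuplicated(taxid)) {
    abort(paste0(
      "Lineage table '", path, "': duplicate taxid(s) ",
      paste(unique(taxid[duplicated(taxid)]), collapse = ", ")
    ))
  }
  rows <- purrr::map2(taxid, fields[, 2], function(tx, spec) {
    pairs <- stringr::str_split_1(spec, stringr::fixed(";"))
    pairs <- pairs[nzchar(pairs)]
    if (length(pairs) == 0) {
      abort(paste0("Lineage table '", path, "': empty lineage for taxid ", tx))
    }
    rank_name <- stringr::str_split_fixed(pairs, stringr::fixed(":"), 2)
    if (any(rank_name[, 1] == "" | rank_name[, 2] == "")) {
      abort(paste0(
        "Lineage table '", path, "': malformed rank:name pair '",
        pairs[rank_name[, 1] == "" | rank_name[, 2] == ""][1],
        "' for taxid ", tx
      ))
    }
    if (anyDuplicated(rank_name[, 1])) {
      abort(paste0(
        "Lineage table '", path, "': duplicate rank within lineage of taxid ", tx
      ))
    }
    tibble(
      taxid = tx, depth = seq_along(pairs),
      rank = rank_name[, 1], name = rank_name[, 2]
    )
  })
  bind_rows(rows)
}

#' Test lineage membership at a given rank
#'
#' @param lineages Long lineage tibble from [read_lineage_table()].
#' @param taxid Taxid(s) to test (vectorised).
#' @param rank Rank to look at, e.g. `"order"`.
#' @param name Name required at that rank, e.g. `"Rodentia"`.
#' @return Logical vector, one element per input taxid; `FALSE` for taxids
#'   absent from the table.
#' @examples
#' lin <- tibble::tibble(
#'   taxid = 10090L, depth = 1:2,
#'   rank = c("order", "species"), name = c("Rodentia", "Mus musculus")
#' )
#' lineage_contains(lin, 10090L, "order", "Rodentia")
#' @export
lineage_contains <- function(lineages, taxid, rank, name) {
  hits <- lineages$taxid[lineages$rank == rank & lineages$name == name]
  as.integer(taxid) %in% hits
}

#' Write a lineage tibble back to the two-column TSV interchange format
#'
#' Rows are emitted sorted by taxid, pairs in `depth` order.
#'
#' @param lineages Long lineage tibble from [read_lineage_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(lineages, path) {
  spec <- lineages %>%
    arrange(.data$taxid, .data$depth) %>%
    group_by(.data$taxid) %>%
    summarise(
      lineage = paste(paste0(.data$rank, ":", .data$name), collapse = ";"),
      .groups = "drop"
    )
  readr::write_lines(paste0(spec$taxid, "\t", spec$lineage), path)
  invisible(path)
}
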