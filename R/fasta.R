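#' Read a FASTA file into a contig table
#'
#' Parses a (possibly line-wrapped) multi-record nucleotide FASTA file and
#' returns one row per record, in file order. The first whitespace-delimited
#' token of each header is taken as the contig id.
#'
#' @param path Path to a FASTA file.
#' @param keep_sequence Keep the sequence column (default `TRUE`). Dropping it
#'   saves memory when only lengths are needed (e.g. contiguity statistics).
#' @return A tibble with columns `id` (character), `length` (integer, bp) and,
#'   when `keep_sequence = TRUE`, `sequence` (uppercase character).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGT", ">c2", "AC"), fa)
#' read_fasta(fa)
#' @seealso [write_fasta()], [contiguity_stats()]
#' @export
read_fasta <- function(path, keep_sequence = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path),
      error = function(e) {
        abort(paste0("Malformed FASTA in '", path, "': ", conditionMessage(e)))
      }
    ),
    warning = function(w) {
      # non-IUPAC residues are silently dropped by the reader; treat as fatal
      if (grepl("invalid one-letter sequence code", conditionMessage(w))) {
        abort(paste0("Non-IUPAC residue(s) in '", path, "': ", conditionMessage(w)))
      }
      invokeRestart("muffleWarning")
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyNA(ids) || any(ids == "")) {
    abort(paste0("FASTA record with empty header in '", path, "'"))
  }
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate contig id(s) in '", path, "': ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  out <- tibble(
    id = unname(ids),
    length = Biostrings::width(set)
  )
  if (keep_sequence) {
    out$sequence <- unname(toupper(as.character(set)))
  }
  out
}

#' Write a contig table to FASTA
#'
#' Records are written in the order of the input table, wrapped at a fixed
#' line width, so identical tables yield byte-identical files.
#'
#' @param contigs Tibble with `id` and `sequence` columns (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @param width Sequence line width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 70) {
  check_contigs(contigs, need_sequence = TRUE)
  set <- Biostrings::DNAStringSet(setNames(contigs$sequence, contigs$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Validate the contig-table contract shared by all modules.
check_contigs <- function(contigs, need_sequence = FALSE, arg = "contigs") {
  if (!is.data.frame(contigs) || !all(c("id", "length") %in% names(contigs))) {
    abort(paste0("`", arg, "` must be a data frame with columns id, length"))
  }
  if (anyDuplicated(contigs$id)) {
    abort(paste0("`", arg, "` has duplicated contig ids"))
  }
  if (need_sequence) {
    if (!"sequence" %in% names(contigs) || anyNA(contigs$sequence)) {
      abort(paste0("`", arg, "` must carry a sequence for every contig"))
    }
    if (any(nchar(contigs$sequence) != contigs$length)) {
      abort(paste0("`", arg, "`: length column disagrees with sequence length"))
    }
  }
  invisible(contigs)
}
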