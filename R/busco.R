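#' Read a BUSCO short-summary text file
#'
#' Extracts the six labelled category counts from BUSCO's
#' `short_summary*.txt` format: complete (C), complete single-copy (S),
#' complete duplicated (D), fragmented (F), missing (M) and the total number
#' of groups searched. Parsing keys on the `(C)`/`(S)`/`(D)`/`(F)`/`(M)`
#' labels and the "Total BUSCO groups searched" line, so indentation and the
#' one-line `C:...%[S:...]` summary are ignored.
#'
#' @param path Path to a BUSCO short-summary text file.
#' @return A `busco_summary` object: a list with integer fields `complete`,
#'   `single`, `duplicated`, `fragmented`, `missing`, `total`.
#' @seealso [validate_busco_summary()], [simulate_busco()]
#' @export
read_busco_summary <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("BUSCO summary not found: ", path))
  }
  lines <- readr::read_lines(path)
  grab <- function(pattern, label) {
    hit <- stringr::str_match(lines, paste0("(\\d+)\\s+[^\\d]*", pattern))
    vals <- hit[!is.na(hit[, 2]), 2]
    if (length(vals) == 0) {
      abort(paste0(
        "BUSCO summary '", path, "': no line with a count labelled ", label
      ))
    }
    as.integer(vals[1])
  }
  out <- list(
    complete = grab("\\(C\\)", "(C)"),
    single = grab("\\(S\\)", "(S)"),
    duplicated = grab("\\(D\\)", "(D)"),
    fragmented = grab("\\(F\\)", "(F)"),
    missing = grab("\\(M\\)", "(M)"),
    total = grab("Total BUSCO groups searched", "'Total BUSCO groups searched'")
  )
  if (any(unlist(out) < 0)) {
    abort(paste0("BUSCO summary '", path, "': negative count"))
  }
  structure(out, class = "busco_summary")
}

#' Construct a BUSCO summary object directly
#'
#' @param single,duplicated,fragmented,missing Category counts.
#' @param complete Complete count; defaults to `single + duplicated`.
#' @param total Groups searched; defaults to
#'   `complete + fragmented + missing`.
#' @return A `busco_summary` object.
#' @export
busco_summary <- function(single, duplicated, fragmented, missing,
                          complete = single + duplicated,
                          total = complete + fragmented + missing) {
  out <- list(
    complete = as.integer(complete), single = as.integer(single),
    duplicated = as.integer(duplicated), fragmented = as.integer(fragmented),
    missing = as.integer(missing), total = as.integer(total)
  )
  if (any(unlist(out) < 0)) {
    abort("BUSCO counts must be non-negative")
  }
  structure(out, class = "busco_summary")
}

#' Check the arithmetic identities of a BUSCO summary
#'
#' A consistent summary satisfies `complete = single + duplicated` and
#' `total = complete + fragmented + missing`. Inconsistency is reported, not
#' raised: parsing a malformed report should not stop a pipeline, but the
#' recomputed sums make the discrepancy auditable.
#'
#' @param s A `busco_summary` object.
#' @return A one-row tibble: `ok`, `complete_stated`, `complete_recomputed`,
#'   `total_stated`, `total_recomputed`, `complete_consistent`,
#'   `total_consistent`.
#' @examples
#' validate_busco_summary(busco_summary(12467, 225, 267, 839))
#' @export
validate_busco_summary <- function(s) {
  stopifnot(inherits(s, "busco_summary"))
  complete_rec <- s$single + s$duplicated
  total_rec <- complete_rec + s$fragmented + s$missing
  cc <- s$complete == complete_rec
  tc <- s$total == s$complete + s$fragmented + s$missing
  tibble(
    ok = cc && tc,
    complete_stated = s$complete,
    complete_recomputed = complete_rec,
    total_stated = s$total,
    total_recomputed = total_rec,
    complete_consistent = cc,
    total_consistent = tc
  )
}

#' @export
print.busco_summary <- function(x, ...) {
  cat(
    "BUSCO summary: C:", x$complete, " [S:", x$single, ", D:", x$duplicated,
    "], F:", x$fragmented, ", M:", x$missing, ", n:", x$total, "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method
tidy.busco_summary <- function(x, ...) {
  tibble(
    category = c(
      "complete", "single_copy", "duplicated", "fragmented", "missing",
      "total_searched"
    ),
    count = c(x$complete, x$single, x$duplicated, x$fragmented, x$missing, x$total)
  )
}

#' @exportS3Method
glance.busco_summary <- function(x, ...) {
  tibble(
    complete = x$complete, single = x$single, duplicated = x$duplicated,
    fragmented = x$fragmented, missing = x$missing, total = x$total,
    pct_complete = 100 * x$complete / x$total,
    consistent = validate_busco_summary(x)$ok
  )
}
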