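#' Validate a range query against the numbering table and limits
#'
#' Each endpoint is resolved to a polymer index through the structure's
#' numbering table; ranges are checked against the query limits: at most
#' `max_ranges` ranges (default 5) and at most `max_span` structure
#' residues per range inclusive (default 50). Endpoints must be in
#' increasing polymer order — the order of the numbering table, so
#' insertion-code runs such as 190, 190A, ..., 190L validate correctly —
#' and must be mappable: an endpoint aligned to a gap in the lookup
#' sequence (an engineered insert or unalignable residue) has no
#' equivalent alignment position and fails with the error condition
#' "No data available in table".
#'
#' @param ranges list of `unit_range` (or a `units=` string).
#' @param la a `lookup_aln` (provides numbering).
#' @param rm residue map from [build_residue_map()].
#' @param max_ranges,max_span query limits.
#' @return An object of class `range_query`: the validated ranges with
#'   polymer-index intervals, ready for [resolve_columns()].
#' @export
validate_query <- function(ranges, la, rm, max_ranges = 5L, max_span = 50L) {
  if (is.character(ranges)) ranges <- parse_units_string(ranges)
  stopifnot(inherits(la, "lookup_aln"))
  if (length(ranges) == 0) {
    msamap_abort("PARSE_ERROR", "A query must contain at least one range.")
  }
  if (length(ranges) > max_ranges) {
    msamap_abort("TOO_MANY_RANGES", sprintf(
      "Query has %d ranges; at most %d are allowed.", length(ranges), max_ranges
    ))
  }
  numbering <- la$numbering
  rows <- dplyr::bind_rows(lapply(ranges, function(r) {
    start_pi <- polymer_index_of(r$start$number, r$start$insertion_code, numbering)
    end_pi <- polymer_index_of(r$end$number, r$end$insertion_code, numbering)
    if (start_pi > end_pi) {
      msamap_abort("ENDPOINTS_OUT_OF_ORDER", sprintf(
        "Range endpoints %s:%s are not in increasing order.",
        residue_key(r$start$number, r$start$insertion_code),
        residue_key(r$end$number, r$end$insertion_code)
      ))
    }
    span <- end_pi - start_pi + 1L
    if (span > max_span) {
      msamap_abort("RANGE_TOO_LONG", sprintf(
        "Range %s:%s spans %d residues; at most %d are allowed.",
        residue_key(r$start$number, r$start$insertion_code),
        residue_key(r$end$number, r$end$insertion_code), span, max_span
      ))
    }
    if (is.na(rm[start_pi]) || is.na(rm[end_pi])) {
      msamap_abort("NO_DATA", "No data available in table")
    }
    tibble::tibble(
      start_key = residue_key(r$start$number, r$start$insertion_code),
      end_key = residue_key(r$end$number, r$end$insertion_code),
      start_pi = start_pi, end_pi = end_pi, span = span
    )
  }))
  structure(
    list(
      units = format_units_string(ranges),
      ranges = rows,
      limits = list(max_ranges = as.integer(max_ranges), max_span = as.integer(max_span))
    ),
    class = "range_query"
  )
}

#' @export
print.range_query <- function(x, ...) {
  cat("<range_query> ", x$units, "\n", sep = "")
  print(x$ranges)
  invisible(x)
}

#' Resolve validated ranges to alignment column intervals
#'
#' Maps each range's endpoints through the residue and column maps and
#' takes the inclusive column interval between them. The interval keeps
#' interior columns where the lookup row is gapped — insertions carried by
#' other sequences — and bridges interior unmappable residues: extraction
#' is purely column-interval based.
#'
#' @param q a validated `range_query`.
#' @param rm,cm residue and column maps.
#' @param offset natural-position offset from [check_consistency()].
#' @return `q` with `start_col`, `end_col`, `width` added per range.
#' @export
resolve_columns <- function(q, rm, cm, offset = 0L) {
  stopifnot(inherits(q, "range_query"))
  q$ranges <- dplyr::mutate(
    q$ranges,
    start_col = cm[rm[.data$start_pi] + offset],
    end_col = cm[rm[.data$end_pi] + offset],
    width = .data$end_col - .data$start_col + 1L
  )
  q
}

#' Extract the addressed column blocks for every sequence
#'
#' For each sequence of the data alignment, takes the substring of its
#' gapped row over each range's column interval. Sequences whose extracts
#' are all gaps are retained: a deletion is data. The display string joins
#' per-range extracts with `", "`.
#'
#' @param q a column-resolved `range_query`.
#' @param msa data alignment tibble.
#' @return A tibble with `seq_id`, `extracts` (list-column of per-range
#'   strings, in query order) and `display`.
#' @export
extract_columns <- function(q, msa) {
  stopifnot(inherits(q, "range_query"))
  if (!"start_col" %in% names(q$ranges)) {
    msamap_abort("USAGE_ERROR", "Call resolve_columns() before extract_columns().")
  }
  starts <- q$ranges$start_col
  ends <- q$ranges$end_col
  extracts <- lapply(msa$seq, function(row) {
    vapply(seq_along(starts), function(i) substr(row, starts[i], ends[i]), character(1))
  })
  tibble::tibble(
    seq_id = msa$seq_id,
    extracts = extracts,
    display = vapply(extracts, paste, character(1), collapse = ", ")
  )
}
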