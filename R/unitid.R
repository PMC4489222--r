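#' Unit IDs: residue-level addresses in macromolecular structure files
#'
#' A Unit ID is a pipe-delimited address of one residue in a 3D structure
#' file, with positional fields
#' `pdb|model|chain|identity|number|atom|alt_id|insertion_code|symmetry_op`.
#' `pdb_id`, `model` and `chain` are mandatory; everything after the residue
#' number is optional and trailing empty fields are omitted when formatting.
#' Insertion codes distinguish residues that share an author number, as in
#' structures numbered to match a homolog (`190`, `190A`, ..., `190L`).
#'
#' @param pdb_id 4-character structure identifier.
#' @param model positive integer model number.
#' @param chain non-empty chain identifier (case-sensitive).
#' @param identity optional one-letter residue code; ignored in comparisons.
#' @param number integer author residue number.
#' @param atom,alt_id optional fields, carried but unused.
#' @param insertion_code optional insertion code (compared case-insensitively).
#' @param symmetry_op optional symmetry operator.
#' @return An object of class `unit_id`.
#' @examples
#' u <- unit_id("2AW7", 1, "A", number = 1430)
#' format(u)
#' @export
unit_id <- function(pdb_id, model, chain, identity = "", number,
                    atom = "", alt_id = "", insertion_code = "",
                    symmetry_op = "") {
  if (!nzchar(pdb_id)) msamap_abort("PARSE_ERROR", "Unit ID field 'pdb_id' must be non-empty.")
  if (!nzchar(chain)) msamap_abort("PARSE_ERROR", "Unit ID field 'chain' must be non-empty.")
  model <- suppressWarnings(as.integer(model))
  if (is.na(model) || model < 1) {
    msamap_abort("PARSE_ERROR", "Unit ID field 'model' must be a positive integer.")
  }
  number <- suppressWarnings(as.integer(number))
  if (is.na(number)) msamap_abort("PARSE_ERROR", "Unit ID field 'number' must be an integer.")
  structure(
    list(
      pdb_id = pdb_id, model = model, chain = chain,
      identity = identity, number = number, atom = atom,
      alt_id = alt_id, insertion_code = insertion_code,
      symmetry_op = symmetry_op
    ),
    class = "unit_id"
  )
}

#' Parse a pipe-delimited Unit ID string
#'
#' Fields are positional: `pdb|model|chain|identity|number|atom|alt_id|`
#' `insertion_code|symmetry_op`. At least the first five must be present
#' (identity may be empty, as in `"2AW7|1|A||1430"`); absent trailing fields
#' default to empty. Whitespace around delimiters is tolerated.
#'
#' @param text a single Unit ID string.
#' @return A `unit_id` object.
#' @examples
#' parse_unit_id("2AW7|1|A||1430")
#' parse_unit_id("1FJG|1|A|U|190|||L")
#' @export
parse_unit_id <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) {
    msamap_abort("PARSE_ERROR", "Empty Unit ID string.")
  }
  fields <- trimws(strsplit(text, "|", fixed = TRUE)[[1]])
  # strsplit drops a trailing empty field; pad rather than guess
  if (length(fields) < 5) {
    msamap_abort("PARSE_ERROR", sprintf(
      "Unit ID '%s' has %d field(s); at least 5 (pdb|model|chain|identity|number) are required.",
      text, length(fields)
    ))
  }
  if (length(fields) > 9) {
    msamap_abort("PARSE_ERROR", sprintf("Unit ID '%s' has more than 9 fields.", text))
  }
  fields <- c(fields, rep("", 9 - length(fields)))
  if (!nzchar(fields[1])) msamap_abort("PARSE_ERROR", sprintf("Unit ID '%s': field 'pdb_id' is empty.", text))
  if (!nzchar(fields[3])) msamap_abort("PARSE_ERROR", sprintf("Unit ID '%s': field 'chain' is empty.", text))
  if (is.na(suppressWarnings(as.integer(fields[2])))) {
    msamap_abort("PARSE_ERROR", sprintf("Unit ID '%s': field 'model' ('%s') is not an integer.", text, fields[2]))
  }
  if (is.na(suppressWarnings(as.integer(fields[5])))) {
    msamap_abort("PARSE_ERROR", sprintf("Unit ID '%s': field 'number' ('%s') is not an integer.", text, fields[5]))
  }
  unit_id(
    pdb_id = fields[1], model = fields[2], chain = fields[3],
    identity = fields[4], number = fields[5], atom = fields[6],
    alt_id = fields[7], insertion_code = fields[8], symmetry_op = fields[9]
  )
}

#' Serialize a Unit ID to its canonical pipe-delimited form
#'
#' Internal empty fields are kept as empty strings between delimiters;
#' trailing empty fields are trimmed, so `unit_id("2AW7", 1, "A", number =
#' 1430)` prints as `"2AW7|1|A||1430"` and an insertion-code address as
#' `"1FJG|1|A|U|190|||L"`. Re-parsing the output yields a Unit ID
#' query-equal to the input.
#'
#' @param u a `unit_id`.
#' @return A single string.
#' @export
format_unit_id <- function(u) {
  stopifnot(inherits(u, "unit_id"))
  fields <- c(
    u$pdb_id, u$model, u$chain, u$identity, u$number,
    u$atom, u$alt_id, u$insertion_code, u$symmetry_op
  )
  fields <- as.character(fields)
  last <- max(5L, max(which(nzchar(fields))))
  paste(fields[seq_len(last)], collapse = "|")
}

#' @export
format.unit_id <- function(x, ...) format_unit_id(x)

#' @export
print.unit_id <- function(x, ...) {
  cat("<unit_id> ", format_unit_id(x), "\n", sep = "")
  invisible(x)
}

#' Compare two Unit IDs the way range queries do
#'
#' Two addresses are query-equal when `pdb_id`, `model`, `chain`, `number`
#' and `insertion_code` all agree. The residue identity field is ignored
#' (so `2AW7|1|A||1430` and `2AW7|1|A|A|1430` are identical addresses), as
#' are atom and alt-id; the symmetry operator is compared only when both
#' sides carry one. Insertion codes compare case-insensitively; pdb and
#' chain are case-sensitive.
#'
#' @param a,b `unit_id` objects.
#' @return Logical scalar.
#' @export
query_equal <- function(a, b) {
  stopifnot(inherits(a, "unit_id"), inherits(b, "unit_id"))
  same <- a$pdb_id == b$pdb_id &&
    a$model == b$model &&
    a$chain == b$chain &&
    a$number == b$number &&
    toupper(a$insertion_code) == toupper(b$insertion_code)
  if (same && nzchar(a$symmetry_op) && nzchar(b$symmetry_op)) {
    same <- a$symmetry_op == b$symmetry_op
  }
  same
}

#' Inclusive residue range between two Unit IDs
#'
#' @param start,end `unit_id` objects sharing pdb, model and chain; `end`
#'   may equal `start` for a single-residue range.
#' @return An object of class `unit_range`.
#' @export
unit_range <- function(start, end = start) {
  stopifnot(inherits(start, "unit_id"), inherits(end, "unit_id"))
  if (start$pdb_id != end$pdb_id || start$model != end$model ||
      start$chain != end$chain) {
    msamap_abort("PARSE_ERROR", sprintf(
      "Range endpoints '%s' and '%s' must share pdb_id, model and chain.",
      format_unit_id(start), format_unit_id(end)
    ))
  }
  structure(list(start = start, end = end), class = "unit_range")
}

#' @export
format.unit_range <- function(x, ...) {
  if (query_equal(x$start, x$end)) {
    format_unit_id(x$start)
  } else {
    paste0(format_unit_id(x$start), ":", format_unit_id(x$end))
  }
}

#' @export
print.unit_range <- function(x, ...) {
  cat("<unit_range> ", format(x), "\n", sep = "")
  invisible(x)
}

#' Parse a `units=` range-query string
#'
#' The query grammar used in query URLs: comma-separated items, each either
#' a single Unit ID (a single-residue range) or two Unit IDs joined by a
#' colon denoting an inclusive range, e.g.
#' `"2AW7|1|A||1430:2AW7|1|A||1435,2AW7|1|A||1466:2AW7|1|A||1470"`.
#' Range order is preserved. A lone colon at the start or end of an item is
#' an error: only closed inclusive ranges exist.
#'
#' @param text the `units=` fragment.
#' @return A list of `unit_range` objects.
#' @export
parse_units_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) {
    msamap_abort("PARSE_ERROR", "Empty units string.")
  }
  items <- strsplit(text, ",", fixed = TRUE)[[1]]
  if (length(items) == 0) msamap_abort("PARSE_ERROR", "Empty units string.")
  lapply(items, function(item) {
    item <- trimws(item)
    if (!nzchar(item)) msamap_abort("PARSE_ERROR", "Empty range item in units string.")
    parts <- strsplit(item, ":", fixed = TRUE)[[1]]
    if (grepl("^:", item) || grepl(":$", item) || length(parts) > 2) {
      msamap_abort("PARSE_ERROR", sprintf(
        "Range item '%s' must be 'UNIT' or 'UNIT:UNIT'.", item
      ))
    }
    if (length(parts) == 1) {
      unit_range(parse_unit_id(parts[1]))
    } else {
      unit_range(parse_unit_id(parts[1]), parse_unit_id(parts[2]))
    }
  })
}

#' Serialize a list of unit ranges back to a `units=` string
#'
#' @param ranges list of `unit_range` objects.
#' @return A single string in the query grammar.
#' @export
format_units_string <- function(ranges) {
  paste(vapply(ranges, format, character(1)), collapse = ",")
}
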