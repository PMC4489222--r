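#' Read a gapped alignment from FASTA or Clustal
#'
#' Returns the alignment as a tibble with one row per sequence, columns
#' `seq_id` (first whitespace-delimited token of the record header) and
#' `seq` (the gapped row). Residues are uppercased; the gap characters
#' `.` and `~` are normalized to `-`. `T` is preserved as written —
#' comparisons elsewhere in the package treat `T` and `U` as equivalent.
#' Clustal conservation lines are ignored.
#'
#' @param path file to read.
#' @param format `"fasta"` or `"clustal"`; default guesses from the file
#'   extension (`.aln`/`.clustal` mean Clustal, anything else FASTA).
#' @return A tibble with columns `seq_id`, `seq`; all `seq` equal length.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "AC-G", ">s2", "ACUG"), f)
#' read_alignment(f)
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(aln|clustal|clu)$", path, ignore.case = TRUE)) "clustal" else "fasta"
  }
  if (!file.exists(path)) {
    msamap_abort("FORMAT_ERROR", sprintf("Alignment file not found: %s", path))
  }
  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readBStringSet(path),
      error = function(e) msamap_abort("FORMAT_ERROR", sprintf("Cannot read FASTA '%s': %s", path, conditionMessage(e)))
    )
    ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
    rows <- unname(as.character(set))
  } else {
    parsed <- read_clustal_lines(readLines(path), path)
    ids <- parsed$ids
    rows <- parsed$rows
  }
  if (length(ids) == 0) {
    msamap_abort("EMPTY_INPUT", sprintf("Alignment '%s' contains no sequences.", path))
  }
  aln <- tibble::tibble(seq_id = ids, seq = normalize_gaps(rows))
  validate_alignment(aln, path)
  aln
}

# Clustal parser: header line beginning CLUSTAL, then blocks of
# "<name><spaces><chunk>" lines; lines that are blank, start with a space,
# or consist of conservation symbols are skipped. Chunks for each name are
# concatenated across blocks in order of first appearance.
read_clustal_lines <- function(lines, path = "<clustal>") {
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1])) {
    msamap_abort("FORMAT_ERROR", sprintf("'%s' lacks a CLUSTAL header line.", path))
  }
  body <- lines[-1]
  keep <- nzchar(trimws(body)) & !grepl("^\\s", body)
  body <- body[keep]
  chunks <- list()
  for (line in body) {
    m <- regmatches(line, regexec("^(\\S+)\\s+(\\S+)", line))[[1]]
    if (length(m) != 3) {
      msamap_abort("FORMAT_ERROR", sprintf("Malformed Clustal line in '%s': '%s'", path, line))
    }
    nm <- m[2]
    # drop trailing cumulative residue counts some writers append
    chunk <- sub("\\s+\\d+$", "", m[3])
    chunks[[nm]] <- c(chunks[[nm]], chunk)
  }
  list(
    ids = names(chunks),
    rows = unname(vapply(chunks, paste, character(1), collapse = ""))
  )
}

normalize_gaps <- function(rows) {
  gsub("[.~]", "-", toupper(rows))
}

validate_alignment <- function(aln, path = "<alignment>") {
  widths <- nchar(aln$seq)
  if (length(unique(widths)) > 1) {
    bad <- aln$seq_id[widths != widths[1]][1]
    msamap_abort("FORMAT_ERROR", sprintf(
      "Ragged alignment '%s': row '%s' has length %d, expected %d.",
      path, bad, nchar(aln$seq[aln$seq_id == bad][1]), widths[1]
    ))
  }
  dup <- aln$seq_id[duplicated(aln$seq_id)]
  if (length(dup) > 0) {
    msamap_abort("DUPLICATE_ID", sprintf(
      "Duplicate sequence id(s) in '%s': %s", path, paste(unique(dup), collapse = ", ")
    ))
  }
  invisible(aln)
}

#' Write a gapped alignment to FASTA or Clustal
#'
#' The gap character on output is always `-`. Clustal output wraps rows in
#' 60-column blocks with a blank conservation line per block (so that
#' third-party Clustal readers that expect one are satisfied);
#' `read_alignment()` round-trips both formats losslessly.
#'
#' @param aln tibble with columns `seq_id`, `seq` (equal-length rows).
#' @param path output file.
#' @param format `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (nrow(aln) == 0) {
    msamap_abort("EMPTY_INPUT", "Refusing to write an empty alignment.")
  }
  aln <- dplyr::mutate(aln, seq = normalize_gaps(.data$seq))
  validate_alignment(aln, path)
  if (format == "fasta") {
    set <- Biostrings::BStringSet(stats::setNames(aln$seq, aln$seq_id))
    Biostrings::writeXStringSet(set, path, width = 60)
  } else {
    width <- 60L
    total <- nchar(aln$seq[1])
    namew <- max(nchar(aln$seq_id)) + 3L
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("CLUSTAL multiple sequence alignment", con)
    writeLines("", con)
    for (start in seq(1, total, by = width)) {
      end <- min(start + width - 1L, total)
      for (i in seq_len(nrow(aln))) {
        writeLines(sprintf(
          "%-*s%s", namew, aln$seq_id[i], substr(aln$seq[i], start, end)
        ), con)
      }
      writeLines(strrep(" ", namew + end - start + 1L), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' Read a per-sequence metadata table
#'
#' A TSV with a header naming (at least) `seq_id`; the conventional columns
#' are `seq_id`, `crw_id`, `accession`, `taxonomy_id`, `organism`,
#' `lineage`. Missing columns are added as empty strings and unknown extra
#' columns are ignored, so partial metadata joins cleanly against an
#' alignment later.
#'
#' @param path TSV file with a header row.
#' @return A tibble with the six metadata columns, one row per input row.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    msamap_abort("FORMAT_ERROR", sprintf("Metadata file not found: %s", path))
  }
  md <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!"seq_id" %in% names(md)) {
    msamap_abort("FORMAT_ERROR", sprintf("Metadata '%s' lacks a 'seq_id' column.", path))
  }
  wanted <- c("seq_id", "crw_id", "accession", "taxonomy_id", "organism", "lineage")
  for (col in setdiff(wanted, names(md))) md[[col]] <- ""
  md <- md[wanted]
  md[is.na(md)] <- ""
  md
}

#' Read (or synthesize) a residue-numbering table
#'
#' The numbering sidecar pairs each position of the ungapped structure
#' sequence (`polymer_index`, 1..N) with its author residue number and
#' optional insertion code — the addressing used in Unit IDs. Structures
#' numbered to match a homolog carry insertion-code runs such as
#' 190A..190L. When `path` is `NULL` a default table numbering residues
#' 1..N with no insertion codes is synthesized.
#'
#' @param path TSV with header columns `polymer_index`, `residue_number`,
#'   `insertion_code`, `identity`; or `NULL`.
#' @param n sequence length, required when `path` is `NULL`.
#' @return A tibble with those four columns, `polymer_index` exactly 1..N.
#' @export
read_numbering <- function(path = NULL, n = NULL) {
  if (is.null(path)) {
    stopifnot(!is.null(n))
    return(default_numbering(n))
  }
  if (!file.exists(path)) {
    msamap_abort("FORMAT_ERROR", sprintf("Numbering file not found: %s", path))
  }
  nt <- readr::read_tsv(path, col_types = readr::cols(
    polymer_index = readr::col_integer(),
    residue_number = readr::col_integer(),
    insertion_code = readr::col_character(),
    identity = readr::col_character()
  ), progress = FALSE)
  nt$insertion_code[is.na(nt$insertion_code)] <- ""
  nt$identity[is.na(nt$identity)] <- ""
  validate_numbering(nt, path)
}

#' @rdname read_numbering
#' @export
default_numbering <- function(n) {
  tibble::tibble(
    polymer_index = seq_len(n),
    residue_number = seq_len(n),
    insertion_code = "",
    identity = ""
  )
}

validate_numbering <- function(nt, path = "<numbering>") {
  if (!identical(nt$polymer_index, seq_len(nrow(nt)))) {
    msamap_abort("FORMAT_ERROR", sprintf(
      "Numbering '%s': polymer_index must be exactly 1..N in order.", path
    ))
  }
  key <- residue_key(nt$residue_number, nt$insertion_code)
  dup <- key[duplicated(key)]
  if (length(dup) > 0) {
    msamap_abort("DUPLICATE_RESIDUE_KEY", sprintf(
      "Numbering '%s': duplicate residue key(s): %s", path, paste(unique(dup), collapse = ", ")
    ))
  }
  nt
}

# canonical display/lookup key for (number, insertion code), e.g. "190", "190A"
residue_key <- function(number, insertion_code) {
  paste0(number, toupper(ifelse(is.na(insertion_code), "", insertion_code)))
}
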