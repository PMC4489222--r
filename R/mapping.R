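#' Construct a lookup alignment
#'
#' A lookup alignment is the pairwise gapped alignment of the
#' structure-derived sequence (`pdb_row`) against its closest reference
#' ("lookup") sequence, plus the numbering sidecar for the structure
#' sequence. It is the first half of the two-step coordinate map: it
#' carries author-numbered structure residues onto the natural (ungapped,
#' 1-based) numbering of the lookup sequence. Residues present only in the
#' structure — e.g. an engineered crystallization insert — sit over gaps in
#' the lookup row and are unmappable.
#'
#' @param aln two-row alignment tibble (`seq_id`, `seq`) as returned by
#'   [read_alignment()]: first row the structure sequence, second the
#'   lookup sequence — or pass `pdb_row`/`lookup_row` explicitly.
#' @param numbering numbering table for the structure sequence
#'   ([read_numbering()]); defaults to sequential 1..N.
#' @param pdb_row,lookup_row gapped rows (named alternative to `aln`).
#' @param pdb_id,lookup_id sequence identifiers.
#' @return An object of class `lookup_aln`.
#' @export
lookup_alignment <- function(aln = NULL, numbering = NULL,
                             pdb_row = NULL, lookup_row = NULL,
                             pdb_id = "structure", lookup_id = "lookup") {
  if (!is.null(aln)) {
    if (nrow(aln) != 2) {
      msamap_abort("INVALID_ALIGNMENT", sprintf(
        "A lookup alignment must have exactly 2 rows, got %d.", nrow(aln)
      ))
    }
    pdb_id <- aln$seq_id[1]
    lookup_id <- aln$seq_id[2]
    pdb_row <- aln$seq[1]
    lookup_row <- aln$seq[2]
  }
  pdb_row <- normalize_gaps(pdb_row)
  lookup_row <- normalize_gaps(lookup_row)
  if (nchar(pdb_row) != nchar(lookup_row)) {
    msamap_abort("INVALID_ALIGNMENT", "Lookup alignment rows differ in length.")
  }
  p <- strsplit(pdb_row, "")[[1]]
  l <- strsplit(lookup_row, "")[[1]]
  if (any(p == "-" & l == "-")) {
    msamap_abort("INVALID_ALIGNMENT", sprintf(
      "All-gap column at position %d of the lookup alignment.",
      which(p == "-" & l == "-")[1]
    ))
  }
  n_res <- sum(p != "-")
  if (is.null(numbering)) numbering <- default_numbering(n_res)
  if (nrow(numbering) != n_res) {
    msamap_abort("INVALID_ALIGNMENT", sprintf(
      "Numbering table has %d rows but the structure row has %d residues.",
      nrow(numbering), n_res
    ))
  }
  structure(
    list(
      pdb_id = pdb_id, lookup_id = lookup_id,
      pdb_row = pdb_row, lookup_row = lookup_row,
      numbering = validate_numbering(numbering)
    ),
    class = "lookup_aln"
  )
}

#' @export
print.lookup_aln <- function(x, ...) {
  cat("<lookup_aln> ", x$pdb_id, " vs ", x$lookup_id,
      " (", nchar(x$pdb_row), " columns, ",
      nrow(x$numbering), " structure residues)\n", sep = "")
  invisible(x)
}

#' Map structure residues to natural positions of the lookup sequence
#'
#' Scans the lookup alignment column by column. At each column where the
#' structure row has a residue: if the lookup row also has a residue, the
#' structure residue maps to the lookup sequence's running natural
#' position; if the lookup row is gapped there, the residue is unmappable
#' (`NA`) — it has no equivalent in the reference, so it can never serve
#' as a query endpoint.
#'
#' @param la a `lookup_aln`.
#' @return Integer vector over polymer indices 1..N; `NA` marks
#'   unmappable residues. Defined values are strictly increasing.
#' @export
build_residue_map <- function(la) {
  stopifnot(inherits(la, "lookup_aln"))
  p <- strsplit(la$pdb_row, "")[[1]]
  l <- strsplit(la$lookup_row, "")[[1]]
  natural <- cumsum(l != "-")
  map <- ifelse(l != "-", natural, NA_integer_)[p != "-"]
  as.integer(map)
}

#' Map natural positions of the lookup sequence to alignment columns
#'
#' The k-th non-gap character of the lookup sequence's row in the data
#' alignment defines the column of natural position k.
#'
#' @param msa alignment tibble (`seq_id`, `seq`).
#' @param lookup_id id of the lookup sequence's row.
#' @return Integer vector of columns over natural positions 1..L,
#'   strictly increasing.
#' @export
build_column_map <- function(msa, lookup_id) {
  row <- msa$seq[msa$seq_id == lookup_id]
  if (length(row) != 1) {
    msamap_abort("LOOKUP_NOT_FOUND", sprintf(
      "Lookup sequence '%s' not found in the data alignment.", lookup_id
    ))
  }
  chars <- strsplit(normalize_gaps(row), "")[[1]]
  which(chars != "-")
}

# T and U are interchangeable (GenBank rRNA entries are DNA-alphabet);
# comparisons are case-insensitive.
normalize_seq <- function(x) {
  gsub("T", "U", toupper(x), fixed = TRUE)
}

#' Check that the lookup sequence agrees between the two alignments
#'
#' The ungapped lookup sequence from the lookup alignment must occur
#' exactly once as a substring of the ungapped lookup row of the data
#' alignment (T and U equivalent, case-insensitive). The data copy may be
#' longer at either end — e.g. extra 3' sequence — which has no effect on
#' column mapping; the match offset is returned so natural positions can
#' be shifted accordingly.
#'
#' @param la a `lookup_aln`.
#' @param msa data alignment tibble.
#' @return Integer offset (0 when the sequences start together),
#'   invisibly usable as the shift from lookup-alignment natural
#'   positions to data-alignment natural positions.
#' @export
check_consistency <- function(la, msa) {
  stopifnot(inherits(la, "lookup_aln"))
  from_la <- normalize_seq(gsub("-", "", la$lookup_row, fixed = TRUE))
  row <- msa$seq[msa$seq_id == la$lookup_id]
  if (length(row) != 1) {
    msamap_abort("LOOKUP_NOT_FOUND", sprintf(
      "Lookup sequence '%s' not found in the data alignment.", la$lookup_id
    ))
  }
  from_msa <- normalize_seq(gsub("-", "", normalize_gaps(row), fixed = TRUE))
  hits <- gregexpr(from_la, from_msa, fixed = TRUE)[[1]]
  if (identical(as.integer(hits), -1L)) {
    # report the first differing natural position when aligned at offset 0
    a <- strsplit(from_la, "")[[1]]
    b <- strsplit(from_msa, "")[[1]]
    k <- min(length(a), length(b))
    diff <- which(a[seq_len(k)] != b[seq_len(k)])
    pos <- if (length(diff) > 0) diff[1] else k + 1L
    msamap_abort("LOOKUP_MISMATCH", sprintf(
      "Lookup sequence disagrees between alignments (first difference at natural position %d).",
      pos
    ))
  }
  if (length(hits) > 1) {
    msamap_abort("LOOKUP_MISMATCH", sprintf(
      "Lookup sequence matches the data copy at %d offsets; cannot anchor natural numbering.",
      length(hits)
    ))
  }
  invisible(as.integer(hits[1]) - 1L)
}

#' Resolve a residue key through both coordinate maps
#'
#' Composes the residue map and column map: the author residue address
#' (number plus optional insertion code) is looked up in the numbering
#' table, carried to a natural position of the lookup sequence, then to a
#' data-alignment column. `NA` (an unmappable residue) propagates.
#'
#' @param number author residue number.
#' @param insertion_code insertion code, `""` for none.
#' @param numbering numbering table.
#' @param rm residue map from [build_residue_map()].
#' @param cm column map from [build_column_map()].
#' @param offset natural-position offset from [check_consistency()].
#' @return Column index, or `NA` if the residue is unmappable.
#' @export
residue_to_column <- function(number, insertion_code = "", numbering, rm, cm,
                              offset = 0L) {
  idx <- polymer_index_of(number, insertion_code, numbering)
  nat <- rm[idx]
  if (is.na(nat)) return(NA_integer_)
  cm[nat + offset]
}

polymer_index_of <- function(number, insertion_code, numbering) {
  key <- residue_key(number, insertion_code)
  keys <- residue_key(numbering$residue_number, numbering$insertion_code)
  idx <- match(key, keys)
  if (is.na(idx)) {
    msamap_abort("UNKNOWN_RESIDUE", sprintf(
      "Residue %s is not present in the structure's numbering table.", key
    ))
  }
  numbering$polymer_index[idx]
}
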