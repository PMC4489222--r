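#' Summarize distinct sequence variants
#'
#' Groups the per-sequence display strings (gapped extracts, ranges joined
#' by `", "`) into distinct variants with occurrence counts and the
#' percentage of all alignment sequences each represents. Percentages are
#' computed at full precision and rendered to two decimals; counts always
#' sum to the number of sequences. Rows are ordered by count descending,
#' then variant ascending, so output is deterministic.
#'
#' @param es extract tibble from [extract_columns()].
#' @return A tibble with columns `variant`, `count`, `percent`.
#' @export
summarize_variants <- function(es) {
  if (nrow(es) == 0) msamap_abort("EMPTY_INPUT", "No extracts to summarize.")
  n <- nrow(es)
  es |>
    dplyr::count(variant = .data$display, name = "count") |>
    dplyr::mutate(percent = round(100 * .data$count / n, 2)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$variant)
}

#' Structure letters per range, from the mapped residues only
#'
#' The reference sequence shown in green highlighting is the structure's
#' own residues; unmappable residues (engineered inserts) have no
#' alignment columns, so they are excluded — a range bridging an insert
#' compares only its biological flanks.
#'
#' @param q a validated `range_query`.
#' @param la the `lookup_aln`.
#' @param rm residue map.
#' @return Character vector, one gap-free string per range.
#' @export
structure_letters <- function(q, la, rm) {
  res <- strsplit(gsub("-", "", la$pdb_row, fixed = TRUE), "")[[1]]
  vapply(seq_len(nrow(q$ranges)), function(i) {
    idx <- seq(q$ranges$start_pi[i], q$ranges$end_pi[i])
    paste(res[idx[!is.na(rm[idx])]], collapse = "")
  }, character(1))
}

# per-range comparison of a gap-stripped extract against the structure
# letters; T and U equivalent, case-insensitive
matches_structure_flag <- function(extracts, struct_letters) {
  vapply(extracts, function(ex) {
    stripped <- normalize_seq(gsub("-", "", ex, fixed = TRUE))
    all(stripped == normalize_seq(struct_letters))
  }, logical(1))
}

#' Flag extract rows for display highlighting
#'
#' `matches_structure` (green) marks sequences whose gap-stripped extract
#' equals the structure's own residues in every range; `is_lookup` (blue)
#' marks the lookup sequence used to anchor the mapping.
#'
#' @param es extract tibble from [extract_columns()].
#' @param struct_letters per-range structure letters from
#'   [structure_letters()].
#' @param lookup_id id of the lookup sequence.
#' @return `es` with logical columns `matches_structure`, `is_lookup`.
#' @export
flag_rows <- function(es, struct_letters, lookup_id) {
  dplyr::mutate(
    es,
    matches_structure = matches_structure_flag(.data$extracts, struct_letters),
    is_lookup = .data$seq_id == lookup_id
  )
}

#' Filter report rows by a literal substring
#'
#' Retains rows where any character column contains `pattern` as a
#' literal, case-insensitive substring. Gaps count as characters, so the
#' pattern `"ACGU"` matches only contiguous `ACGU` and excludes
#' `"AC-GU"`; in a details table the pattern also matches organism or
#' lineage fields. Filtering is display-level: it never changes the
#' summary's counts.
#'
#' @param rows a tibble (summary or details rows).
#' @param pattern non-empty literal pattern.
#' @return The matching rows.
#' @export
filter_rows <- function(rows, pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1, nzchar(pattern))
  chr_cols <- names(rows)[vapply(rows, is.character, logical(1))]
  # literal, case-insensitive: uppercase both sides and use a fixed match
  hit <- Reduce(`|`, lapply(chr_cols, function(col) {
    stringr::str_detect(
      stringr::str_to_upper(rows[[col]]),
      stringr::fixed(stringr::str_to_upper(pattern))
    )
  }), init = rep(FALSE, nrow(rows)))
  rows[hit, , drop = FALSE]
}

#' Run a range query end to end
#'
#' The full pipeline: parse and validate the `units=` string, build the
#' residue and column maps, check lookup-sequence consistency between the
#' two alignments, resolve ranges to column intervals, extract every
#' sequence's column blocks, aggregate the variant summary, and join
#' per-sequence metadata into the details table.
#'
#' @param units a `units=` query string or list of `unit_range`.
#' @param data_aln data alignment tibble ([read_alignment()]).
#' @param lookup a `lookup_aln` ([lookup_alignment()]).
#' @param metadata optional metadata tibble ([read_metadata()]).
#' @param max_ranges,max_span query limits (defaults 5 and 50).
#' @param alignment_id label echoed into serialized output.
#' @return An object of class `variant_report` with components `units`,
#'   `alignment_id`, `limits`, `ranges`, `summary`, `details`,
#'   `extracts`, `n_sequences`.
#' @examples
#' fx <- make_fixture(n = 6, length = 40, seed = 1)
#' rep <- msa_query("STRU|1|A||5:STRU|1|A||10", fx$data_aln, fx$lookup)
#' rep$summary
#' @export
msa_query <- function(units, data_aln, lookup, metadata = NULL,
                      max_ranges = 5L, max_span = 50L, alignment_id = "") {
  validate_alignment(data_aln)
  rm <- build_residue_map(lookup)
  offset <- check_consistency(lookup, data_aln)
  cm <- build_column_map(data_aln, lookup$lookup_id)
  q <- validate_query(units, lookup, rm, max_ranges = max_ranges, max_span = max_span)
  q <- resolve_columns(q, rm, cm, offset = offset)
  es <- extract_columns(q, data_aln)
  sl <- structure_letters(q, lookup, rm)
  es <- flag_rows(es, sl, lookup$lookup_id)
  summary <- summarize_variants(es)
  summary$matches_structure <- matches_structure_flag(
    lapply(summary$variant, function(v) strsplit(v, ", ", fixed = TRUE)[[1]]), sl
  )
  details <- build_details(es, metadata)
  structure(
    list(
      units = q$units,
      alignment_id = alignment_id,
      limits = q$limits,
      ranges = q$ranges,
      structure_letters = sl,
      lookup_id = lookup$lookup_id,
      summary = summary,
      details = details,
      extracts = es,
      n_sequences = nrow(data_aln)
    ),
    class = "variant_report"
  )
}

build_details <- function(es, metadata) {
  details <- tibble::tibble(
    seq_id = es$seq_id,
    crw_id = es$seq_id,
    variant = es$display,
    accession = "",
    taxonomy_id = "",
    organism = "",
    lineage = "",
    matches_structure = es$matches_structure,
    is_lookup = es$is_lookup
  )
  if (!is.null(metadata)) {
    md <- dplyr::rename(metadata, md_crw_id = "crw_id")
    details <- details |>
      dplyr::select(-"accession", -"taxonomy_id", -"organism", -"lineage") |>
      dplyr::left_join(md, by = "seq_id") |>
      dplyr::mutate(
        crw_id = dplyr::if_else(
          !is.na(.data$md_crw_id) & nzchar(.data$md_crw_id),
          .data$md_crw_id, .data$crw_id
        )
      ) |>
      dplyr::select(-"md_crw_id")
    for (col in c("accession", "taxonomy_id", "organism", "lineage")) {
      details[[col]][is.na(details[[col]])] <- ""
    }
    details <- details[, c(
      "seq_id", "crw_id", "variant", "accession", "taxonomy_id",
      "organism", "lineage", "matches_structure", "is_lookup"
    )]
  }
  details
}

#' @export
print.variant_report <- function(x, ...) {
  cat("<variant_report> query: ", x$units, "\n", sep = "")
  cat(x$n_sequences, " sequences, ", nrow(x$summary), " distinct variants over ",
      nrow(x$ranges), " range(s)\n", sep = "")
  print(x$summary, n = 10)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a variant report into its details table
#'
#' @param x a `variant_report`.
#' @param ... unused.
#' @return The details tibble: one row per alignment sequence with its
#'   extract and metadata.
#' @export
tidy.variant_report <- function(x, ...) x$details

#' One-row summary of a variant report
#'
#' @param x a `variant_report`.
#' @param ... unused.
#' @return A one-row tibble: numbers of sequences, variants and ranges,
#'   total extract width, and the top variant with its percentage.
#' @export
glance.variant_report <- function(x, ...) {
  tibble::tibble(
    n_sequences = x$n_sequences,
    n_variants = nrow(x$summary),
    n_ranges = nrow(x$ranges),
    total_width = sum(x$ranges$width),
    top_variant = x$summary$variant[1],
    top_percent = x$summary$percent[1]
  )
}

#' Plot the variant-frequency spectrum of a report
#'
#' A horizontal bar chart of the distinct variants' percentages, the
#' variant matching the 3D structure's own sequence highlighted.
#'
#' @param object a `variant_report`.
#' @param top_n show at most this many variants (default 20).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.variant_report <- function(object, top_n = 20, ...) {
  df <- utils::head(object$summary, top_n)
  df$variant <- factor(df$variant, levels = rev(df$variant))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$percent, y = .data$variant, fill = .data$matches_structure
  )) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#2e7d32", `FALSE` = "grey55"),
      name = "matches 3D structure"
    ) +
    ggplot2::labs(
      x = "% of sequences", y = NULL,
      title = "Distinct sequence variants",
      subtitle = object$units
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Serialize a variant report
#'
#' * `json` — the full result: query echo (units string, limits,
#'   alignment id, resolved ranges), the variant summary and the complete
#'   details table, unpaginated.
#' * `tsv` — the details table, one row per sequence plus a header.
#' * `fasta` / `clustal` — the extracted sub-alignment; per-range blocks
#'   are concatenated (those formats cannot carry a separator), sequence
#'   ids preserved.
#'
#' @param report a `variant_report`.
#' @param path output file.
#' @param format one of `"json"`, `"tsv"`, `"fasta"`, `"clustal"`.
#' @return `path`, invisibly.
#' @export
serialize_report <- function(report, path, format = c("json", "tsv", "fasta", "clustal")) {
  stopifnot(inherits(report, "variant_report"))
  format <- tryCatch(match.arg(format), error = function(e) {
    msamap_abort("USAGE_ERROR", sprintf("Unknown output format '%s'.", format[1]))
  })
  if (format == "json") {
    payload <- list(
      schema_version = "1.0",
      query = list(
        units = report$units,
        alignment_id = report$alignment_id,
        limits = report$limits,
        ranges = report$ranges
      ),
      n_sequences = report$n_sequences,
      summary = report$summary,
      details = report$details
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (format == "tsv") {
    readr::write_tsv(report$details, path, progress = FALSE)
  } else {
    sub <- tibble::tibble(
      seq_id = report$extracts$seq_id,
      seq = vapply(report$extracts$extracts, paste, character(1), collapse = "")
    )
    write_alignment(sub, path, format = format)
  }
  invisible(path)
}
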