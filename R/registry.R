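#' Load a registry of structure-to-alignment mappings
#'
#' The registry enumerates which structures, models and chains give access
#' to which data alignment, and where the four input files live: data
#' alignment, lookup alignment, numbering sidecar and metadata table. It
#' is a YAML file with a top-level `entries` list; relative paths are
#' resolved against the registry file's directory.
#'
#' ```yaml
#' entries:
#'   - pdb_id: STRA
#'     model: 1
#'     chain: A
#'     molecule: SSU rRNA
#'     alignment_id: ssu
#'     data_alignment: ssu_data.fasta
#'     lookup_alignment: STRA_ssu_lookup.fasta
#'     numbering: STRA_numbering.tsv
#'     metadata: ssu_metadata.tsv
#' ```
#'
#' @param path registry YAML file.
#' @param check_files verify that every referenced file exists.
#' @return A tibble of registry entries with absolute paths.
#' @export
load_registry <- function(path, check_files = TRUE) {
  if (!file.exists(path)) {
    msamap_abort("CONFIG_ERROR", sprintf("Registry file not found: %s", path))
  }
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e) {
    msamap_abort("CONFIG_ERROR", sprintf("Cannot parse registry '%s': %s", path, conditionMessage(e)))
  })
  entries <- cfg$entries
  if (is.null(entries)) entries <- list()
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || !nzchar(p)) return("")
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  reg <- dplyr::bind_rows(lapply(entries, function(e) {
    for (f in c("pdb_id", "chain", "alignment_id", "data_alignment", "lookup_alignment")) {
      if (is.null(e[[f]])) {
        msamap_abort("CONFIG_ERROR", sprintf("Registry entry missing field '%s'.", f))
      }
    }
    tibble::tibble(
      pdb_id = e$pdb_id,
      model = as.integer(e$model %||% 1L),
      chain = e$chain,
      molecule = e$molecule %||% "",
      alignment_id = e$alignment_id,
      data_alignment = resolve(e$data_alignment),
      lookup_alignment = resolve(e$lookup_alignment),
      numbering = resolve(e$numbering),
      metadata = resolve(e$metadata)
    )
  }))
  if (nrow(reg) == 0) {
    reg <- tibble::tibble(
      pdb_id = character(), model = integer(), chain = character(),
      molecule = character(), alignment_id = character(),
      data_alignment = character(), lookup_alignment = character(),
      numbering = character(), metadata = character()
    )
  }
  if (nrow(reg) > 0) {
    key <- paste(reg$pdb_id, reg$model, reg$chain, reg$alignment_id)
    if (anyDuplicated(key)) {
      msamap_abort("CONFIG_ERROR", sprintf(
        "Duplicate registry entry for %s.", key[duplicated(key)][1]
      ))
    }
    if (check_files) {
      paths <- c(reg$data_alignment, reg$lookup_alignment,
                 reg$numbering[nzchar(reg$numbering)], reg$metadata[nzchar(reg$metadata)])
      missing <- paths[!file.exists(paths)]
      if (length(missing) > 0) {
        msamap_abort("CONFIG_ERROR", sprintf(
          "Registry references missing file(s): %s", paste(missing, collapse = ", ")
        ))
      }
    }
  }
  reg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the alignment entry for a structure chain
#'
#' If exactly one alignment is registered for the chain it is selected
#' automatically (the usual case for SSU rRNA); if several are — an LSU
#' chain typically has both the long LSU and the 5S alignment — the
#' caller must name one via `alignment_id`.
#'
#' @param reg registry tibble from [load_registry()].
#' @param pdb_id structure identifier.
#' @param chain chain identifier (optional when unambiguous).
#' @param model model number (default 1).
#' @param alignment_id explicit alignment choice.
#' @return The single matching registry row.
#' @export
select_alignment <- function(reg, pdb_id, chain = NULL, model = 1L,
                             alignment_id = NULL) {
  hits <- reg[reg$pdb_id == pdb_id & reg$model == model, , drop = FALSE]
  if (!is.null(chain)) hits <- hits[hits$chain == chain, , drop = FALSE]
  if (nrow(hits) == 0) {
    msamap_abort("UNKNOWN_STRUCTURE", sprintf(
      "No registry entry for structure '%s'%s.", pdb_id,
      if (is.null(chain)) "" else sprintf(" chain '%s'", chain)
    ))
  }
  if (!is.null(alignment_id)) {
    hits <- hits[hits$alignment_id == alignment_id, , drop = FALSE]
    if (nrow(hits) == 0) {
      msamap_abort("UNKNOWN_STRUCTURE", sprintf(
        "Structure '%s' has no alignment '%s'.", pdb_id, alignment_id
      ))
    }
  }
  if (nrow(hits) > 1) {
    msamap_abort("AMBIGUOUS_ALIGNMENT", sprintf(
      "Structure '%s' maps to %d alignments (%s); select one with alignment_id.",
      pdb_id, nrow(hits), paste(hits$alignment_id, collapse = ", ")
    ))
  }
  hits
}

#' Run a units query against a registry
#'
#' Parses the `units=` string, selects the registry entry for the query's
#' structure (all ranges must address one structure/model/chain), loads
#' the four input files and runs [msa_query()].
#'
#' @param reg registry tibble.
#' @param units `units=` query string.
#' @param alignment_id explicit alignment choice when the chain has more
#'   than one.
#' @param max_ranges,max_span query limits.
#' @return A `variant_report`.
#' @export
registry_query <- function(reg, units, alignment_id = NULL,
                           max_ranges = 5L, max_span = 50L) {
  ranges <- parse_units_string(units)
  first <- ranges[[1]]$start
  for (r in ranges) {
    for (u in list(r$start, r$end)) {
      if (u$pdb_id != first$pdb_id || u$model != first$model || u$chain != first$chain) {
        msamap_abort("PARSE_ERROR", "All ranges in one query must address the same structure, model and chain.")
      }
    }
  }
  entry <- select_alignment(reg, first$pdb_id, first$chain, first$model, alignment_id)
  data_aln <- read_alignment(entry$data_alignment)
  lk_aln <- read_alignment(entry$lookup_alignment)
  numbering <- if (nzchar(entry$numbering)) {
    read_numbering(entry$numbering)
  } else {
    default_numbering(sum(strsplit(normalize_gaps(lk_aln$seq[1]), "")[[1]] != "-"))
  }
  lookup <- lookup_alignment(lk_aln, numbering = numbering)
  metadata <- if (nzchar(entry$metadata)) read_metadata(entry$metadata) else NULL
  msa_query(ranges, data_aln, lookup, metadata = metadata,
            max_ranges = max_ranges, max_span = max_span,
            alignment_id = entry$alignment_id)
}

#' Write a miniature fixture registry to a directory
#'
#' Generates two synthetic structures with fixtures: one chain with a
#' single alignment (auto-selected) and one chain registered against two
#' alignments (requires explicit selection), writes every input file plus
#' `registry.yaml`, and returns the registry path.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return Path of the written `registry.yaml`.
#' @export
make_fixture_registry <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  specs <- list(
    list(pdb = "STRA", aln_id = "ssu", molecule = "SSU rRNA", seed = seed),
    list(pdb = "STRB", aln_id = "lsu", molecule = "LSU rRNA", seed = seed + 10L),
    list(pdb = "STRB", aln_id = "s5", molecule = "5S rRNA", seed = seed + 20L)
  )
  for (sp in specs) {
    fx <- make_fixture(n = 12, length = 80, seed = sp$seed,
                       insert_len = 4, missing_len = 3, with_metadata = TRUE)
    fx$lookup$pdb_id <- sp$pdb
    stem <- paste0(sp$pdb, "_", sp$aln_id)
    write_alignment(fx$data_aln, file.path(dir, paste0(stem, "_data.fasta")))
    write_alignment(
      tibble::tibble(
        seq_id = c(sp$pdb, fx$lookup$lookup_id),
        seq = c(fx$lookup$pdb_row, fx$lookup$lookup_row)
      ),
      file.path(dir, paste0(stem, "_lookup.fasta"))
    )
    readr::write_tsv(fx$lookup$numbering, file.path(dir, paste0(stem, "_numbering.tsv")),
                     progress = FALSE)
    readr::write_tsv(fx$metadata, file.path(dir, paste0(stem, "_metadata.tsv")),
                     progress = FALSE)
    entries[[length(entries) + 1]] <- list(
      pdb_id = sp$pdb, model = 1L, chain = "A", molecule = sp$molecule,
      alignment_id = sp$aln_id,
      data_alignment = paste0(stem, "_data.fasta"),
      lookup_alignment = paste0(stem, "_lookup.fasta"),
      numbering = paste0(stem, "_numbering.tsv"),
      metadata = paste0(stem, "_metadata.tsv")
    )
  }
  reg_path <- file.path(dir, "registry.yaml")
  yaml::write_yaml(list(entries = entries), reg_path)
  reg_path
}
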