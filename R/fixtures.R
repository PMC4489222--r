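# Synthetic alignment fixtures with exact ground-truth homology.
#
# Indels are simulated at the alignment level: every insertion or deletion
# is recorded as columns while the alignment is built, so the true
# natural-position -> column homology is exact by construction rather than
# inferred afterwards.

with_seed_local <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a data alignment with known column homology
#'
#' An ancestor sequence of the requested length is the lookup sequence;
#' every other sequence derives from it by independent substitutions and
#' indels. Deletions gap an ancestor position in one sequence; insertions
#' open new columns (1–3 residues) after an ancestor position, gapped in
#' every other sequence — so the lookup row is gapped exactly at insert
#' columns and the true column of each natural position is known.
#'
#' @param n number of sequences including the lookup (>= 2).
#' @param length ungapped ancestor length.
#' @param sub_rate per-position substitution probability in `[0, 1)`.
#' @param indel_rate per-position indel probability in `[0, 1)`, split
#'   evenly between deletions and insertions.
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param alphabet residue alphabet (default RNA `ACGU`).
#' @param lookup_id sequence id given to the lookup row.
#' @return A list: `aln` (tibble `seq_id`, `seq`), `lookup_id`,
#'   `lookup_seq` (ungapped ancestor), and `truth_columns` — a tibble
#'   `(natural_position, column)` giving the true data-alignment column
#'   of every natural position of the lookup sequence.
#' @export
simulate_data_alignment <- function(n, length, sub_rate = 0.05,
                                    indel_rate = 0.02, seed = 1,
                                    alphabet = c("A", "C", "G", "U"),
                                    lookup_id = "lookup") {
  if (n < 2 || length < 1 || sub_rate < 0 || sub_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1) {
    msamap_abort("USAGE_ERROR", "Need n >= 2, length >= 1 and rates in [0, 1).")
  }
  with_seed_local(seed, {
    L <- as.integer(length)
    ancestor <- sample(alphabet, L, replace = TRUE)
    ids <- c(lookup_id, sprintf("seq%03d", seq_len(n - 1)))
    # residue at each ancestor position ("-" = deleted), per sequence
    residues <- matrix("", nrow = n, ncol = L)
    residues[1, ] <- ancestor
    # insertions keyed by slot s (after ancestor position s, 0..L)
    inserts <- replicate(n, vector("list", L + 1L), simplify = FALSE)
    for (i in 2:n) {
      row <- ancestor
      sub_at <- stats::runif(L) < sub_rate
      row[sub_at] <- vapply(row[sub_at], function(ch) {
        sample(setdiff(alphabet, ch), 1)
      }, character(1))
      del_at <- stats::runif(L) < indel_rate / 2
      row[del_at] <- "-"
      residues[i, ] <- row
      ins_at <- which(stats::runif(L) < indel_rate / 2)
      for (s in ins_at) {
        k <- sample(1:3, 1)
        inserts[[i]][[s + 1L]] <- sample(alphabet, k, replace = TRUE)
      }
    }
    slot_width <- vapply(seq_len(L + 1L), function(s) {
      max(c(0L, vapply(inserts, function(x) base::length(x[[s]]), integer(1))))
    }, integer(1))
    rows <- vapply(seq_len(n), function(i) {
      # interleave: slot 0 inserts, pos 1, slot 1 inserts, pos 2, ...
      out <- character(0)
      for (p in 0:L) {
        s <- p + 1L
        if (p > 0) out <- c(out, residues[i, p])
        if (slot_width[s] > 0) {
          ins <- inserts[[i]][[s]]
          out <- c(out, paste0(
            paste(ins, collapse = ""),
            strrep("-", slot_width[s] - base::length(ins))
          ))
        }
      }
      paste(out, collapse = "")
    }, character(1))
    # true column of ancestor (= natural) position p
    cum_ins <- cumsum(slot_width)  # slots 0..L -> index s = p + 1
    truth <- tibble::tibble(
      natural_position = seq_len(L),
      column = seq_len(L) + cum_ins[seq_len(L)]
    )
    list(
      aln = tibble::tibble(seq_id = ids, seq = rows),
      lookup_id = lookup_id,
      lookup_seq = paste(ancestor, collapse = ""),
      truth_columns = truth,
      params = list(n = n, length = L, sub_rate = sub_rate,
                    indel_rate = indel_rate, seed = seed)
    )
  })
}

#' Build a structure variant of a lookup sequence, with truth table
#'
#' Emulates a 3D-structure chain aligned to its reference: the structure
#' sequence equals the lookup sequence except that the residues of
#' `missing_span` are absent (disordered or unresolved), and the residues
#' of `insert_span` are replaced by an engineered insert (for example a
#' crystallization hairpin). In the resulting pairwise alignment, replaced
#' and missing lookup residues sit over gaps in the structure row and the
#' insert sits over gaps in the lookup row; insert residues are therefore
#' unmappable.
#'
#' @param lookup_seq ungapped lookup sequence (string).
#' @param insert_span `c(first, last)` lookup positions replaced by the
#'   insert, or `NULL` for none.
#' @param insert_seq insert as a string, or an integer length to draw
#'   randomly; `NULL`/empty for none.
#' @param missing_span `c(first, last)` lookup positions absent from the
#'   structure, or `NULL`. Must not overlap `insert_span`.
#' @param seed used when `insert_seq` is given as a length.
#' @param numbering_style `"sequential"` numbers structure residues 1..N;
#'   `"insertion_codes"` numbers the biological residues sequentially and
#'   gives insert residues the preceding residue's number with insertion
#'   codes A, B, C, ... (the homolog-matched numbering convention).
#' @param pdb_id,lookup_id sequence ids for the two rows.
#' @return A list: `lookup` (a `lookup_aln`), and `truth` — a tibble
#'   `(polymer_index, residue_number, insertion_code, key,
#'   natural_position)` with `NA` natural position for insert residues.
#' @export
make_structure_variant <- function(lookup_seq, insert_span = NULL,
                                   insert_seq = NULL, missing_span = NULL,
                                   seed = 1,
                                   numbering_style = c("sequential", "insertion_codes"),
                                   pdb_id = "STRU", lookup_id = "lookup") {
  numbering_style <- match.arg(numbering_style)
  L <- nchar(lookup_seq)
  lchars <- strsplit(toupper(lookup_seq), "")[[1]]
  check_span <- function(span, nm) {
    if (is.null(span)) return(integer(0))
    if (base::length(span) != 2 || span[1] > span[2] || span[1] < 1 || span[2] > L) {
      msamap_abort("USAGE_ERROR", sprintf("Invalid %s.", nm))
    }
    seq(span[1], span[2])
  }
  ins_pos <- check_span(insert_span, "insert_span")
  mis_pos <- check_span(missing_span, "missing_span")
  if (base::length(intersect(ins_pos, mis_pos)) > 0) {
    msamap_abort("USAGE_ERROR", "insert_span and missing_span must be disjoint.")
  }
  if (is.numeric(insert_seq) && base::length(insert_seq) == 1) {
    insert_seq <- with_seed_local(seed, paste(
      sample(c("A", "C", "G", "U"), insert_seq, replace = TRUE), collapse = ""
    ))
  }
  ichars <- if (is.null(insert_seq) || !nzchar(insert_seq)) character(0) else strsplit(toupper(insert_seq), "")[[1]]
  if (base::length(ichars) > 0 && base::length(ins_pos) == 0) {
    msamap_abort("USAGE_ERROR", "insert_seq given without insert_span.")
  }

  pdb <- character(0)
  lkp <- character(0)
  nat_of_residue <- integer(0)  # per structure residue, NA for inserts
  for (p in seq_len(L)) {
    if (p %in% mis_pos || p %in% ins_pos) {
      pdb <- c(pdb, "-")
      lkp <- c(lkp, lchars[p])
    } else {
      pdb <- c(pdb, lchars[p])
      lkp <- c(lkp, lchars[p])
      nat_of_residue <- c(nat_of_residue, p)
    }
    if (base::length(ins_pos) > 0 && p == max(ins_pos) && base::length(ichars) > 0) {
      pdb <- c(pdb, ichars)
      lkp <- c(lkp, rep("-", base::length(ichars)))
      nat_of_residue <- c(nat_of_residue, rep(NA_integer_, base::length(ichars)))
    }
  }
  # nat_of_residue was accumulated in column order of structure residues
  pdb_row <- paste(pdb, collapse = "")
  lookup_row <- paste(lkp, collapse = "")
  n_res <- sum(pdb != "-")
  is_insert <- is.na(nat_of_residue)

  if (numbering_style == "sequential") {
    numbering <- tibble::tibble(
      polymer_index = seq_len(n_res),
      residue_number = seq_len(n_res),
      insertion_code = "",
      identity = pdb[pdb != "-"]
    )
  } else {
    num <- integer(n_res)
    code <- character(n_res)
    counter <- 0L
    run <- 0L
    for (i in seq_len(n_res)) {
      if (!is_insert[i]) {
        counter <- counter + 1L
        run <- 0L
        num[i] <- counter
        code[i] <- ""
      } else {
        run <- run + 1L
        if (run > 26L) msamap_abort("USAGE_ERROR", "Insertion-code runs support at most 26 residues.")
        num[i] <- counter
        code[i] <- LETTERS[run]
      }
    }
    numbering <- tibble::tibble(
      polymer_index = seq_len(n_res),
      residue_number = num,
      insertion_code = code,
      identity = pdb[pdb != "-"]
    )
  }
  la <- lookup_alignment(
    pdb_row = pdb_row, lookup_row = lookup_row, numbering = numbering,
    pdb_id = pdb_id, lookup_id = lookup_id
  )
  truth <- dplyr::mutate(
    numbering[, c("polymer_index", "residue_number", "insertion_code")],
    key = residue_key(.data$residue_number, .data$insertion_code),
    natural_position = nat_of_residue
  )
  list(lookup = la, truth = truth,
       insert_span = insert_span, missing_span = missing_span)
}

#' Generate a complete query fixture with ground truth
#'
#' Combines [simulate_data_alignment()] and [make_structure_variant()]:
#' the data alignment's lookup sequence becomes the reference for a
#' structure chain carrying an engineered insert and a missing span
#' (placed at fixed relative positions so the head of the chain is always
#' mappable). The returned truth tables give, for every structure
#' residue, its true natural position, and for every natural position its
#' true alignment column — everything needed to verify the mapping
#' pipeline by brute force.
#'
#' @param n,length,sub_rate,indel_rate,seed passed to
#'   [simulate_data_alignment()].
#' @param insert_len engineered-insert length (0 for none).
#' @param missing_len missing-span length (0 for none).
#' @param numbering_style passed to [make_structure_variant()].
#' @param with_metadata attach a synthetic metadata tibble.
#' @return A list: `data_aln`, `lookup` (a `lookup_aln`), `truth`
#'   (structure-residue table), `truth_columns` (natural position ->
#'   column), `metadata` (or `NULL`), plus the generator parameters.
#' @export
make_fixture <- function(n = 20, length = 120, sub_rate = 0.05,
                         indel_rate = 0.02, seed = 1,
                         insert_len = 6, missing_len = 4,
                         numbering_style = "sequential",
                         with_metadata = FALSE) {
  sim <- simulate_data_alignment(n, length, sub_rate, indel_rate, seed)
  L <- nchar(sim$lookup_seq)
  missing_span <- NULL
  insert_span <- NULL
  if (missing_len > 0) {
    a <- max(2L, floor(L * 0.40))
    missing_span <- c(a, min(L - 1L, a + missing_len - 1L))
  }
  if (insert_len > 0) {
    a <- max(2L, floor(L * 0.70))
    insert_span <- c(a, min(L - 1L, a + max(1L, floor(insert_len / 2)) - 1L))
    if (!is.null(missing_span) && insert_span[1] <= missing_span[2]) {
      insert_span <- insert_span + (missing_span[2] - insert_span[1] + 2L)
    }
  }
  sv <- make_structure_variant(
    sim$lookup_seq,
    insert_span = insert_span,
    insert_seq = if (insert_len > 0) insert_len else NULL,
    missing_span = missing_span,
    seed = seed + 1L,
    numbering_style = numbering_style,
    lookup_id = sim$lookup_id
  )
  md <- NULL
  if (with_metadata) md <- synth_metadata(sim$aln$seq_id, seed = seed + 2L)
  list(
    data_aln = sim$aln,
    lookup = sv$lookup,
    truth = sv$truth,
    truth_columns = sim$truth_columns,
    lookup_seq = sim$lookup_seq,
    metadata = md,
    insert_span = sv$insert_span,
    missing_span = sv$missing_span,
    params = sim$params
  )
}

#' Synthesize a per-sequence metadata table
#'
#' @param seq_ids sequence ids to cover.
#' @param seed integer seed.
#' @return A metadata tibble with the six standard columns; values are
#'   synthetic (ids, accession-shaped strings, a few bacterial lineages).
#' @export
synth_metadata <- function(seq_ids, seed = 1) {
  lineages <- c(
    "Bacteria; Proteobacteria; Gammaproteobacteria; Enterobacterales",
    "Bacteria; Proteobacteria; Alphaproteobacteria; Rhizobiales",
    "Bacteria; Firmicutes; Bacilli; Bacillales",
    "Bacteria; Actinobacteria; Actinomycetia; Streptomycetales"
  )
  genera <- c("Escherichia", "Rhizobium", "Bacillus", "Streptomyces")
  with_seed_local(seed, {
    k <- base::length(seq_ids)
    pick <- sample(base::length(lineages), k, replace = TRUE)
    tibble::tibble(
      seq_id = seq_ids,
      crw_id = sprintf("CRW:%05d", sample(1e4, k)),
      accession = sprintf("AB%06d", sample(1e6 - 1, k)),
      taxonomy_id = as.character(sample(1e5, k)),
      organism = sprintf("%s sp. %03d", genera[pick], sample(999, k, replace = TRUE)),
      lineage = lineages[pick]
    )
  })
}
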