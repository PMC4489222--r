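# Brute-force oracles computed directly from fixture truth tables,
# independent of the residue/column map code paths.

# column of a residue key, straight from the two truth tables
oracle_column_of <- function(key, fx) {
  row <- fx$truth[fx$truth$key == key, ]
  stopifnot(nrow(row) == 1)
  nat <- row$natural_position
  if (is.na(nat)) return(NA_integer_)
  fx$truth_columns$column[fx$truth_columns$natural_position == nat]
}

# per-sequence extract over the column interval implied by two residue keys
oracle_extracts <- function(start_key, end_key, fx) {
  c1 <- oracle_column_of(start_key, fx)
  c2 <- oracle_column_of(end_key, fx)
  vapply(fx$data_aln$seq, function(row) {
    paste(strsplit(row, "")[[1]][c1:c2], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# a units string addressing the fixture chain STRU|1|A by residue keys
units_for <- function(start_key, end_key = start_key, pdb = "STRU") {
  split_key <- function(k) {
    m <- regmatches(k, regexec("^(-?\\d+)([A-Za-z]?)$", k))[[1]]
    list(number = m[2], code = m[3])
  }
  s <- split_key(start_key); e <- split_key(end_key)
  fmt <- function(x) {
    base <- sprintf("%s|1|A||%s", pdb, x$number)
    if (nzchar(x$code)) paste0(base, "|||", x$code) else base
  }
  if (start_key == end_key) fmt(s) else paste0(fmt(s), ":", fmt(e))
}

# full maps for a fixture, built through the package
fixture_maps <- function(fx) {
  rm <- build_residue_map(fx$lookup)
  offset <- check_consistency(fx$lookup, fx$data_aln)
  cm <- build_column_map(fx$data_aln, fx$lookup$lookup_id)
  list(rm = rm, cm = cm, offset = offset)
}
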