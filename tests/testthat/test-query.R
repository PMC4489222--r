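# 100-residue chain, identity lookup alignment: every residue maps to itself
identity_fixture <- function(L = 100, seed = 2) {
  seq <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
  la <- lookup_alignment(pdb_row = seq, lookup_row = seq, pdb_id = "STRU")
  msa <- tibble::tibble(seq_id = "lookup", seq = seq)
  list(la = la, msa = msa, rm = build_residue_map(la),
       cm = build_column_map(msa, "lookup"))
}

test_that("query limits are enforced exactly", {
  set.seed(2)
  fx <- identity_fixture()
  one <- function(a, b) unit_range(unit_id("STRU", 1, "A", number = a),
                                   unit_id("STRU", 1, "A", number = b))
  # five ranges pass, six fail
  expect_s3_class(validate_query(lapply(1:5, function(i) one(i, i)), fx$la, fx$rm),
                  "range_query")
  expect_error(validate_query(lapply(1:6, function(i) one(i, i)), fx$la, fx$rm),
               class = "msamap_too_many_ranges")
  # 50-residue span passes, 51 fails
  expect_equal(validate_query(list(one(1, 50)), fx$la, fx$rm)$ranges$span, 50L)
  expect_error(validate_query(list(one(1, 51)), fx$la, fx$rm),
               class = "msamap_range_too_long")
  # endpoints must be in increasing polymer order
  expect_error(validate_query(list(one(10, 5)), fx$la, fx$rm),
               class = "msamap_endpoints_out_of_order")
  expect_error(validate_query(list(one(1, 200)), fx$la, fx$rm),
               class = "msamap_unknown_residue")
})

test_that("an unmappable endpoint fails with the no-data error condition", {
  sv <- make_structure_variant(
    paste(rep("ACGU", 10), collapse = ""),
    insert_span = c(17, 20), insert_seq = "GGGAAA"
  )
  rm <- build_residue_map(sv$lookup)
  insert_keys <- sv$truth$key[is.na(sv$truth$natural_position)]
  expect_gt(length(insert_keys), 0)
  r <- unit_range(
    unit_id("STRU", 1, "A", number = as.integer(insert_keys[1])),
    unit_id("STRU", 1, "A", number = as.integer(insert_keys[1]) + 3L)
  )
  err <- expect_error(validate_query(list(r), sv$lookup, rm), class = "msamap_no_data")
  expect_match(conditionMessage(err), "No data available in table", fixed = TRUE)
})

test_that("endpoint order follows the numbering table through insertion-code runs", {
  sv <- make_structure_variant(
    paste(rep("ACGU", 10), collapse = ""),
    insert_span = c(17, 18), insert_seq = "GGAA",
    numbering_style = "insertion_codes"
  )
  rm <- build_residue_map(sv$lookup)
  nb <- sv$lookup$numbering
  last <- nb[nrow(nb), ]
  # 16 -> 17 brackets the 16A..16D insert run; numerically equal endpoints
  # 16 and 16A are still correctly ordered
  r <- unit_range(unit_id("STRU", 1, "A", number = 16),
                  unit_id("STRU", 1, "A", number = 17))
  q <- validate_query(list(r), sv$lookup, rm)
  expect_equal(q$ranges$span, 6L)  # 16, 16A..16D, 17
  bad <- unit_range(
    unit_id("STRU", 1, "A", number = 16, insertion_code = "B"),
    unit_id("STRU", 1, "A", number = 16, insertion_code = "A")
  )
  expect_error(validate_query(list(bad), sv$lookup, rm),
               class = "msamap_endpoints_out_of_order")
})

test_that("column resolution keeps interior gap columns of the lookup row", {
  la <- lookup_alignment(pdb_row = "ACGGAU", lookup_row = "ACGGAU", pdb_id = "STRU")
  msa <- tibble::tibble(
    seq_id = c("lookup", "other"),
    seq = c("AC-GGAU", "ACUGGAU")
  )
  rm <- build_residue_map(la)
  cm <- build_column_map(msa, "lookup")
  q <- validate_query("STRU|1|A||2:STRU|1|A||3", la, rm)
  q <- resolve_columns(q, rm, cm)
  expect_equal(q$ranges$start_col, 2L)
  expect_equal(q$ranges$end_col, 4L)
  expect_equal(q$ranges$width, 3L)
  es <- extract_columns(q, msa)
  expect_equal(es$display, c("C-G", "CUG"))
})

test_that("extracts are direct substrings, equal width, all-gap rows retained", {
  la <- lookup_alignment(pdb_row = "ACGU", lookup_row = "ACGU", pdb_id = "STRU")
  msa <- tibble::tibble(seq_id = c("lookup", "s2", "s3"),
                        seq = c("ACGU", "AC-U", "A-GU"))
  rm <- build_residue_map(la)
  cm <- build_column_map(msa, "lookup")
  q <- resolve_columns(validate_query("STRU|1|A||2:STRU|1|A||3", la, rm), rm, cm)
  es <- extract_columns(q, msa)
  expect_equal(es$display, c("CG", "C-", "-G"))

  # two single-residue ranges joined with a comma in display order
  q2 <- resolve_columns(validate_query("STRU|1|A||1,STRU|1|A||4", la, rm), rm, cm)
  es2 <- extract_columns(q2, msa)
  expect_equal(es2$display[1], "A, U")

  # full-width interval returns the whole row
  q3 <- resolve_columns(validate_query("STRU|1|A||1:STRU|1|A||4", la, rm), rm, cm)
  expect_equal(extract_columns(q3, msa)$display, msa$seq)
})

test_that("adjacent column intervals concatenate to the spanning interval", {
  fx <- make_fixture(n = 15, length = 120, seed = 9)
  m <- fixture_maps(fx)
  mapped <- fx$truth[!is.na(fx$truth$natural_position), ]
  # a seam where both natural positions and columns are consecutive, so the
  # two sub-intervals tile the spanning interval exactly
  nat <- mapped$natural_position
  seam <- which(diff(nat) == 1 & diff(m$cm[nat]) == 1)
  seam <- seam[seam > 10 & seam < nrow(mapped) - 10][1]
  a <- mapped$key[seam - 10]; b <- mapped$key[seam]
  b_next <- mapped$key[seam + 1]; cc <- mapped$key[seam + 10]
  run <- function(u) {
    q <- validate_query(u, fx$lookup, m$rm)
    extract_columns(resolve_columns(q, m$rm, m$cm, m$offset), fx$data_aln)
  }
  left <- run(units_for(a, b))
  right <- run(units_for(b_next, cc))
  whole <- run(units_for(a, cc))
  expect_equal(paste0(vapply(left$extracts, `[`, character(1), 1),
                      vapply(right$extracts, `[`, character(1), 1)),
               vapply(whole$extracts, `[`, character(1), 1))
})
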