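toy_extracts <- function(displays) {
  tibble::tibble(
    seq_id = sprintf("s%d", seq_along(displays)),
    extracts = lapply(displays, function(d) strsplit(d, ", ", fixed = TRUE)[[1]]),
    display = displays
  )
}

test_that("variant summary groups, counts and orders deterministically", {
  s <- summarize_variants(toy_extracts(c("CG", "CG", "C-")))
  expect_equal(s$variant, c("CG", "C-"))
  expect_equal(s$count, c(2L, 1L))
  expect_equal(s$percent, c(66.67, 33.33))

  one <- summarize_variants(toy_extracts(rep("ACGU", 7)))
  expect_equal(nrow(one), 1)
  expect_equal(one$percent, 100)

  singletons <- summarize_variants(toy_extracts(c("AA", "CC", "GG")))
  expect_equal(singletons$count, rep(1L, 3))
  expect_equal(singletons$variant, sort(singletons$variant))
})

test_that("summary counts conserve n and percents sum to 100 within rounding", {
  for (seed in 1:4) {
    fx <- make_fixture(n = 30, length = 150, seed = seed, with_metadata = TRUE)
    keys <- fx$truth$key[!is.na(fx$truth$natural_position)]
    rep <- msa_query(units_for(keys[10], keys[25]), fx$data_aln, fx$lookup,
                     metadata = fx$metadata)
    expect_equal(sum(rep$summary$count), nrow(fx$data_aln))
    r <- nrow(rep$summary)
    expect_lte(abs(sum(rep$summary$percent) - 100), 0.05 * r)
    # details: exactly one row per sequence, exactly one lookup row
    expect_equal(sort(rep$details$seq_id), sort(fx$data_aln$seq_id))
    expect_equal(sum(rep$details$is_lookup), 1L)
  }
})

test_that("structure and lookup highlighting flags follow the extracts", {
  fx <- make_fixture(n = 10, length = 80, seed = 21, sub_rate = 0.1)
  keys <- fx$truth$key[!is.na(fx$truth$natural_position)]
  rep <- msa_query(units_for(keys[5], keys[12]), fx$data_aln, fx$lookup)
  lk <- rep$details[rep$details$is_lookup, ]
  # the lookup sequence is identical to the structure over mapped residues
  expect_true(lk$matches_structure)
  # flagged variants are exactly those whose gap-stripped extract equals
  # the structure letters (T/U equivalent)
  stripped <- gsub("-", "", gsub(", ", "", rep$details$variant))
  expect_equal(
    rep$details$matches_structure,
    gsub("T", "U", toupper(stripped)) == gsub("T", "U", paste(rep$structure_letters, collapse = ""))
  )
})

test_that("a range bridging the engineered insert compares flanks only", {
  sv <- make_structure_variant(
    paste(rep("AC", 20), collapse = ""),
    insert_span = c(15, 18), insert_seq = "GGGGGG"
  )
  lookup_seq <- gsub("-", "", sv$lookup$lookup_row, fixed = TRUE)
  # s2 deletes exactly the replaced region, i.e. it looks like the structure
  chars <- strsplit(lookup_seq, "")[[1]]
  chars[15:18] <- "-"
  msa <- tibble::tibble(
    seq_id = c("lookup", "s2"),
    seq = c(lookup_seq, paste(chars, collapse = ""))
  )
  # polymer 12..24 brackets the insert (insert residues are polymer 15..20)
  rep <- msa_query("STRU|1|A||12:STRU|1|A||24", msa, sv$lookup)
  # structure letters exclude the 6 insert residues
  expect_false(grepl("G", rep$structure_letters))
  det <- rep$details
  # only the flank-matching deletion variant is highlighted, not the
  # full-length lookup variant that retains the replaced residues
  expect_true(det$matches_structure[det$seq_id == "s2"])
  expect_false(det$matches_structure[det$seq_id == "lookup"])
})

test_that("filtering is literal, case-insensitive, and display-level", {
  rows <- summarize_variants(toy_extracts(c("ACGU", "ACGU", "AC-GU")))
  kept <- filter_rows(rows, "ACGU")
  expect_equal(kept$variant, "ACGU")
  expect_equal(nrow(filter_rows(rows, "acgu")), 1)
  expect_equal(nrow(filter_rows(rows, "ZZZ")), 0)
  # summary counts are unchanged by filtering
  expect_equal(sum(rows$count), 3L)

  fx <- make_fixture(n = 12, length = 60, seed = 4, with_metadata = TRUE)
  keys <- fx$truth$key[!is.na(fx$truth$natural_position)]
  rep <- msa_query(units_for(keys[3], keys[8]), fx$data_aln, fx$lookup,
                   metadata = fx$metadata)
  gam <- filter_rows(rep$details, "Gammaproteobacteria")
  expect_true(all(grepl("Gammaproteobacteria", gam$lineage)))
  expect_equal(nrow(gam), sum(grepl("Gammaproteobacteria", rep$details$lineage)))
})

test_that("serialization round-trips and respects per-format shapes", {
  fx <- make_fixture(n = 15, length = 100, seed = 6, with_metadata = TRUE)
  keys <- fx$truth$key[!is.na(fx$truth$natural_position)]
  rep <- msa_query(units_for(keys[4], keys[10], pdb = "STRU"), fx$data_aln,
                   fx$lookup, metadata = fx$metadata, alignment_id = "fix")

  json_path <- withr::local_tempfile(fileext = ".json")
  serialize_report(rep, json_path, "json")
  parsed <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  expect_equal(parsed$query$units, rep$units)
  expect_equal(parsed$summary$count, rep$summary$count)
  expect_equal(parsed$details$variant, rep$details$variant)
  expect_equal(parsed$n_sequences, nrow(fx$data_aln))

  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  serialize_report(rep, tsv_path, "tsv")
  tsv <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  expect_equal(nrow(tsv), nrow(fx$data_aln))
  expect_equal(tsv$variant, rep$details$variant)

  fa_path <- withr::local_tempfile(fileext = ".fasta")
  serialize_report(rep, fa_path, "fasta")
  sub <- read_alignment(fa_path)
  expect_equal(nrow(sub), nrow(fx$data_aln))
  expect_true(all(nchar(sub$seq) == sum(rep$ranges$width)))

  cl_path <- withr::local_tempfile(fileext = ".aln")
  serialize_report(rep, cl_path, "clustal")
  expect_equal(read_alignment(cl_path), sub)

  expect_error(serialize_report(rep, withr::local_tempfile(), "xml"),
               class = "msamap_usage_error")
})

test_that("tidy, glance and autoplot expose the report", {
  fx <- make_fixture(n = 8, length = 60, seed = 13)
  keys <- fx$truth$key[!is.na(fx$truth$natural_position)]
  rep <- msa_query(units_for(keys[2], keys[7]), fx$data_aln, fx$lookup)
  expect_identical(generics::tidy(rep), rep$details)
  g <- generics::glance(rep)
  expect_equal(g$n_sequences, 8)
  expect_equal(g$top_percent, rep$summary$percent[1])
  p <- ggplot2::autoplot(rep)
  expect_s3_class(p, "ggplot")
})
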