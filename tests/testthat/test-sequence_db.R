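test_that("read_fasta parses entries, accessions and order", {
  path <- write_tmp_fasta(
    c("sp|P02769|ALBU_BOVIN Serum albumin", "Q12345 some protein",
      "plainacc"),
    c("MKWVTFISLLLLFSSAYSR", "ACDEFGHIKLMNP", "PEPTIDEK"))
  db <- read_fasta(path, species = "bovine", source = "test")
  expect_s3_class(db, "sequence_db")
  expect_equal(length(db), 3L)
  expect_equal(db$records$accession, c("P02769", "Q12345", "plainacc"))
  expect_equal(db$records$sequence[1], "MKWVTFISLLLLFSSAYSR")
  expect_equal(db$records$description[1], "Serum albumin")
  expect_true(all(db$records$species == "bovine"))
})

test_that("read_fasta rejects empty sequences and duplicate accessions", {
  path <- write_tmp_fasta(c("A1 ok", "A2 empty"), c("PEPTIDEK", ""))
  expect_error(read_fasta(path, species = "human"), "empty sequence")
  path2 <- write_tmp_fasta(c("A1", "A1"), c("PEPTIDEK", "ELVISLIVESK"))
  expect_error(read_fasta(path2, species = "human"), "duplicate")
})

test_that("sequence validation tolerates ambiguity codes, strips stops", {
  expect_warning(
    db <- sequence_database("A1", "PEPTXDEK*", species = "human"),
    "ambiguity")
  expect_equal(db$records$sequence, "PEPTXDEK")
  expect_error(sequence_database("A2", "PEPT1DEK", species = "human"),
               "invalid residue")
})

test_that("FASTA round-trip preserves accessions and sequences", {
  db <- sequence_database(c("X1", "X2"),
                          c(strrep("ACDEFGHIK", 10), "MKWVTFISLLK"),
                          species = "human", description = c("d one", ""))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(db, path)
  back <- read_fasta(path, species = "human")
  expect_equal(back$records$accession, db$records$accession)
  expect_equal(back$records$sequence, db$records$sequence)
})

test_that("merge_databases concatenates with provenance and is
           associative in entry counts", {
  mk <- function(pre, n, name) sequence_database(
    sprintf("%s%03d", pre, seq_len(n)), rep("ACDEFGHIK", n),
    species = "human", name = name, source = name)
  a <- mk("A", 5, "a"); b <- mk("B", 3, "b"); c <- mk("C", 2, "c")
  m <- merge_databases(list(a, b, c), "abc")
  expect_equal(length(m), 10L)
  expect_equal(m$components$source, c("a", "b", "c"))
  expect_equal(sum(m$components$n), 10L)
  m2 <- merge_databases(list(a, merge_databases(list(b, c), "bc")), "abc2")
  expect_equal(length(m2), length(m))
  # merging with an empty database is an identity on counts
  e <- sequence_database(character(), character(), species = "human",
                         name = "empty")
  expect_equal(length(merge_databases(list(a, e), "ae")), length(a))
})

test_that("accession collisions follow the configured policy", {
  a <- sequence_database("P1", "ACDEFGHIK", species = "human",
                         name = "a", source = "srcA")
  b <- sequence_database("P1", "MKWVTFISK", species = "bovine",
                         name = "b", source = "srcB")
  expect_error(merge_databases(list(a, b), "ab", collision = "error"),
               "collision")
  expect_warning(m <- merge_databases(list(a, b), "ab"), "suffix")
  expect_equal(length(m), 2L)
  expect_setequal(m$records$accession, c("P1", "P1|srcB"))
})

test_that("build_fbs_database subsets in list order and flags absentees", {
  bov <- sequence_database(sprintf("B%02d", 1:10),
                           rep("ACDEFGHIKLMNPQR", 10),
                           species = "bovine", name = "bo")
  fbs <- build_fbs_database(bov, c("B05", "B02", "B09"))
  expect_equal(fbs$records$accession, c("B05", "B02", "B09"))
  # subset invariant: every record present in the source database
  expect_true(all(fbs$records$sequence %in% bov$records$sequence))
  expect_equal(length(build_fbs_database(bov, character())), 0L)
  expect_warning(p <- build_fbs_database(bov, c("B01", "B02", "B03", "B04",
                                                "NOPE")), "absent")
  expect_equal(length(p), 4L)
  expect_error(build_fbs_database(bov, "NOPE", strict = TRUE), "absent")
})

test_that("utility sequences append by count and carry the utility tag", {
  util <- utility_sequences()
  expect_equal(length(util), 20L)
  expect_true(all(util$records$species == "utility"))
  hu <- sequence_database(sprintf("H%02d", 1:7), rep("ACDEFGHIK", 7),
                          species = "human", name = "hu")
  out <- append_utility_sequences(hu, util)
  expect_equal(length(out), 27L)
  expect_identical(append_utility_sequences(
    hu, sequence_database(character(), character(), species = "utility",
                          name = "none")), hu)
  not_util <- sequence_database("X", "ACDEFGHIK", species = "human")
  expect_error(append_utility_sequences(hu, not_util), "utility")
})

test_that("accession lists skip comments and blanks", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# contaminants", "P1", "", "P2  # trailing", "  P3"), path)
  expect_equal(read_accession_list(path), c("P1", "P2", "P3"))
})
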