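test_that("psm_set validates required columns and score ranges", {
  expect_error(psm_set(data.frame(scan = 1)), "required PSM column")
  expect_error(make_psms(q_value = 1.5), "q_value")
  expect_error(make_psms(pep = 0), "pep")
  p <- make_psms(3)
  expect_s3_class(p, "psm_set")
  expect_equal(nrow(p), 3L)
})

test_that("PSM tables round-trip and dialects map vendor columns", {
  p <- make_psms(10, peptide = "SAMPLER", proteins = "P1;P2",
                 modifications = "M3(Oxidation)")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_psm_table(p, path)
  back <- read_psm_table(path)
  expect_equal(back$peptide, p$peptide)
  expect_equal(back$xcorr, p$xcorr)
  expect_equal(back$modifications, p$modifications)
  # vendor-style export with mapped column names
  pd <- data.frame(check.names = FALSE,
    `Spectrum File` = "a.raw", `First Scan` = 5L, Charge = 2L, Rank = 1L,
    Sequence = "SAMPLER", Modifications = "M3(Oxidation)", XCorr = 2.8,
    `Percolator q-Value` = 0.002, `Percolator PEP` = 0.01,
    `Protein Accessions` = "P1; P2")
  path2 <- withr::local_tempfile(fileext = ".txt")
  write.table(pd, path2, sep = "\t", row.names = FALSE, quote = FALSE)
  got <- read_psm_table(path2, dialect = "pd_export")
  expect_equal(got$scan, 5L)
  expect_equal(got$pep, 0.01)
  expect_equal(got$peptide, "SAMPLER")
})

test_that("a missing required column is an explicit error", {
  p <- make_psms(2)
  df <- as.data.frame(p)
  df$pep <- NULL
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_psm_table(path, required = "pep"), "pep")
})

test_that("modification strings parse positions, names and masses", {
  m <- parse_modifications("M3(Oxidation)", "SAMPLER")[[1]]
  expect_equal(m$position, 2L)           # 0-based
  expect_equal(m$residue, "M")
  expect_equal(m$delta_mass, 15.99)
  m2 <- parse_modifications("K1(Lys8);R7(Arg10)", "KAPSAMR")[[1]]
  expect_equal(m2$position, c(0L, 6L))
  expect_equal(m2$delta_mass, c(8.01, 10.01))
  mt <- parse_modifications("N-Term(Acetyl)", "SAMPLER")[[1]]
  expect_equal(mt$terminus, "N")
  expect_error(parse_modifications("M9(Oxidation)", "SAMPLER"),
               "out of range")
  expect_error(parse_modifications("A3(Oxidation)", "SAMPLER"),
               "mismatch")
  expect_error(parse_modifications("garbage", "SAMPLER"), "unparsable")
})

test_that("filter_psms applies q, charge-dependent XCorr and rank", {
  crit <- filter_criteria()
  # below the +2 threshold of 2 despite a good q
  expect_equal(nrow(filter_psms(make_psms(charge = 2L, xcorr = 1.9,
                                          q_value = 0.005), crit)), 0L)
  expect_equal(nrow(filter_psms(make_psms(charge = 3L, xcorr = 2.30,
                                          q_value = 0.005), crit)), 1L)
  # the over-7 bucket
  expect_equal(nrow(filter_psms(make_psms(charge = 9L, xcorr = 3.39,
                                          q_value = 0.005), crit)), 0L)
  expect_equal(nrow(filter_psms(make_psms(charge = 9L, xcorr = 3.41,
                                          q_value = 0.005), crit)), 1L)
  expect_equal(nrow(filter_psms(make_psms(q_value = 0.02), crit)), 0L)
  expect_equal(nrow(filter_psms(make_psms(rank = 2L), crit)), 0L)
  expect_equal(nrow(filter_psms(make_psms(0), crit)), 0L)
  expect_error(filter_psms(make_psms(charge = 0L), crit), "charge")
})

test_that("filtering is idempotent and monotone in its criteria", {
  set.seed(3)
  n <- 200
  p <- make_psms(n, charge = sample(1:9, n, TRUE),
                 xcorr = runif(n, 0, 5), q_value = runif(n, 0, 0.05),
                 rank = sample(1:2, n, TRUE, prob = c(0.8, 0.2)))
  crit <- filter_criteria()
  once <- filter_psms(p, crit)
  expect_identical(filter_psms(once, crit), once)
  # relaxing any single criterion never shrinks the retained set
  expect_gte(nrow(filter_psms(p, filter_criteria(q_max = 0.05))),
             nrow(once))
  looser_x <- filter_criteria(
    xcorr_min_by_charge = filter_criteria()$xcorr_min_by_charge - 0.5)
  expect_gte(nrow(filter_psms(p, looser_x)), nrow(once))
  expect_gte(nrow(filter_psms(p, filter_criteria(top_rank_only = FALSE))),
             nrow(once))
})

test_that("target-decoy q-values match hand-computed FDRs", {
  p <- make_psms(4, xcorr = c(10, 8, 6, 7), q_value = NA_real_,
                 is_decoy = c(FALSE, FALSE, FALSE, TRUE))
  q <- estimate_q_values(p)
  expect_equal(q$q_value[1:3], c(0, 0, 1 / 3))
  # all targets above all decoys: every target q = 0
  p2 <- make_psms(4, xcorr = c(9, 8, 7, 2), q_value = NA_real_,
                  is_decoy = c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(estimate_q_values(p2)$q_value[1:3], c(0, 0, 0))
  expect_error(estimate_q_values(make_psms(3, q_value = NA_real_)),
               "decoy")
})

test_that("q-values are monotone non-increasing in score and in [0,1]", {
  set.seed(5)
  n <- 400
  p <- make_psms(n, xcorr = c(rnorm(n / 2, 3, 0.7), rnorm(n / 2, 1.5, 0.7)),
                 q_value = NA_real_,
                 is_decoy = rep(c(FALSE, TRUE), each = n / 2))
  q <- estimate_q_values(p)
  ord <- order(q$xcorr, decreasing = TRUE)
  expect_true(all(diff(q$q_value[ord]) >= -1e-12))
  expect_true(all(q$q_value >= 0 & q$q_value <= 1))
})
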