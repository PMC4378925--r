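small_cfg <- function(...) {
  args <- utils::modifyList(
    list(seed = 101, n_human_proteins = 40L, n_bovine_proteins = 30L,
         protein_length = c(80L, 160L), n_spectra = 400L,
         n_fbs_proteins = 15L, major_fbs_count = 10L),
    list(...))
  do.call(synthetic_config, args)
}

test_that("configs validate their ranges", {
  expect_error(synthetic_config(contaminant_psm_fraction = 1.5))
  expect_error(synthetic_config(n_spectra = 0))
  expect_error(synthetic_config(n_fbs_proteins = 50,
                                n_bovine_proteins = 40))
})

test_that("generation is deterministic for a fixed seed and leaves the
           session RNG untouched", {
  cfg <- small_cfg()
  set.seed(999)
  before <- .Random.seed
  p1 <- generate_proteomes(cfg)
  expect_identical(.Random.seed, before)
  p2 <- generate_proteomes(cfg)
  expect_identical(p1$human$records, p2$human$records)
  expect_identical(p1$truth$shared_peptides, p2$truth$shared_peptides)
  g1 <- generate_psm_tables(cfg, p1, "HFDB")
  g2 <- generate_psm_tables(cfg, p2, "HFDB")
  expect_identical(as.data.frame(g1$tables$HFDB),
                   as.data.frame(g2$tables$HFDB))
  s1 <- generate_silac_annotations(cfg, g1$tables$HFDB, g1$truth)
  s2 <- generate_silac_annotations(cfg, g2$tables$HFDB, g2$truth)
  expect_identical(s1$modifications, s2$modifications)
})

test_that("orthology fraction controls cross-species shared peptides", {
  none <- generate_proteomes(small_cfg(orthology_fraction = 0))
  expect_length(none$truth$shared_peptides, 0)
  idx0 <- build_peptide_index(list(none$human, none$bovine))
  expect_equal(sum(idx0$species_map$has_human & idx0$species_map$has_bovine),
               0L)
  some <- generate_proteomes(small_cfg(orthology_fraction = 0.4))
  expect_gt(length(some$truth$shared_peptides), 0)
  # generator bookkeeping agrees exactly with the index
  idx <- build_peptide_index(list(some$human, some$bovine))
  shared_idx <- idx$species_map$peptide[
    idx$species_map$has_human & idx$species_map$has_bovine]
  expect_setequal(shared_idx, some$truth$shared_peptides)
  # every clone preserves its designated peptide in both parents
  for (i in seq_len(nrow(some$truth$clone_pairs)))
    expect_true(some$truth$clone_pairs$preserved_peptide[i] %in%
                  some$truth$shared_peptides)
})

test_that("zero contaminant fraction gives identical spectra across
           databases", {
  cfg <- small_cfg(contaminant_psm_fraction = 0)
  pr <- generate_proteomes(cfg)
  gen <- generate_psm_tables(cfg, pr)
  scans <- lapply(gen$tables, function(t) sort(t$scan[!t$is_decoy]))
  expect_identical(scans$HuDB, scans$HFDB)
  expect_identical(scans$HuDB, scans$HBDB)
  expect_true(all(gen$truth$origin == "human"))
})

test_that("bovine-unique contaminant spectra are absent from the
           human-only table and present in the composite one", {
  cfg <- small_cfg(contaminant_psm_fraction = 0.2, incorrect_psm_rate = 0)
  pr <- generate_proteomes(cfg)
  gen <- generate_psm_tables(cfg, pr)
  tr <- gen$truth
  bovine_unique <- tr$origin == "contaminant" & !tr$shared
  expect_gt(sum(bovine_unique), 0)
  expect_true(all(tr$emitted_HuDB[bovine_unique] == "absent"))
  expect_true(all(tr$emitted_HFDB[bovine_unique] == "correct"))
  hu_scans <- gen$tables$HuDB$scan[!gen$tables$HuDB$is_decoy]
  expect_false(any(tr$scan[bovine_unique] %in% hu_scans))
})

test_that("incorrect matches appear under the human-only database when
           enabled, with worse error probabilities", {
  cfg <- small_cfg(contaminant_psm_fraction = 0.3, incorrect_psm_rate = 1)
  pr <- generate_proteomes(cfg)
  gen <- generate_psm_tables(cfg, pr, c("HuDB", "HFDB"))
  tr <- gen$truth
  forced <- tr$emitted_HuDB == "incorrect"
  expect_gt(sum(forced), 0)
  hu <- gen$tables$HuDB; hf <- gen$tables$HFDB
  pep_hu <- hu$pep[match(tr$scan[forced], hu$scan)]
  pep_hf <- hf$pep[match(tr$scan[forced], hf$scan)]
  expect_true(mean(pep_hu > pep_hf) > 0.9)
})

test_that("SILAC annotation labels only cell-derived PSMs", {
  cfg <- small_cfg(contaminant_psm_fraction = 0.3, label_efficiency = 1,
                   proline_conversion_rate = 0)
  pr <- generate_proteomes(cfg)
  gen <- generate_psm_tables(cfg, pr, "HFDB")
  sil <- generate_silac_annotations(cfg, gen$tables$HFDB, gen$truth)
  has_lab <- grepl("Arg10|Lys8|Pro6", sil$modifications)
  origin <- gen$truth$origin[match(sil$scan, gen$truth$scan)]
  tgt <- !sil$is_decoy
  # efficiency 1: every human-origin PSM containing R or K is labeled
  rk <- grepl("[RK]", sil$peptide)
  expect_true(all(has_lab[tgt & origin == "human" & rk]))
  expect_false(any(has_lab[tgt & origin == "contaminant"]))
  # efficiency 0: nothing labeled, every protein group non-labeled
  cfg0 <- small_cfg(label_efficiency = 0, proline_conversion_rate = 0)
  gen0 <- generate_psm_tables(cfg0, generate_proteomes(cfg0), "HFDB")
  sil0 <- generate_silac_annotations(cfg0, gen0$tables$HFDB, gen0$truth)
  flt0 <- filter_psms(sil0)
  flt0 <- flt0[!flt0$is_decoy, ]
  st0 <- classify_protein_labels(group_proteins(flt0), flt0)
  expect_true(all(st0$status == "non_labeled"))
})

test_that("fixture sets are written as plain text with ground truth", {
  outdir <- withr::local_tempdir()
  cfg <- small_cfg(n_spectra = 100L)
  write_fixture_set(cfg, outdir, databases = "HFDB")
  expect_true(file.exists(file.path(outdir, "human.fasta")))
  expect_true(file.exists(file.path(outdir, "psms_HFDB.tsv")))
  expect_true(file.exists(file.path(outdir, "ground_truth.json")))
  gt <- jsonlite::read_json(file.path(outdir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(nrow(gt$truth), 100L)
  back <- read_psm_table(file.path(outdir, "psms_HFDB.tsv"))
  expect_s3_class(back, "psm_set")
})
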