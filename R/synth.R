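# residue sampling frequencies: roughly vertebrate-like, with K+R ~ 11%
# combined so tryptic peptides have realistic lengths
AA_FREQ <- c(A = 7.5, C = 1.5, D = 5, E = 6, F = 4, G = 7, H = 2.5,
             I = 5, K = 5.5, L = 9, M = 2, N = 4, P = 5, Q = 4,
             R = 5.5, S = 7, T = 5.5, V = 6.5, W = 1.5, Y = 3.5)

# run code under a temporary RNG state; the session RNG is untouched
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

random_protein <- function(len) {
  paste(sample(names(AA_FREQ), len, replace = TRUE, prob = AA_FREQ),
        collapse = "")
}

#' Configuration for the synthetic secretome scenario
#'
#' Defines the study conditions the generator emulates: a human proteome
#' contaminated by fetal bovine serum (FBS) proteins, with a controlled
#' fraction of bovine proteins orthologous to human ones (sharing tryptic
#' peptides), a controlled FBS-contaminant PSM fraction, major (top-
#' abundance) versus minor FBS contaminants, SILAC labeling of
#' cell-derived (human-origin) PSMs, and a two-population XCorr/PEP score
#' model with target-decoy q-value estimation.
#'
#' @param seed integer seed; identical seed and config give identical
#'   output. Stages derive their sub-seeds from it deterministically.
#' @param n_human_proteins,n_bovine_proteins proteome sizes.
#' @param protein_length length range (residues), uniform.
#' @param orthology_fraction fraction of bovine proteins cloned from a
#'   human protein with mutations that preserve one shared tryptic
#'   peptide.
#' @param n_spectra number of MS/MS spectra simulated.
#' @param contaminant_psm_fraction probability a spectrum originates from
#'   an FBS contaminant protein (default 0.07, the midpoint of the 5-10%
#'   residual-FBS share expected in a secretome preparation).
#' @param n_fbs_proteins number of bovine proteins on the profiled FBS
#'   list.
#' @param major_fbs_count top-abundance FBS proteins designated major
#'   contaminants (default 30).
#' @param major_psm_weight share of contaminant PSMs drawn from major FBS
#'   proteins (default 0.93, matching the top-30 share observed in FBS
#'   profiling).
#' @param label_efficiency per-residue probability that an R/K of a
#'   cell-derived PSM is heavy-labeled (default 0.97, consistent with the
#'   >95% incorporation expected after several passages).
#' @param proline_conversion_rate per-residue probability of a +6.01 Da
#'   heavy proline from Arg-to-Pro conversion (default 0.03).
#' @param incorrect_psm_rate probability that a spectrum whose true
#'   peptide is absent from the search database is instead matched to a
#'   wrong (low-scoring) peptide of that database.
#' @param decoy_fraction decoy PSMs generated per database, as a fraction
#'   of `n_spectra`.
#' @param xcorr_correct,xcorr_incorrect `c(mean, sd)` of the XCorr
#'   distributions of correct and incorrect matches.
#' @param pep_slope,pep_mid PEP is a logistic function of XCorr:
#'   `PEP = 1 / (1 + exp(pep_slope * (xcorr - pep_mid)))`.
#' @param score_jitter_sd per-database XCorr jitter applied to re-searches
#'   of the same spectrum.
#' @param digestion a [digestion_params()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_human_proteins = 120L,
                             n_bovine_proteins = 80L,
                             protein_length = c(120L, 300L),
                             orthology_fraction = 0.25,
                             n_spectra = 2000L,
                             contaminant_psm_fraction = 0.07,
                             n_fbs_proteins = 40L,
                             major_fbs_count = 30L,
                             major_psm_weight = 0.93,
                             label_efficiency = 0.97,
                             proline_conversion_rate = 0.03,
                             incorrect_psm_rate = 0,
                             decoy_fraction = 0.3,
                             xcorr_correct = c(mean = 3.2, sd = 0.4),
                             xcorr_incorrect = c(mean = 1.6, sd = 0.35),
                             pep_slope = 3, pep_mid = 2.2,
                             score_jitter_sd = 0.05,
                             digestion = digestion_params()) {
  cfg <- list(seed = as.integer(seed),
              n_human_proteins = as.integer(n_human_proteins),
              n_bovine_proteins = as.integer(n_bovine_proteins),
              protein_length = as.integer(protein_length),
              orthology_fraction = orthology_fraction,
              n_spectra = as.integer(n_spectra),
              contaminant_psm_fraction = contaminant_psm_fraction,
              n_fbs_proteins = as.integer(n_fbs_proteins),
              major_fbs_count = as.integer(major_fbs_count),
              major_psm_weight = major_psm_weight,
              label_efficiency = label_efficiency,
              proline_conversion_rate = proline_conversion_rate,
              incorrect_psm_rate = incorrect_psm_rate,
              decoy_fraction = decoy_fraction,
              xcorr_correct = xcorr_correct,
              xcorr_incorrect = xcorr_incorrect,
              pep_slope = pep_slope, pep_mid = pep_mid,
              score_jitter_sd = score_jitter_sd,
              digestion = digestion)
  fr <- c(cfg$orthology_fraction, cfg$contaminant_psm_fraction,
          cfg$major_psm_weight, cfg$label_efficiency,
          cfg$proline_conversion_rate, cfg$incorrect_psm_rate)
  stopifnot(all(fr >= 0 & fr <= 1), cfg$n_spectra >= 1L,
            length(cfg$protein_length) == 2L,
            cfg$protein_length[1] <= cfg$protein_length[2],
            cfg$major_fbs_count <= cfg$n_fbs_proteins,
            cfg$n_fbs_proteins <= cfg$n_bovine_proteins)
  structure(cfg, class = "synthetic_config")
}

#' Generate paired human/bovine proteomes with controlled orthology
#'
#' Builds a human proteome and a bovine proteome in which a configured
#' fraction of bovine proteins are orthologous clones of human proteins:
#' one tryptic peptide of the human template (and its cleavage context)
#' is preserved exactly while the rest of the sequence is mutated, giving
#' exact control over cross-species shared peptides. A subset of bovine
#' proteins forms the profiled-FBS list, partitioned into major
#' (top-abundance) and minor contaminants with sampling weights.
#'
#' @param config a [synthetic_config()].
#' @return List with `human` and `bovine` `sequence_db`s, `fbs_major` /
#'   `fbs_minor` accession vectors, `fbs_weights` (named sampling
#'   weights over the FBS list) and `truth` (protein species map, clone
#'   pairs with their preserved peptides, and the exact cross-species
#'   shared-peptide set).
#' @export
generate_proteomes <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    lens <- sample(config$protein_length[1]:config$protein_length[2],
                   config$n_human_proteins, replace = TRUE)
    hum_seq <- vapply(lens, random_protein, "")
    hum_acc <- sprintf("HUM%05d", seq_len(config$n_human_proteins))
    n_orth <- round(config$orthology_fraction * config$n_bovine_proteins)
    bov_seq <- character(config$n_bovine_proteins)
    bov_acc <- sprintf("BOV%05d", seq_len(config$n_bovine_proteins))
    clone_pairs <- data.frame(bovine = character(), human = character(),
                              preserved_peptide = character(),
                              stringsAsFactors = FALSE)
    if (n_orth > 0L) {
      if (n_orth > config$n_human_proteins)
        stop("orthology_fraction requires more human templates than exist")
      templates <- sample(config$n_human_proteins, n_orth)
      for (j in seq_len(n_orth)) {
        tmpl <- hum_seq[templates[j]]
        d <- digest(tmpl, config$digestion)
        d <- d[d$missed_cleavages == 0L, , drop = FALSE]
        if (nrow(d) == 0L)
          stop("proteome too small to realize a shared tryptic peptide")
        pick <- d[sample(nrow(d), 1L), ]
        chars <- strsplit(tmpl, "")[[1]]
        s1 <- pick$start + 1L           # 1-based peptide interval
        e1 <- pick$start + pick$length
        protect <- c(if (pick$start > 0L) pick$start, s1:e1)
        mutable <- setdiff(seq_along(chars), protect)
        hit <- mutable[runif(length(mutable)) < 0.3]
        for (p in hit) {
          pool <- setdiff(names(AA_FREQ), chars[p])
          # the residue after the peptide must stay non-proline so the
          # preserved peptide remains a tryptic product
          if (p == e1 + 1L) pool <- setdiff(pool, "P")
          chars[p] <- sample(pool, 1L)
        }
        bov_seq[j] <- paste(chars, collapse = "")
        clone_pairs <- rbind(clone_pairs, data.frame(
          bovine = bov_acc[j], human = hum_acc[templates[j]],
          preserved_peptide = pick$peptide, stringsAsFactors = FALSE))
      }
    }
    for (j in seq_len(config$n_bovine_proteins))
      if (!nzchar(bov_seq[j]))
        bov_seq[j] <- random_protein(
          sample(config$protein_length[1]:config$protein_length[2], 1L))
    human <- sequence_database(hum_acc, hum_seq, species = "human",
                               name = "synthetic-human",
                               source = "synthetic-human")
    bovine <- sequence_database(bov_acc, bov_seq, species = "bovine",
                                name = "synthetic-bovine",
                                source = "synthetic-bovine")
    fbs <- sample(bov_acc, config$n_fbs_proteins)
    fbs_major <- fbs[seq_len(config$major_fbs_count)]
    fbs_minor <- setdiff(fbs, fbs_major)
    w_major <- 1 / seq_along(fbs_major)
    w_major <- config$major_psm_weight * w_major / sum(w_major)
    w_minor <- if (length(fbs_minor)) 1 / seq_along(fbs_minor) else numeric()
    if (length(w_minor))
      w_minor <- (1 - config$major_psm_weight) * w_minor / sum(w_minor)
    fbs_weights <- setNames(c(w_major, w_minor), c(fbs_major, fbs_minor))
    # exact cross-species shared peptides, by digesting both proteomes
    dg <- function(seqs) unique(unlist(lapply(seqs, function(s)
      canonical_peptide(digest(s, config$digestion)$peptide,
                        config$digestion))))
    shared <- intersect(dg(hum_seq), dg(bov_seq))
    truth <- list(
      protein_species = setNames(c(rep("human", length(hum_acc)),
                                   rep("bovine", length(bov_acc))),
                                 c(hum_acc, bov_acc)),
      clone_pairs = clone_pairs,
      shared_peptides = shared)
    list(human = human, bovine = bovine, fbs_major = fbs_major,
         fbs_minor = fbs_minor, fbs_weights = fbs_weights, truth = truth,
         config = config)
  })
}

logistic_pep <- function(xcorr, config) {
  p <- 1 / (1 + exp(config$pep_slope * (xcorr - config$pep_mid)))
  pmin(pmax(p, 1e-12), 1)
}

#' Generate per-database PSM tables with ground truth
#'
#' Simulates searching one spectrum set against several databases. Each
#' spectrum originates from a human secretome protein (probability
#' `1 - contaminant_psm_fraction`) or an FBS contaminant (drawn from the
#' FBS list with its abundance weights); its true peptide is a tryptic
#' peptide of the source protein. Under each database the spectrum yields
#' a PSM only if its peptide exists in that database: a contaminant
#' spectrum on a bovine-unique peptide gets no PSM under a human-only
#' database (or, with probability `incorrect_psm_rate`, a low-scoring
#' incorrect human PSM), and a correct bovine PSM under a composite
#' database; shared-peptide spectra match everywhere. XCorr is drawn from
#' the correct/incorrect score populations (with small per-database
#' jitter for re-searches of the same spectrum), PEP is a logistic
#' function of XCorr, and q-values are filled by target-decoy counting
#' over generated decoys.
#'
#' @param config a [synthetic_config()].
#' @param proteomes a [generate_proteomes()] result.
#' @param databases database labels among `"HuDB"`, `"HFDB"`, `"HBDB"`.
#' @return List with `tables` (named list of `psm_set`, decoy rows
#'   included and flagged), `truth` (per-spectrum data.frame: scan,
#'   origin, source protein, peptide, shared flag, true census class, and
#'   one `emitted_<db>` column per database with values
#'   correct/incorrect/absent) and `index` (the peptide index over both
#'   proteomes used for bookkeeping).
#' @export
generate_psm_tables <- function(config, proteomes,
                                databases = c("HuDB", "HFDB", "HBDB")) {
  stopifnot(inherits(config, "synthetic_config"),
            all(databases %in% c("HuDB", "HFDB", "HBDB")))
  index <- build_peptide_index(list(proteomes$human, proteomes$bovine),
                               config$digestion)
  ent <- index$entries
  parents_of <- split(ent$accession, ent$peptide)
  parents_of <- lapply(parents_of, unique)
  pep_of_prot <- split(ent$peptide, ent$accession)
  pep_of_prot <- lapply(pep_of_prot, unique)
  ok_prot <- names(pep_of_prot)[lengths(pep_of_prot) > 0L]
  hum_acc <- proteomes$human$records$accession
  fbs_acc <- names(proteomes$fbs_weights)
  hum_pool <- intersect(hum_acc, ok_prot)
  fbs_pool <- fbs_acc[fbs_acc %in% ok_prot]
  if (!length(hum_pool) || !length(fbs_pool))
    stop("proteome yields no indexable peptides")
  fbs_w <- proteomes$fbs_weights[fbs_pool]
  db_accs <- list(
    HuDB = hum_acc,
    HFDB = c(hum_acc, fbs_acc),
    HBDB = c(hum_acc, proteomes$bovine$records$accession))
  shared <- proteomes$truth$shared_peptides
  with_seed(config$seed + 1L, {
    n <- config$n_spectra
    is_cont <- runif(n) < config$contaminant_psm_fraction
    src <- character(n); pep <- character(n)
    src[is_cont] <- sample(fbs_pool, sum(is_cont), replace = TRUE,
                           prob = fbs_w)
    src[!is_cont] <- sample(hum_pool, sum(!is_cont), replace = TRUE)
    for (i in seq_len(n)) {
      pp <- pep_of_prot[[src[i]]]
      pep[i] <- pp[sample.int(length(pp), 1L)]
    }
    is_shared <- pep %in% shared
    true_class <- ifelse(is_shared, "orthologous",
                  ifelse(!is_cont, "human",
                  ifelse(src %in% proteomes$fbs_major, "major_fbs",
                  ifelse(src %in% proteomes$fbs_minor, "minor_fbs",
                         "other_bovine"))))
    charge <- sample(2:4, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
    xcorr_base <- pmax(0.5, rnorm(n, config$xcorr_correct["mean"],
                                  config$xcorr_correct["sd"]))
    truth <- data.frame(scan = seq_len(n),
                        origin = ifelse(is_cont, "contaminant", "human"),
                        source_protein = src, peptide = pep,
                        shared = is_shared, true_class = true_class,
                        stringsAsFactors = FALSE)
    prot_str <- function(peps, accs) vapply(peps, function(p)
      paste(sort(intersect(parents_of[[p]], accs)), collapse = ";"), "")
    tables <- list()
    for (db in databases) {
      accs <- db_accs[[db]]
      present <- vapply(pep, function(p)
        any(parents_of[[p]] %in% accs), logical(1))
      emitted <- ifelse(present, "correct", "absent")
      ip <- which(present)
      xc_p <- xcorr_base[ip] + rnorm(length(ip), 0, config$score_jitter_sd)
      rows <- list(data.frame(
        spectrum_file = "synthetic.raw", scan = ip, charge = charge[ip],
        rank = 1L, peptide = pep[ip], modifications = "", xcorr = xc_p,
        q_value = NA_real_, pep = logistic_pep(xc_p, config),
        proteins = prot_str(pep[ip], accs), search_db = db,
        is_decoy = FALSE, stringsAsFactors = FALSE))
      ia <- which(!present)
      ii <- ia[runif(length(ia)) < config$incorrect_psm_rate]
      if (length(ii)) {
        # spectra forced onto a wrong (human) peptide of this database
        wrong_prot <- sample(hum_pool, length(ii), replace = TRUE)
        wrong_pep <- vapply(wrong_prot, function(a) {
          wp <- pep_of_prot[[a]]
          wp[sample.int(length(wp), 1L)]
        }, "")
        xc_i <- pmax(0.1, rnorm(length(ii), config$xcorr_incorrect["mean"],
                                config$xcorr_incorrect["sd"]))
        emitted[ii] <- "incorrect"
        rows[[2L]] <- data.frame(
          spectrum_file = "synthetic.raw", scan = ii, charge = charge[ii],
          rank = 1L, peptide = wrong_pep, modifications = "", xcorr = xc_i,
          q_value = NA_real_, pep = logistic_pep(xc_i, config),
          proteins = prot_str(wrong_pep, accs), search_db = db,
          is_decoy = FALSE, stringsAsFactors = FALSE)
      }
      n_dec <- round(config$decoy_fraction * n)
      if (n_dec > 0L) {
        xc_d <- pmax(0.1, rnorm(n_dec, config$xcorr_incorrect["mean"],
                                config$xcorr_incorrect["sd"]))
        rows[[length(rows) + 1L]] <- data.frame(
          spectrum_file = "synthetic.raw", scan = n + seq_len(n_dec),
          charge = sample(2:4, n_dec, replace = TRUE,
                          prob = c(0.6, 0.3, 0.1)),
          rank = 1L,
          peptide = vapply(rep(12L, n_dec), random_protein, ""),
          modifications = "", xcorr = xc_d, q_value = NA_real_,
          pep = logistic_pep(xc_d, config),
          proteins = sprintf("DECOY_%05d", seq_len(n_dec)),
          search_db = db, is_decoy = TRUE, stringsAsFactors = FALSE)
      }
      tab <- psm_set(data.table::rbindlist(rows))
      tab <- tab[order(tab$scan), , drop = FALSE]
      rownames(tab) <- NULL
      tab <- estimate_q_values(tab)
      tables[[db]] <- tab
      truth[[paste0("emitted_", db)]] <- emitted
    }
    list(tables = tables, truth = truth, index = index)
  })
}

#' Add SILAC modifications to a synthetic PSM table
#'
#' Cell-derived (human-origin) PSMs receive heavy-label modifications:
#' each R gets Arg10 and each K gets Lys8 with probability
#' `label_efficiency`, and each P gets the Arg-to-Pro conversion label
#' Pro6 with probability `proline_conversion_rate`. Contaminant-origin
#' PSMs receive no labels: serum proteins are not synthesized in the
#' labeling medium. Decoy rows are left unmodified.
#'
#' @param config a [synthetic_config()].
#' @param psm_table one `psm_set` from [generate_psm_tables()].
#' @param truth the matching `truth` data.frame (per-spectrum origin).
#' @return The `psm_set` with `modifications` filled, plus an attribute
#'   `label_truth`: data.frame of per-residue true label states (scan,
#'   position, residue, labeled).
#' @export
generate_silac_annotations <- function(config, psm_table, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(psm_table, "psm_set"))
  origin_of <- setNames(truth$origin, truth$scan)
  with_seed(config$seed + 2L, {
    lt <- list()
    for (i in seq_len(nrow(psm_table))) {
      if (psm_table$is_decoy[i]) next
      orig <- origin_of[as.character(psm_table$scan[i])]
      chars <- strsplit(psm_table$peptide[i], "")[[1]]
      pos <- which(chars %in% c("R", "K", "P"))
      if (!length(pos)) next
      labeled <- logical(length(pos))
      if (identical(unname(orig), "human")) {
        pr <- ifelse(chars[pos] == "P", config$proline_conversion_rate,
                     config$label_efficiency)
        labeled <- runif(length(pos)) < pr
      }
      if (any(labeled)) {
        nm <- c(R = "Arg10", K = "Lys8", P = "Pro6")
        toks <- sprintf("%s%d(%s)", chars[pos[labeled]], pos[labeled],
                        nm[chars[pos[labeled]]])
        psm_table$modifications[i] <- paste(toks, collapse = ";")
      }
      lt[[length(lt) + 1L]] <- data.frame(
        scan = psm_table$scan[i], position = pos - 1L,
        residue = chars[pos], labeled = labeled,
        stringsAsFactors = FALSE)
    }
    attr(psm_table, "label_truth") <-
      if (length(lt)) do.call(rbind, lt) else NULL
    psm_table
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Writes the proteome FASTAs, contaminant accession lists, per-database
#' PSM tables, the SILAC-annotated table and the ground truth as plain
#' text under `outdir`.
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created if needed).
#' @param databases database labels to simulate.
#' @return The output directory, invisibly.
#' @export
write_fixture_set <- function(config, outdir,
                              databases = c("HuDB", "HFDB", "HBDB")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pr <- generate_proteomes(config)
  write_fasta(pr$human, file.path(outdir, "human.fasta"))
  write_fasta(pr$bovine, file.path(outdir, "bovine.fasta"))
  writeLines(pr$fbs_major, file.path(outdir, "fbs_major.txt"))
  writeLines(pr$fbs_minor, file.path(outdir, "fbs_minor.txt"))
  writeLines(c(pr$fbs_major, pr$fbs_minor),
             file.path(outdir, "fbs_all.txt"))
  gen <- generate_psm_tables(config, pr, databases)
  for (db in names(gen$tables))
    write_psm_table(gen$tables[[db]],
                    file.path(outdir, sprintf("psms_%s.tsv", db)))
  silac <- generate_silac_annotations(config, gen$tables[[1L]], gen$truth)
  write_psm_table(silac, file.path(outdir, "psms_silac.tsv"))
  jsonlite::write_json(
    list(truth = gen$truth,
         shared_peptides = pr$truth$shared_peptides,
         clone_pairs = pr$truth$clone_pairs),
    file.path(outdir, "ground_truth.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(outdir)
}
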