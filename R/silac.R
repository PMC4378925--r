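#' SILAC and search modification specifications
#'
#' The packaged modification set: the heavy labels
#' \code{[L-13C6,15N4]}-Arg (Arg10, +10.01 Da on R), \code{[L-13C6,15N2]}-Lys
#' (Lys8, +8.01 Da on K) and the +6.01 Da heavy proline produced by
#' metabolic Arg-to-Pro conversion, plus the non-label search
#' modifications carbamidomethyl-C (+57.02 Da) and oxidation-M
#' (+15.99 Da).
#'
#' @return data.frame with columns `name`, `residue`, `delta_mass`,
#'   `is_label`.
#' @export
silac_modification_specs <- function() {
  data.frame(
    name = c("Arg10", "Lys8", "Pro6", "Carbamidomethyl", "Oxidation"),
    residue = c("R", "K", "P", "C", "M"),
    delta_mass = c(10.01, 8.01, 6.01, 57.02, 15.99),
    is_label = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Per-residue label flags for one PSM
#'
#' Flags every R, K and P residue of the peptide as isotope-labeled or
#' not, according to whether a label modification of the matching residue
#' type sits at its position. A label modification annotated on a
#' non-matching residue indicates a corrupt table and is an error.
#'
#' @param peptide peptide sequence.
#' @param modifications modification string (see
#'   [parse_modifications()]).
#' @param specs modification specs (default
#'   [silac_modification_specs()]).
#' @return data.frame with one row per R/K/P residue: `position`
#'   (0-based), `residue`, `labeled`.
#' @export
annotate_labels <- function(peptide, modifications = "",
                            specs = silac_modification_specs()) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  mods <- parse_modifications(modifications, peptide)[[1L]]
  labels <- specs[specs$is_label, , drop = FALSE]
  lab_mods <- mods[mods$name %in% labels$name & !is.na(mods$position), ,
                   drop = FALSE]
  if (nrow(lab_mods)) {
    want <- labels$residue[match(lab_mods$name, labels$name)]
    bad <- lab_mods$residue != want
    if (any(bad))
      stop("label modification ", lab_mods$name[bad][1L],
           " on residue ", lab_mods$residue[bad][1L],
           " (expected ", want[bad][1L], "): corrupt table")
  }
  chars <- strsplit(peptide, "")[[1]]
  pos0 <- which(chars %in% c("R", "K", "P")) - 1L
  data.frame(position = pos0, residue = chars[pos0 + 1L],
             labeled = pos0 %in% lab_mods$position,
             stringsAsFactors = FALSE)
}

psm_has_label <- function(psms, specs = silac_modification_specs()) {
  label_names <- specs$name[specs$is_label]
  mods <- parse_modifications(psms$modifications, psms$peptide)
  vapply(mods, function(m) any(m$name %in% label_names), logical(1))
}

#' Residue-level SILAC census per species class
#'
#' Counts labeled and unlabeled R, K and P residues over all PSM peptides
#' of each species class. In a SILAC experiment only newly synthesized
#' cellular proteins incorporate heavy residues, so the human classes are
#' expected at the labeling efficiency (>95% in practice) and genuine
#' serum contaminants at zero.
#'
#' @param psms a [psm_set()].
#' @param classes per-PSM species class, e.g. `census_psms(...)$classes`;
#'   recycled factor/character of length `nrow(psms)`.
#' @param specs modification specs.
#' @return data.frame of class `silac_residue_census`: `class`,
#'   `residue`, `labeled`, `unlabeled`, `fraction_labeled`.
#' @export
residue_census <- function(psms, classes,
                           specs = silac_modification_specs()) {
  stopifnot(inherits(psms, "psm_set"), length(classes) == nrow(psms))
  classes <- as.character(classes)
  acc <- list()
  for (i in seq_len(nrow(psms))) {
    fl <- annotate_labels(psms$peptide[i], psms$modifications[i], specs)
    if (nrow(fl)) {
      fl$class <- classes[i]
      acc[[length(acc) + 1L]] <- fl
    }
  }
  cls_levels <- unique(classes)
  grid <- expand.grid(class = cls_levels, residue = c("R", "K", "P"),
                      stringsAsFactors = FALSE)
  if (length(acc)) {
    all_fl <- do.call(rbind, acc)
    all_fl$total <- 1L
    all_fl$labeled <- as.integer(all_fl$labeled)
    agg <- aggregate(cbind(labeled, total) ~ class + residue,
                     data = all_fl, FUN = sum)
    grid <- merge(grid, agg, all.x = TRUE)
  } else {
    grid$labeled <- NA_integer_; grid$total <- NA_integer_
  }
  grid$labeled[is.na(grid$labeled)] <- 0L
  grid$total[is.na(grid$total)] <- 0L
  grid$unlabeled <- grid$total - grid$labeled
  grid$fraction_labeled <- ifelse(grid$total > 0,
                                  grid$labeled / grid$total, NA_real_)
  grid <- grid[order(grid$class, match(grid$residue, c("R", "K", "P"))),
               c("class", "residue", "labeled", "unlabeled",
                 "fraction_labeled")]
  rownames(grid) <- NULL
  class(grid) <- c("silac_residue_census", "data.frame")
  grid
}

#' Protein-level SILAC label classification
#'
#' Classifies each protein group as `labeled` (every supporting peptide
#' carries at least one heavy label), `non_labeled` (no peptide does) or
#' `partially_labeled` (a mix). A peptide observation is labeled iff its
#' PSM carries at least one label modification. Two tallies are emitted:
#' observation level, where each distinct (peptide sequence, charge,
#' label state) observation counts separately, and sequence level, where
#' a peptide sequence is labeled if any of its PSMs is.
#'
#' @param groups a [group_proteins()] result.
#' @param psms the [psm_set()] the groups were built from.
#' @param specs modification specs.
#' @return data.frame of class `protein_label_status`: `leader`,
#'   `species`, `status` (observation-level), `status_sequence`,
#'   `n_labeled_obs`, `n_unlabeled_obs`.
#' @export
classify_protein_labels <- function(groups, psms,
                                    specs = silac_modification_specs()) {
  stopifnot(inherits(groups, "protein_groups"), inherits(psms, "psm_set"))
  has_label <- psm_has_label(psms, specs)
  pep_groups <- strsplit(groups$peptides, ";", fixed = TRUE)
  if (any(lengths(pep_groups) == 0L | !nzchar(groups$peptides)))
    stop("protein group with zero peptides")
  status_of <- function(n_lab, n_unlab) {
    if (n_lab > 0L && n_unlab == 0L) "labeled"
    else if (n_lab == 0L && n_unlab > 0L) "non_labeled"
    else "partially_labeled"
  }
  res <- lapply(seq_len(nrow(groups)), function(g) {
    in_group <- psms$peptide %in% pep_groups[[g]]
    # observation level: distinct (sequence, charge, label state)
    obs <- unique(data.frame(peptide = psms$peptide[in_group],
                             charge = psms$charge[in_group],
                             labeled = has_label[in_group],
                             stringsAsFactors = FALSE))
    n_lab_obs <- sum(obs$labeled); n_unlab_obs <- sum(!obs$labeled)
    # sequence level: a sequence is labeled if any supporting PSM is
    seq_lab <- tapply(has_label[in_group], psms$peptide[in_group], any)
    data.frame(leader = groups$leader[g], species = groups$species[g],
               status = status_of(n_lab_obs, n_unlab_obs),
               status_sequence = status_of(sum(seq_lab), sum(!seq_lab)),
               n_labeled_obs = n_lab_obs, n_unlabeled_obs = n_unlab_obs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("protein_label_status", "data.frame")
  out
}

#' SILAC audit report
#'
#' Combines the residue census and the protein label classification into
#' one report, ready for JSON serialization.
#'
#' @param psms a [psm_set()].
#' @param classes per-PSM species class.
#' @param groups a [group_proteins()] result.
#' @param specs modification specs.
#' @return List with `residue_census` and `protein_status` (status counts
#'   per species).
#' @export
silac_audit <- function(psms, classes, groups,
                        specs = silac_modification_specs()) {
  rc <- residue_census(psms, classes, specs)
  ps <- classify_protein_labels(groups, psms, specs)
  status_counts <- as.data.frame(table(species = ps$species,
                                       status = ps$status),
                                 stringsAsFactors = FALSE)
  list(residue_census = rc, protein_status = ps,
       protein_status_counts = status_counts)
}

#' @importFrom stats aggregate na.omit ave
NULL
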