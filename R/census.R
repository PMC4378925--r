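CENSUS_CLASSES <- c("human", "major_fbs", "minor_fbs", "other_bovine",
                    "orthologous", "utility")

#' Contaminant accession lists
#'
#' The FBS-profiled contaminants are split into major contaminants (the
#' top proteins by PSM abundance in the FBS profiling runs, plus proteins
#' found in residual-FBS media or plate-surface analyses) and minor
#' contaminants (the remaining profiled FBS proteins). The two sets must
#' be disjoint; their union is the full FBS list.
#'
#' @param major,minor character vectors of bovine accessions.
#' @return A `contaminant_lists` object.
#' @export
contaminant_lists <- function(major, minor = character()) {
  major <- unique(as.character(major))
  minor <- unique(as.character(minor))
  both <- intersect(major, minor)
  if (length(both))
    stop("accession(s) in both major and minor lists: ",
         paste(both, collapse = ", "))
  structure(list(major_fbs = major, minor_fbs = minor), class =
              "contaminant_lists")
}

# per-PSM species class given an index and contaminant lists
psm_species_class <- function(psms, index, lists) {
  stopifnot(inherits(psms, "psm_set"), inherits(index, "peptide_index"),
            inherits(lists, "contaminant_lists"))
  prot_lists <- split_proteins(psms$proteins)
  known <- c(index$accessions,
             grep("^DECOY_", unlist(prot_lists), value = TRUE))
  absent <- !vapply(prot_lists, function(p) all(p %in% known), logical(1))
  if (any(absent))
    stop("PSM protein(s) absent from the index's databases (database ",
         "mismatch), e.g. row ", which(absent)[1L], ": ",
         psms$proteins[which(absent)[1L]])
  pep_cls <- classify_peptide(psms$peptide, index)
  sp_of <- setNames(
    index$entries[!duplicated(accession), species],
    index$entries[!duplicated(accession), accession])
  cls <- character(nrow(psms))
  for (i in seq_len(nrow(psms))) {
    pc <- pep_cls[i]
    if (pc == "shared") { cls[i] <- "orthologous"; next }
    if (pc == "utility_only") { cls[i] <- "utility"; next }
    if (pc == "bovine_unique") {
      accs <- prot_lists[[i]]
      bov <- accs[!is.na(sp_of[accs]) & sp_of[accs] == "bovine"]
      acc <- if (length(bov)) bov[1L] else accs[1L]
      cls[i] <- if (acc %in% lists$major_fbs) "major_fbs"
        else if (acc %in% lists$minor_fbs) "minor_fbs"
        else "other_bovine"
      next
    }
    cls[i] <- "human"
  }
  factor(cls, levels = CENSUS_CLASSES)
}

#' Species census of a PSM set
#'
#' Classifies every PSM by the species specificity of its peptide: a PSM
#' on a peptide shared between human and bovine proteins is `orthologous`
#' regardless of the reported protein (the peptide identifies neither
#' species exclusively); a PSM on a bovine-unique peptide is `major_fbs`,
#' `minor_fbs` or `other_bovine` according to its resolved bovine
#' accession's contaminant-list membership; PSMs on utility-only peptides
#' are tracked separately; everything else is `human`. The class counts
#' partition the PSM set.
#'
#' @param psms a filtered [psm_set()].
#' @param index a [build_peptide_index()] covering the search database's
#'   proteomes; a PSM whose proteins are absent from the indexed
#'   databases is a database-mismatch error.
#' @param lists a [contaminant_lists()].
#' @return A `species_census`: list with `counts` (named integer over the
#'   six classes), `fractions`, `total` and `classes` (per-PSM factor).
#' @export
census_psms <- function(psms, index, lists) {
  cls <- psm_species_class(psms, index, lists)
  counts <- table(cls)
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 fractions = setNames(as.numeric(counts) /
                                        max(1L, nrow(psms)), names(counts)),
                 total = nrow(psms), classes = cls),
            class = "species_census")
}

#' @export
print.species_census <- function(x, ...) {
  cat(sprintf("<species_census> %d PSMs\n", x$total))
  for (k in names(x$counts))
    cat(sprintf("  %-12s %6d (%5.1f%%)\n", k, x$counts[k],
                100 * x$fractions[k]))
  invisible(x)
}

#' Census of protein groups by species class
#'
#' Each group is assigned one class by its leader accession's species and
#' contaminant-list membership; groups whose members span species are
#' reported separately as `ambiguous`.
#'
#' @param groups a [group_proteins()] result with `species` filled.
#' @param lists a [contaminant_lists()].
#' @return Named integer vector over `{human, major_fbs, minor_fbs,
#'   other_bovine, utility, ambiguous}` (zero-count classes included).
#' @export
census_protein_groups <- function(groups, lists) {
  stopifnot(inherits(groups, "protein_groups"),
            inherits(lists, "contaminant_lists"))
  classes <- c("human", "major_fbs", "minor_fbs", "other_bovine",
               "utility", "ambiguous")
  cls <- vapply(seq_len(nrow(groups)), function(i) {
    sp <- groups$species[i]
    if (is.na(sp)) return("ambiguous")
    if (sp == "bovine") {
      if (groups$leader[i] %in% lists$major_fbs) "major_fbs"
      else if (groups$leader[i] %in% lists$minor_fbs) "minor_fbs"
      else "other_bovine"
    } else sp
  }, "")
  tab <- table(factor(cls, levels = classes))
  setNames(as.integer(tab), names(tab))
}

#' Venn partition of human proteins across two searches
#'
#' Partitions the human-classified protein-group leaders of two search
#' results over the same spectra into database-exclusive and shared sets.
#'
#' @param groups_by_db named list of two [group_proteins()] results (with
#'   `species` filled), names being the database labels.
#' @return List with `only_in_<labelA>`, `only_in_<labelB>` and `both`
#'   (character vectors of leader accessions).
#' @export
venn_human_proteins <- function(groups_by_db) {
  stopifnot(is.list(groups_by_db), length(groups_by_db) == 2L,
            !is.null(names(groups_by_db)))
  human_leaders <- lapply(groups_by_db, function(g)
    unique(g$leader[!is.na(g$species) & g$species == "human"]))
  a <- human_leaders[[1L]]; b <- human_leaders[[2L]]
  out <- list(setdiff(a, b), setdiff(b, a), intersect(a, b))
  names(out) <- c(paste0("only_in_", names(groups_by_db)[1L]),
                  paste0("only_in_", names(groups_by_db)[2L]), "both")
  out
}
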