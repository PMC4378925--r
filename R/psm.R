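PSM_COLUMNS <- c("spectrum_file", "scan", "charge", "rank", "peptide",
                 "modifications", "xcorr", "q_value", "pep", "proteins",
                 "search_db", "is_decoy")

# vendor export column names -> generic model
PD_COLUMN_MAP <- c(
  "Spectrum File" = "spectrum_file",
  "First Scan" = "scan",
  "Charge" = "charge",
  "Rank" = "rank",
  "Sequence" = "peptide",
  "Modifications" = "modifications",
  "XCorr" = "xcorr",
  "Percolator q-Value" = "q_value",
  "Percolator PEP" = "pep",
  "Protein Accessions" = "proteins"
)

#' Construct a PSM set
#'
#' A `psm_set` is a data.frame of peptide-spectrum matches, one row per
#' PSM, with the columns of the generic dialect: `spectrum_file`, `scan`,
#' `charge`, `rank`, `peptide`, `modifications` (semicolon-separated
#' tokens such as `"M3(Oxidation)"`), `xcorr`, `q_value`, `pep`,
#' `proteins` (semicolon-separated accessions), `search_db`, `is_decoy`.
#' A spectrum is identified by (`spectrum_file`, `scan`); charge is
#' deliberately not part of the key so re-searches of the same spectrum
#' join across databases.
#'
#' @param df data.frame with at least `spectrum_file`, `scan`, `charge`,
#'   `peptide`, `proteins`; missing optional columns are filled with
#'   defaults (`rank` 1, empty `modifications`, `NA` scores, `is_decoy`
#'   `FALSE`).
#' @return A `psm_set` (data.frame subclass).
#' @export
psm_set <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("spectrum_file", "scan", "charge", "peptide", "proteins")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required PSM column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$rank)) df$rank <- 1L
  if (is.null(df$modifications)) df$modifications <- ""
  for (col in c("xcorr", "q_value", "pep"))
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (is.null(df$search_db)) df$search_db <- NA_character_
  if (is.null(df$is_decoy)) df$is_decoy <- FALSE
  df$scan <- as.integer(df$scan)
  df$charge <- as.integer(df$charge)
  df$rank <- as.integer(df$rank)
  df$modifications[is.na(df$modifications)] <- ""
  for (col in c("xcorr", "q_value", "pep")) df[[col]] <- as.numeric(df[[col]])
  df$is_decoy <- as.logical(df$is_decoy)
  bad_q <- !is.na(df$q_value) & (df$q_value < 0 | df$q_value > 1)
  bad_p <- !is.na(df$pep) & (df$pep <= 0 | df$pep > 1)
  if (any(bad_q)) stop("q_value outside [0,1] at row(s) ",
                       paste(head(which(bad_q), 5L), collapse = ", "))
  if (any(bad_p)) stop("pep outside (0,1] at row(s) ",
                       paste(head(which(bad_p), 5L), collapse = ", "))
  df <- df[, c(PSM_COLUMNS, setdiff(names(df), PSM_COLUMNS))]
  class(df) <- c("psm_set", "data.frame")
  df
}

#' Read a PSM table from delimited text
#'
#' @param path tab-separated file with a header row.
#' @param dialect `"generic"` (the package's own column names) or
#'   `"pd_export"` (a Proteome Discoverer-style spreadsheet export, whose
#'   vendor column names are mapped onto the generic model).
#' @param required extra generic columns that must be present (e.g.
#'   `"pep"` for a workflow comparing posterior error probabilities); a
#'   missing one is an explicit error rather than a silent default.
#' @return A [psm_set()].
#' @export
read_psm_table <- function(path, dialect = c("generic", "pd_export"),
                           required = character()) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  if (dialect == "pd_export") {
    hit <- names(df) %in% names(PD_COLUMN_MAP)
    names(df)[hit] <- PD_COLUMN_MAP[names(df)[hit]]
  }
  need <- c("spectrum_file", "scan", "charge", "peptide", "proteins",
            required)
  miss <- setdiff(unique(need), names(df))
  if (length(miss))
    stop("PSM table ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(df$modifications)) df$modifications <- as.character(df$modifications)
  psms <- psm_set(df)
  # fail early on unparsable modification strings, reporting the row
  parse_modifications(psms$modifications, psms$peptide)
  psms
}

#' Write a PSM set as TSV (generic dialect)
#' @param psms a `psm_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  data.table::fwrite(as.data.frame(psms)[, PSM_COLUMNS], path, sep = "\t")
  invisible(path)
}

# known modification masses (Da), as printed in typical search settings
MOD_DELTAS <- c(Oxidation = 15.99, Carbamidomethyl = 57.02,
                Arg10 = 10.01, Lys8 = 8.01, Pro6 = 6.01)

#' Parse modification strings
#'
#' Tokens are semicolon-separated `"<residue><pos>(<name>)"` with 1-based
#' positions (e.g. `"M3(Oxidation)"` is an oxidation at 0-based residue
#' index 2), or `"N-Term(<name>)"` / `"C-Term(<name>)"` for terminal
#' modifications. The residue letter must match the peptide at that
#' position.
#'
#' @param modifications character vector of modification strings.
#' @param peptides peptide sequences, same length.
#' @return List (one element per PSM) of data.frames with columns
#'   `position` (0-based residue index, `NA` for a terminus), `terminus`
#'   (`NA`, `"N"` or `"C"`), `residue`, `name`, `delta_mass` (`NA` for
#'   names without a registered mass).
#' @export
parse_modifications <- function(modifications, peptides) {
  stopifnot(length(modifications) == length(peptides))
  lapply(seq_along(modifications), function(i) {
    s <- modifications[i]
    empty <- data.frame(position = integer(), terminus = character(),
                        residue = character(), name = character(),
                        delta_mass = numeric(), stringsAsFactors = FALSE)
    if (is.na(s) || !nzchar(trimws(s))) return(empty)
    toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    toks <- toks[nzchar(toks)]
    out <- lapply(toks, function(tok) {
      m <- regmatches(tok, regexec("^([A-Z])(\\d+)\\(([^)]+)\\)$", tok))[[1]]
      if (length(m) == 4L) {
        pos1 <- as.integer(m[3])
        if (pos1 < 1L || pos1 > nchar(peptides[i]))
          stop("modification position out of range in '", tok,
               "' at row ", i)
        res <- substr(peptides[i], pos1, pos1)
        if (res != m[2])
          stop("modification residue mismatch in '", tok, "' at row ", i,
               ": peptide has ", res, " at position ", pos1)
        return(data.frame(position = pos1 - 1L, terminus = NA_character_,
                          residue = m[2], name = m[4],
                          delta_mass = unname(MOD_DELTAS[m[4]]),
                          stringsAsFactors = FALSE))
      }
      m <- regmatches(tok, regexec("^([NC])-[Tt]erm\\(([^)]+)\\)$", tok))[[1]]
      if (length(m) == 3L)
        return(data.frame(position = NA_integer_, terminus = m[2],
                          residue = NA_character_, name = m[3],
                          delta_mass = unname(MOD_DELTAS[m[3]]),
                          stringsAsFactors = FALSE))
      stop("unparsable modification token '", tok, "' at row ", i)
    })
    do.call(rbind, out)
  })
}

#' PSM filter criteria
#'
#' The post-search filter applied to exported PSM tables: a q-value
#' ceiling, charge-state-dependent XCorr minima, top-rank-only, and
#' protein-level criteria (minimum unique peptides and a protein score
#' floor) applied after grouping.
#'
#' @param q_max maximum q-value (default 0.01).
#' @param xcorr_min_by_charge named numeric vector with entries for
#'   charges `"1"`..`"7"` plus `"over7"`.
#' @param top_rank_only keep only rank-1 PSMs (default `TRUE`).
#' @param min_unique_peptides_per_protein protein-level minimum (default 1).
#' @param protein_score_min protein-level score floor (default 10). When
#'   the input table carries no vendor protein score, the sum of retained
#'   PSM XCorr per group is used as a documented proxy.
#' @param require_high_confidence honor a vendor `confidence` column
#'   (keep rows marked `"High"`) when present; ignored otherwise.
#' @return A `filter_criteria` list.
#' @export
filter_criteria <- function(q_max = 0.01,
                            xcorr_min_by_charge = c(`1` = 1.5, `2` = 2,
                                                    `3` = 2.25, `4` = 2.5,
                                                    `5` = 2.75, `6` = 3,
                                                    `7` = 3.2, over7 = 3.4),
                            top_rank_only = TRUE,
                            min_unique_peptides_per_protein = 1L,
                            protein_score_min = 10,
                            require_high_confidence = FALSE) {
  stopifnot(q_max >= 0, all(xcorr_min_by_charge >= 0),
            all(c(as.character(1:7), "over7") %in%
                  names(xcorr_min_by_charge)))
  structure(list(q_max = q_max, xcorr_min_by_charge = xcorr_min_by_charge,
                 top_rank_only = isTRUE(top_rank_only),
                 min_unique_peptides_per_protein =
                   as.integer(min_unique_peptides_per_protein),
                 protein_score_min = protein_score_min,
                 require_high_confidence = isTRUE(require_high_confidence)),
            class = "filter_criteria")
}

xcorr_threshold <- function(charge, criteria) {
  key <- ifelse(charge > 7L, "over7", as.character(charge))
  unname(criteria$xcorr_min_by_charge[key])
}

#' Filter a PSM set
#'
#' Retains a PSM iff its q-value is at most `q_max`, its XCorr meets the
#' threshold for its charge state, and (when `top_rank_only`) it is the
#' rank-1 match for its spectrum. Protein-level criteria are applied after
#' grouping (see [group_proteins()]). Row order is preserved.
#'
#' @param psms a [psm_set()].
#' @param criteria a [filter_criteria()].
#' @return The retained `psm_set`, in stable order.
#' @export
filter_psms <- function(psms, criteria = filter_criteria()) {
  stopifnot(inherits(psms, "psm_set"), inherits(criteria, "filter_criteria"))
  if (nrow(psms) == 0L) return(psms)
  if (any(psms$charge < 1L)) stop("PSM with charge < 1")
  keep <- !is.na(psms$q_value) & psms$q_value <= criteria$q_max &
    !is.na(psms$xcorr) & psms$xcorr >= xcorr_threshold(psms$charge, criteria)
  if (criteria$top_rank_only) keep <- keep & psms$rank == 1L
  if (criteria$require_high_confidence && !is.null(psms$confidence))
    keep <- keep & psms$confidence == "High"
  psms[keep, , drop = FALSE]
}

split_proteins <- function(proteins) {
  lapply(strsplit(as.character(proteins), ";", fixed = TRUE), trimws)
}

#' Group proteins by greedy maximum parsimony
#'
#' Proteins with identical explained-peptide sets are merged into one
#' group; groups are then selected greedily, each step taking the group
#' explaining the most still-unexplained peptides (ties broken by more
#' total peptides, then lexicographically smallest leader accession), and
#' each peptide is assigned to exactly one group. This yields the protein
#' groups a parsimony-based inference engine reports.
#'
#' @param psms a filtered [psm_set()].
#' @param species optional named character vector mapping accession to
#'   species; a group whose members span species is `"ambiguous"`.
#' @param criteria optional [filter_criteria()]; when given, groups
#'   failing the protein-level criteria (minimum unique peptides, protein
#'   score floor using summed retained-PSM XCorr as the score proxy) are
#'   dropped.
#' @return data.frame of class `protein_groups`: `leader`, `members` and
#'   `peptides` (semicolon-joined), `n_peptides`, `psm_count`,
#'   `protein_score`, `species`.
#' @export
group_proteins <- function(psms, species = NULL, criteria = NULL) {
  stopifnot(inherits(psms, "psm_set"))
  empty <- data.frame(leader = character(), members = character(),
                      peptides = character(), n_peptides = integer(),
                      psm_count = integer(), protein_score = numeric(),
                      species = character(), stringsAsFactors = FALSE)
  class(empty) <- c("protein_groups", "data.frame")
  if (nrow(psms) == 0L) return(empty)
  prot_lists <- split_proteins(psms$proteins)
  long <- data.frame(
    peptide = rep(psms$peptide, lengths(prot_lists)),
    accession = unlist(prot_lists),
    stringsAsFactors = FALSE)
  long <- unique(long)
  pepset_of <- split(long$peptide, long$accession)
  pepset_of <- lapply(pepset_of, function(p) sort(unique(p)))
  # merge proteins with identical peptide sets
  key <- vapply(pepset_of, paste, "", collapse = "\r")
  members_of <- split(names(pepset_of), key)
  members_of <- lapply(members_of, sort)
  grp_peps <- lapply(members_of, function(m) pepset_of[[m[1]]])
  leaders <- vapply(members_of, `[`, "", 1L)
  # greedy set cover over peptides
  unexplained <- unique(long$peptide)
  order_out <- integer()
  assigned <- list()
  active <- seq_along(grp_peps)
  while (length(unexplained) && length(active)) {
    gain <- vapply(active, function(g)
      sum(grp_peps[[g]] %in% unexplained), integer(1))
    best_gain <- max(gain)
    if (best_gain == 0L) break
    cand <- active[gain == best_gain]
    if (length(cand) > 1L) {
      sz <- lengths(grp_peps)[cand]
      cand <- cand[sz == max(sz)]
      cand <- cand[order(leaders[cand])][1L]
    }
    newly <- intersect(grp_peps[[cand]], unexplained)
    assigned[[length(assigned) + 1L]] <- newly
    order_out <- c(order_out, cand)
    unexplained <- setdiff(unexplained, newly)
    active <- setdiff(active, cand)
  }
  pep_to_group <- rep(seq_along(assigned), lengths(assigned))
  names(pep_to_group) <- unlist(assigned)
  psm_group <- pep_to_group[psms$peptide]
  xc <- ifelse(is.na(psms$xcorr), 0, psms$xcorr)
  groups <- data.frame(
    leader = leaders[order_out],
    members = vapply(members_of[order_out], paste, "", collapse = ";"),
    peptides = vapply(assigned, paste, "", collapse = ";"),
    n_peptides = lengths(assigned),
    psm_count = vapply(seq_along(assigned), function(g)
      sum(psm_group == g, na.rm = TRUE), integer(1)),
    protein_score = vapply(seq_along(assigned), function(g)
      sum(xc[!is.na(psm_group) & psm_group == g]), numeric(1)),
    stringsAsFactors = FALSE)
  if (!is.null(species)) {
    groups$species <- vapply(members_of[order_out], function(m) {
      sp <- unique(stats::na.omit(species[m]))
      if (length(sp) == 1L) sp else if (length(sp) > 1L) "ambiguous"
      else NA_character_
    }, "")
  } else groups$species <- NA_character_
  if (!is.null(criteria)) {
    keep <- groups$n_peptides >= criteria$min_unique_peptides_per_protein &
      groups$protein_score >= criteria$protein_score_min
    groups <- groups[keep, , drop = FALSE]
  }
  rownames(groups) <- NULL
  class(groups) <- c("protein_groups", "data.frame")
  groups
}

#' Estimate q-values by target-decoy counting
#'
#' Simple target-decoy false discovery rate estimation used as plumbing
#' for synthetic end-to-end runs (a stand-in for the semi-supervised
#' rescoring a production pipeline would use): at each score threshold t,
#' FDR(t) = #\{decoys >= t\} / #\{targets >= t\}; a PSM's q-value is the
#' minimum FDR over all thresholds at or below its score, so q is
#' monotone non-increasing in score.
#'
#' @param psms a [psm_set()] with `xcorr` and `is_decoy` set; decoys must
#'   be present.
#' @return The same `psm_set` with `q_value` filled for every row.
#' @export
estimate_q_values <- function(psms) {
  stopifnot(inherits(psms, "psm_set"))
  if (!any(psms$is_decoy))
    stop("no decoy PSMs present; q-values undefined")
  if (any(is.na(psms$xcorr))) stop("xcorr required for q-value estimation")
  ord <- order(psms$xcorr, decreasing = TRUE)
  dec <- psms$is_decoy[ord]
  n_dec <- cumsum(dec)
  n_tgt <- cumsum(!dec)
  fdr <- ifelse(n_tgt == 0L, 1, pmin(1, n_dec / pmax(n_tgt, 1L)))
  # ties share the FDR computed at the last PSM of the tied score
  sc <- psms$xcorr[ord]
  fdr <- fdr[ave(seq_along(sc), sc, FUN = max)]
  q <- rev(cummin(rev(fdr)))
  psms$q_value[ord] <- q
  psms
}
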