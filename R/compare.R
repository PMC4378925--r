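REGION_LEVELS <- c("grey", "blue", "red", "green", "a_only_unmatched")

# best PSM per spectrum: lowest PEP across charges; identical
# (file, scan, charge) duplicates are an error
best_per_spectrum <- function(psms, label) {
  stopifnot(inherits(psms, "psm_set"))
  df <- as.data.frame(psms)
  df <- df[!df$is_decoy, , drop = FALSE]
  if (any(is.na(df$pep)))
    stop("PEP required for search comparison but missing in ", label)
  key3 <- paste(df$spectrum_file, df$scan, df$charge, sep = "\r")
  if (anyDuplicated(key3))
    stop("duplicate spectrum (file, scan, charge) in ", label,
         " after top-rank filtering: ",
         key3[duplicated(key3)][1L])
  ord <- order(df$pep)
  df <- df[ord, , drop = FALSE]
  key2 <- paste(df$spectrum_file, df$scan, sep = "\r")
  df[!duplicated(key2), , drop = FALSE]
}

#' Compare one spectrum set searched against two databases
#'
#' Joins the two PSM sets on spectrum identity (file, scan; the best PSM
#' by PEP is used when a spectrum carries matches at several charges) and
#' classifies each spectrum by the change in -log10 posterior error
#' probability between search A and search B:
#' \itemize{
#'   \item grey: present in both, |delta| < `delta_threshold` — the PSM is
#'     essentially unchanged by the database switch;
#'   \item red: delta >= threshold — search B explains the spectrum with a
#'     markedly lower error probability (under a composite database this
#'     is the signature of a contaminant spectrum forced onto a wrong
#'     sequence by a database lacking its true protein);
#'   \item green: delta <= -threshold — the reverse;
#'   \item blue: matched in B only;
#'   \item a_only_unmatched: matched in A only.
#' }
#'
#' @param psms_a,psms_b [psm_set()]s over the same spectra, PEP present.
#' @param delta_threshold region half-width on the -log10 PEP scale
#'   (default 0.7).
#' @param pep_floor PEP values below this are floored before taking logs,
#'   avoiding infinities (default 1e-10).
#' @param index optional [build_peptide_index()]; when given, each side's
#'   peptide species class is recorded and `species_switch` flags spectra
#'   whose resolved species differs between searches.
#' @return data.frame of class `search_comparison`: `spectrum_file`,
#'   `scan`, `neglogpep_a`, `neglogpep_b`, `delta`, `region`,
#'   `peptide_a`, `peptide_b`, `species_a`, `species_b`,
#'   `species_switch`.
#' @export
compare_searches <- function(psms_a, psms_b, delta_threshold = 0.7,
                             pep_floor = 1e-10, index = NULL) {
  a <- best_per_spectrum(psms_a, "set A")
  b <- best_per_spectrum(psms_b, "set B")
  key_a <- paste(a$spectrum_file, a$scan, sep = "\r")
  key_b <- paste(b$spectrum_file, b$scan, sep = "\r")
  keys <- union(key_a, key_b)
  ia <- match(keys, key_a); ib <- match(keys, key_b)
  nlp <- function(p) -log10(pmax(p, pep_floor))
  neglogpep_a <- ifelse(is.na(ia), NA_real_, nlp(a$pep[ia]))
  neglogpep_b <- ifelse(is.na(ib), NA_real_, nlp(b$pep[ib]))
  delta <- neglogpep_b - neglogpep_a
  region <- ifelse(is.na(ia), "blue",
            ifelse(is.na(ib), "a_only_unmatched",
            ifelse(abs(delta) < delta_threshold, "grey",
            ifelse(delta > 0, "red", "green"))))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    spectrum_file = vapply(parts, `[`, "", 1L),
    scan = as.integer(vapply(parts, `[`, "", 2L)),
    neglogpep_a = neglogpep_a, neglogpep_b = neglogpep_b, delta = delta,
    region = factor(region, levels = REGION_LEVELS),
    peptide_a = ifelse(is.na(ia), NA_character_, a$peptide[ia]),
    peptide_b = ifelse(is.na(ib), NA_character_, b$peptide[ib]),
    pep_a = ifelse(is.na(ia), NA_real_, a$pep[ia]),
    pep_b = ifelse(is.na(ib), NA_real_, b$pep[ib]),
    stringsAsFactors = FALSE)
  if (!is.null(index)) {
    out$species_a <- ifelse(is.na(ia), NA_character_,
                            classify_peptide(out$peptide_a, index))
    out$species_b <- ifelse(is.na(ib), NA_character_,
                            classify_peptide(out$peptide_b, index))
    out$species_switch <- !is.na(out$species_a) & !is.na(out$species_b) &
      out$species_a != out$species_b
  } else {
    out$species_a <- out$species_b <- NA_character_
    out$species_switch <- NA
  }
  class(out) <- c("search_comparison", "data.frame")
  out
}

#' Region counts of a search comparison
#' @param comparison a [compare_searches()] result.
#' @return Named integer vector over the five regions.
#' @export
region_counts <- function(comparison) {
  stopifnot(inherits(comparison, "search_comparison"))
  tab <- table(comparison$region)
  setNames(as.integer(tab), names(tab))
}

#' Scatter plot of -logPEP pairs colored by region
#'
#' @param comparison a [compare_searches()] result.
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::plot()].
#' @return The comparison, invisibly.
#' @export
#' @importFrom graphics plot abline legend
plot_comparison <- function(comparison, xlab = "-logPEP (A)",
                            ylab = "-logPEP (B)", ...) {
  stopifnot(inherits(comparison, "search_comparison"))
  cols <- c(grey = "grey60", blue = "blue3", red = "red3",
            green = "green4", a_only_unmatched = "orange3")
  x <- ifelse(is.na(comparison$neglogpep_a), 0, comparison$neglogpep_a)
  y <- ifelse(is.na(comparison$neglogpep_b), 0, comparison$neglogpep_b)
  plot(x, y, col = cols[as.character(comparison$region)], pch = 20,
       xlab = xlab, ylab = ylab, ...)
  abline(0, 1, lty = 2)
  legend("topleft", legend = names(cols), col = cols, pch = 20, bty = "n")
  invisible(comparison)
}
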