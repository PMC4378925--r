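#' Tryptic digestion parameters
#'
#' Fully-tryptic in-silico digestion: cleavage C-terminal to K or R, by
#' default suppressed when the next residue is proline (the classic
#' trypsin rule), with up to `max_missed_cleavages` internal missed
#' cleavage sites.
#'
#' @param enzyme only `"trypsin"` is supported.
#' @param max_missed_cleavages maximum internal missed cleavage sites
#'   (default 2, the value used for the search settings this package
#'   post-processes).
#' @param min_length,max_length retained peptide length bounds, in
#'   residues. Defaults 6 and 50 cover the observable range of a typical
#'   ion-trap shotgun experiment.
#' @param cleave_before_proline if `TRUE`, cleavage before proline is
#'   allowed (KP/RP sites cut).
#' @param equate_il if `TRUE`, isoleucine and leucine are folded together
#'   (I -> L) when peptides are canonicalized for indexing, since CID
#'   fragmentation cannot distinguish them.
#' @return A `digestion_params` list.
#' @export
digestion_params <- function(enzyme = "trypsin", max_missed_cleavages = 2L,
                             min_length = 6L, max_length = 50L,
                             cleave_before_proline = FALSE,
                             equate_il = FALSE) {
  enzyme <- match.arg(enzyme, "trypsin")
  max_missed_cleavages <- as.integer(max_missed_cleavages)
  min_length <- as.integer(min_length)
  max_length <- as.integer(max_length)
  stopifnot(max_missed_cleavages >= 0L, min_length > 0L,
            min_length <= max_length,
            is.logical(cleave_before_proline), is.logical(equate_il))
  structure(list(enzyme = enzyme,
                 max_missed_cleavages = max_missed_cleavages,
                 min_length = min_length, max_length = max_length,
                 cleave_before_proline = cleave_before_proline,
                 equate_il = equate_il),
            class = "digestion_params")
}

canonical_peptide <- function(peptide, params) {
  if (isTRUE(params$equate_il)) gsub("I", "L", peptide, fixed = TRUE)
  else peptide
}

# 1-based positions p such that cleavage occurs between p and p+1
tryptic_sites <- function(chars, cleave_before_proline) {
  n <- length(chars)
  if (n < 2L) return(integer())
  pos <- which(chars[-n] %in% c("K", "R"))
  if (!cleave_before_proline) pos <- pos[chars[pos + 1L] != "P"]
  pos
}

#' In-silico tryptic digestion of one protein sequence
#'
#' Returns every fully-tryptic peptide with between 0 and
#' `max_missed_cleavages` internal missed cleavage sites whose length lies
#' within the configured bounds. Protein N- and C-terminal peptides are
#' included; ambiguous residues pass through unchanged.
#'
#' @param sequence uppercase amino-acid string.
#' @param params a [digestion_params()] object.
#' @return data.frame with columns `peptide`, `start` (0-based offset in
#'   the parent), `length`, `missed_cleavages`.
#' @export
digest <- function(sequence, params = digestion_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            nzchar(sequence))
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  bounds <- c(0L, tryptic_sites(chars, params$cleave_before_proline), n)
  nb <- length(bounds)
  out_start <- integer(); out_end <- integer(); out_mc <- integer()
  for (mc in 0:params$max_missed_cleavages) {
    i <- seq_len(nb - 1L - mc)
    if (!length(i)) break
    out_start <- c(out_start, bounds[i])
    out_end <- c(out_end, bounds[i + mc + 1L])
    out_mc <- c(out_mc, rep.int(mc, length(i)))
  }
  len <- out_end - out_start
  keep <- len >= params$min_length & len <= params$max_length
  if (!any(keep))
    return(data.frame(peptide = character(), start = integer(),
                      length = integer(), missed_cleavages = integer(),
                      stringsAsFactors = FALSE))
  data.frame(
    peptide = substring(sequence, out_start[keep] + 1L, out_end[keep]),
    start = out_start[keep],
    length = len[keep],
    missed_cleavages = out_mc[keep],
    stringsAsFactors = FALSE
  )
}

#' Build a peptide-to-parent index across proteomes
#'
#' Digests every protein of the supplied databases and indexes each
#' peptide by its full set of (accession, species) parents. This is the
#' substrate for classifying peptides as human-unique, bovine-unique or
#' shared between species (orthologous): a peptide whose exact sequence
#' occurs in proteins of both species cannot identify either species
#' exclusively.
#'
#' @param dbs a `sequence_db` or list of them (species-tagged).
#' @param params a [digestion_params()] object.
#' @return A `peptide_index`: list with `entries` (data.table: peptide,
#'   accession, species, start, missed_cleavages), `species_map`
#'   (data.table keyed by peptide with logical has_human / has_bovine /
#'   has_utility), `accessions` (all indexed protein accessions) and
#'   `params`.
#' @export
build_peptide_index <- function(dbs, params = digestion_params()) {
  if (inherits(dbs, "sequence_db")) dbs <- list(dbs)
  stopifnot(all(vapply(dbs, inherits, logical(1), "sequence_db")))
  records <- do.call(rbind, lapply(dbs, `[[`, "records"))
  pieces <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    d <- digest(records$sequence[i], params)
    if (nrow(d)) {
      d$accession <- records$accession[i]
      d$species <- records$species[i]
      pieces[[i]] <- d
    }
  }
  entries <- data.table::rbindlist(pieces)
  if (nrow(entries) == 0L)
    entries <- data.table::data.table(peptide = character(),
                                      start = integer(), length = integer(),
                                      missed_cleavages = integer(),
                                      accession = character(),
                                      species = character())
  entries[, peptide := canonical_peptide(peptide, params)]
  data.table::setcolorder(entries, c("peptide", "accession", "species",
                                     "start", "missed_cleavages", "length"))
  species_map <- entries[, .(
    has_human = any(species == "human"),
    has_bovine = any(species == "bovine"),
    has_utility = any(species == "utility")
  ), by = peptide]
  data.table::setkey(species_map, peptide)
  data.table::setkey(entries, peptide)
  structure(list(entries = entries, species_map = species_map,
                 accessions = unique(records$accession), params = params),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("<peptide_index> %d peptides, %d parent entries, %d proteins\n",
              nrow(x$species_map), nrow(x$entries), length(x$accessions)))
  cat(sprintf("  shared human/bovine: %d\n",
              sum(x$species_map$has_human & x$species_map$has_bovine)))
  invisible(x)
}

#' Classify a peptide's species specificity
#'
#' @param peptide_sequence peptide string(s); canonicalized with the
#'   index's I/L setting before lookup.
#' @param index a [build_peptide_index()] result.
#' @return character vector over `{human_unique, bovine_unique, shared,
#'   utility_only, unknown}`. `shared` means the sequence occurs in both a
#'   human and a bovine protein; `unknown` means no indexed protein yields
#'   the peptide.
#' @export
classify_peptide <- function(peptide_sequence, index) {
  stopifnot(inherits(index, "peptide_index"))
  pep <- canonical_peptide(as.character(peptide_sequence), index$params)
  m <- index$species_map[data.table::data.table(peptide = pep),
                         on = "peptide"]
  cls <- rep("unknown", length(pep))
  hh <- !is.na(m$has_human) & m$has_human
  bb <- !is.na(m$has_bovine) & m$has_bovine
  uu <- !is.na(m$has_utility) & m$has_utility
  cls[hh & bb] <- "shared"
  cls[hh & !bb] <- "human_unique"
  cls[!hh & bb] <- "bovine_unique"
  cls[!hh & !bb & uu] <- "utility_only"
  cls
}

#' Write a peptide index as TSV
#'
#' Columns: peptide, accession, species, start, missed_cleavages.
#'
#' @param index a `peptide_index`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_index <- function(index, path) {
  stopifnot(inherits(index, "peptide_index"))
  data.table::fwrite(
    index$entries[, c("peptide", "accession", "species", "start",
                      "missed_cleavages")],
    path, sep = "\t")
  invisible(path)
}
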