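#' @import data.table
#' @importFrom stats rnorm runif rbinom setNames plogis
#' @importFrom utils head tail
NULL

VALID_SPECIES <- c("human", "bovine", "utility")
# standard 20 amino acids plus ambiguity codes tolerated in UniProt entries
AA_STRICT <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA_TOLERATED <- c(AA_STRICT, "B", "J", "X", "Z", "U")

#' Construct a protein sequence database
#'
#' A `sequence_db` is the in-memory representation of a protein FASTA
#' database: one record per protein with accession, description, species
#' tag and source label, plus provenance (`components`) recording which
#' source databases contributed how many entries. Composite search
#' databases (human + contaminant sequences) are built by merging such
#' objects with [merge_databases()].
#'
#' @param accession character vector of unique accessions.
#' @param sequence character vector of uppercase amino-acid sequences.
#'   Ambiguity codes B, J, X, Z and U are tolerated with a warning;
#'   trailing `*` stop characters are stripped.
#' @param species one of `"human"`, `"bovine"`, `"utility"`; recycled.
#' @param description free-text descriptions (default empty).
#' @param name database name.
#' @param source source-database label recorded in provenance.
#' @return An object of class `sequence_db` with elements `name`,
#'   `records` (data.frame: accession, description, species, sequence,
#'   source_db) and `components` (data.frame: source, n).
#' @export
sequence_database <- function(accession, sequence, species,
                              description = "", name = "db",
                              source = name) {
  accession <- as.character(accession)
  sequence <- as.character(sequence)
  stopifnot(length(accession) == length(sequence))
  if (anyDuplicated(accession)) {
    dup <- unique(accession[duplicated(accession)])
    stop("duplicate accession(s): ", paste(dup, collapse = ", "))
  }
  species <- match.arg(species, VALID_SPECIES)
  sequence <- toupper(sequence)
  # strip terminal stop codons, warn on ambiguity codes
  has_stop <- grepl("\\*+$", sequence)
  if (any(has_stop)) sequence <- sub("\\*+$", "", sequence)
  if (length(sequence) && any(!nzchar(sequence)))
    stop("empty sequence for accession(s): ",
         paste(accession[!nzchar(sequence)], collapse = ", "))
  bad <- vapply(strsplit(sequence, ""), function(ch)
    any(!ch %in% AA_TOLERATED), logical(1))
  if (any(bad))
    stop("invalid residue characters in accession(s): ",
         paste(accession[bad], collapse = ", "))
  ambig <- vapply(strsplit(sequence, ""), function(ch)
    any(ch %in% c("B", "J", "X", "Z", "U")), logical(1))
  if (any(ambig))
    warning(sum(ambig), " sequence(s) contain ambiguity codes (B/J/X/Z/U)")
  records <- data.frame(
    accession = accession,
    description = rep_len(as.character(description), length(accession)),
    species = rep_len(species, length(accession)),
    sequence = sequence,
    source_db = rep_len(as.character(source), length(accession)),
    stringsAsFactors = FALSE
  )
  new_sequence_db(name, records,
                  data.frame(source = source, n = nrow(records),
                             stringsAsFactors = FALSE))
}

new_sequence_db <- function(name, records, components) {
  structure(list(name = name, records = records, components = components),
            class = "sequence_db")
}

#' @export
print.sequence_db <- function(x, ...) {
  cat(sprintf("<sequence_db '%s'> %d entries\n", x$name, nrow(x$records)))
  sp <- table(x$records$species)
  cat("  species:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "),
      "\n")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  component %s: %d entries\n",
                x$components$source[i], x$components$n[i]))
  invisible(x)
}

#' @export
length.sequence_db <- function(x) nrow(x$records)

#' Read a protein FASTA file
#'
#' Accessions are parsed from the header line: for UniProt-style headers
#' (`db|ACCESSION|NAME ...`) the middle pipe-delimited field is used,
#' otherwise the first whitespace-delimited token. Record order is
#' preserved. An entry with no sequence lines or a duplicated accession is
#' an error.
#'
#' @param path FASTA file path.
#' @param species species tag applied to every record.
#' @param source source-database label (default: file name).
#' @param name database name (default: `source`).
#' @return A [sequence_database()] object.
#' @export
read_fasta <- function(path, species, source = basename(path),
                       name = source) {
  species <- match.arg(species, VALID_SPECIES)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    return(new_sequence_db(name,
      data.frame(accession = character(), description = character(),
                 species = character(), sequence = character(),
                 source_db = character(), stringsAsFactors = FALSE),
      data.frame(source = source, n = 0L, stringsAsFactors = FALSE)))
  }
  widths <- Biostrings::width(aa)
  if (any(widths == 0L))
    stop("FASTA entry with empty sequence at index ",
         paste(which(widths == 0L), collapse = ", "), " in ", path)
  headers <- names(aa)
  first_tok <- sub("\\s.*$", "", headers)
  acc <- ifelse(grepl("^[^|]+\\|[^|]+\\|", first_tok),
                vapply(strsplit(first_tok, "|", fixed = TRUE), `[`, "", 2L),
                first_tok)
  if (any(!nzchar(acc)))
    stop("malformed FASTA header at index ",
         paste(which(!nzchar(acc)), collapse = ", "), " in ", path)
  desc <- sub("^\\S*\\s*", "", headers)
  suppressWarnings(
    sequence_database(acc, as.character(aa), species = species,
                      description = desc, name = name, source = source))
}

#' Write a database to FASTA
#'
#' Headers are `accession description`; sequences wrapped at 60 columns.
#'
#' @param db a `sequence_db`.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path, width = 60L) {
  stopifnot(inherits(db, "sequence_db"))
  aa <- Biostrings::AAStringSet(db$records$sequence)
  hdr <- ifelse(nzchar(db$records$description),
                paste(db$records$accession, db$records$description),
                db$records$accession)
  names(aa) <- hdr
  Biostrings::writeXStringSet(aa, path, width = width)
  invisible(path)
}

#' Merge sequence databases into a composite database
#'
#' Concatenates databases in argument order; the entry count of the result
#' is the sum of the parts and provenance records every part. Composite
#' search databases (e.g. human + bovine, or human + profiled FBS
#' contaminant sequences) are built this way.
#'
#' @param parts list of `sequence_db` objects.
#' @param name name for the merged database.
#' @param collision what to do when accessions collide across parts:
#'   `"suffix"` (default) disambiguates by appending the source label,
#'   `"error"` aborts listing the colliding accessions.
#' @return A `sequence_db`.
#' @export
merge_databases <- function(parts, name, collision = c("suffix", "error")) {
  collision <- match.arg(collision)
  stopifnot(length(parts) >= 1L,
            all(vapply(parts, inherits, logical(1), "sequence_db")))
  records <- do.call(rbind, lapply(parts, `[[`, "records"))
  if (anyDuplicated(records$accession)) {
    dup <- unique(records$accession[duplicated(records$accession)])
    if (collision == "error")
      stop("accession collision(s) across parts: ",
           paste(dup, collapse = ", "))
    clash <- records$accession %in% dup
    # keep the first occurrence verbatim, suffix the rest with their source
    first <- !duplicated(records$accession)
    fix <- clash & !first
    records$accession[fix] <-
      paste(records$accession[fix], records$source_db[fix], sep = "|")
    if (anyDuplicated(records$accession))
      stop("accession collision unresolved even after suffixing: ",
           paste(unique(records$accession[duplicated(records$accession)]),
                 collapse = ", "))
    warning("suffix-disambiguated ", sum(fix), " colliding accession(s)")
  }
  components <- do.call(rbind, lapply(parts, `[[`, "components"))
  rownames(records) <- rownames(components) <- NULL
  new_sequence_db(name, records, components)
}

#' Subset a proteome to a contaminant accession list
#'
#' Builds the profiled-FBS database: the subset of the full bovine proteome
#' whose accessions were actually identified in FBS profiling runs, in list
#' order.
#'
#' @param full_bovine a bovine `sequence_db`.
#' @param fbs_accessions character vector of accessions to keep.
#' @param name output database name.
#' @param strict if `TRUE`, an accession absent from `full_bovine` is an
#'   error; otherwise it is excluded with a warning.
#' @return A `sequence_db` containing exactly the listed accessions found.
#' @export
build_fbs_database <- function(full_bovine, fbs_accessions, name = "FBS",
                               strict = FALSE) {
  stopifnot(inherits(full_bovine, "sequence_db"))
  fbs_accessions <- as.character(fbs_accessions)
  idx <- match(fbs_accessions, full_bovine$records$accession)
  missing <- fbs_accessions[is.na(idx)]
  if (length(missing)) {
    msg <- paste0(length(missing), " accession(s) absent from '",
                  full_bovine$name, "': ",
                  paste(head(missing, 10L), collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  records <- full_bovine$records[idx[!is.na(idx)], , drop = FALSE]
  records$source_db <- rep_len(name, nrow(records))
  rownames(records) <- NULL
  new_sequence_db(name, records,
                  data.frame(source = name, n = nrow(records),
                             stringsAsFactors = FALSE))
}

#' Append utility sequences to a search database
#'
#' Utility sequences are the proteases (trypsin, chymotrypsin, Arg-C,
#' Lys-C, Asp-N and their autolytic fragments) and mass standards (yeast
#' enolases) routinely appended to a search database. They carry species
#' `"utility"` and are excluded from human/bovine species censuses
#' downstream.
#'
#' @param db a `sequence_db`.
#' @param utilities a `sequence_db` whose records all have species
#'   `"utility"`; defaults to the packaged synthetic placeholder set of 20.
#' @param name output name (default: `db$name`).
#' @return A `sequence_db` with `length(db) + length(utilities)` entries.
#' @export
append_utility_sequences <- function(db, utilities = utility_sequences(),
                                     name = db$name) {
  stopifnot(inherits(utilities, "sequence_db"))
  if (length(utilities) > 0L &&
      !all(utilities$records$species == "utility"))
    stop("utility database must carry species = 'utility' throughout")
  if (length(utilities) == 0L) return(db)
  merge_databases(list(db, utilities), name = name)
}

#' Packaged utility sequence set
#'
#' Loads the 20-entry utility database shipped with the package. The
#' sequences are synthetic placeholders standing in for the
#' protease/enolase utility entries a search laboratory appends to its
#' databases; only their count and `utility` species tag matter for the
#' analyses here.
#'
#' @return A 20-entry `sequence_db` with species `"utility"`.
#' @export
utility_sequences <- function() {
  path <- system.file("extdata", "utility_sequences_synthetic.fasta",
                      package = "contamsort", mustWork = TRUE)
  read_fasta(path, species = "utility", source = "utility",
             name = "utility")
}

#' Read a plain-text accession list
#'
#' One accession per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return Character vector of accessions.
#' @export
read_accession_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}
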