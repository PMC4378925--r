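# write a FASTA file from header/sequence vectors, returning the path
write_tmp_fasta <- function(headers, sequences, wrap = 60L) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(headers)) {
    writeLines(paste0(">", headers[i]), con)
    s <- sequences[i]
    if (nzchar(s))
      writeLines(substring(s, seq(1, nchar(s), wrap),
                           pmin(seq(wrap, nchar(s) + wrap - 1, wrap),
                                nchar(s))), con)
  }
  path
}

# minimal well-formed PSM data.frame; override fields via ...
make_psms <- function(n = 1L, ...) {
  base <- data.frame(
    spectrum_file = rep_len("run1.raw", n), scan = seq_len(n),
    charge = rep_len(2L, n), rank = rep_len(1L, n),
    peptide = rep_len("ACDEFK", n), modifications = rep_len("", n),
    xcorr = rep_len(3, n), q_value = rep_len(0.001, n),
    pep = rep_len(0.001, n), proteins = rep_len("P1", n),
    search_db = rep_len("db", n), is_decoy = rep_len(FALSE, n),
    stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  psm_set(base)
}

# small two-species database pair used across census/compare tests:
# HSHARE is present identically in both species (every peptide shared);
# the others are species-unique by construction (disjoint alphabet use).
tiny_proteomes <- function() {
  shared_seq <- "AAADDDKEEEFFFRGGGHHHK"
  human <- sequence_database(
    c("HP1", "HP2", "HSHARE"),
    c("MMMIIIKCCCNNNRVVVTTTK", "QQQWWWKYYYSSSR", shared_seq),
    species = "human", name = "hu", source = "hu")
  bovine <- sequence_database(
    c("BP1", "BP2", "BSHARE"),
    c("PPPGGGKFFFMMMRLLLCCCK", "TTTVVVKNNNIIIR", shared_seq),
    species = "bovine", name = "bo", source = "bo")
  list(human = human, bovine = bovine)
}
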