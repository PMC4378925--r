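# Brute-force tryptic-digestion oracle: enumerate all substrings and keep
# those whose boundaries are valid tryptic termini with at most
# max_missed_cleavages internal cleavage sites. Independent of the
# boundary-walk implementation in the package.
oracle_digest <- function(sequence, params) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  site_after <- function(p) {
    # cleavage between positions p and p+1 (1-based p); termini always valid
    if (p == 0L || p == n) return(TRUE)
    chars[p] %in% c("K", "R") &&
      (params$cleave_before_proline || chars[p + 1L] != "P")
  }
  # prefix sums of internal cleavage sites keep the substring scan O(n^2)
  internal_site <- vapply(seq_len(n), function(p)
    p < n && chars[p] %in% c("K", "R") &&
      (params$cleave_before_proline || chars[p + 1L] != "P"), logical(1))
  cum <- c(0L, cumsum(internal_site))
  out <- list()
  for (s in 0:(n - 1L)) {
    if (!site_after(s)) next
    for (e in (s + 1L):n) {
      if (!site_after(e)) next
      len <- e - s
      if (len < params$min_length || len > params$max_length) next
      internal <- cum[e] - cum[s + 1L]
      if (internal > params$max_missed_cleavages) next
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(sequence, s + 1L, e), start = s,
        missed_cleavages = internal, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(peptide = character(), start = integer(),
                      missed_cleavages = integer()))
  res <- do.call(rbind, out)
  res[order(res$start, res$missed_cleavages), ]
}

digest_key <- function(d) {
  sort(paste(d$peptide, d$start, d$missed_cleavages, sep = "/"))
}

random_test_protein <- function(len, p_kr = 0.2) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  w <- rep(1, 20)
  w[aa %in% c("K", "R")] <- 20 * p_kr / 2
  paste(sample(aa, len, replace = TRUE, prob = w / sum(w)), collapse = "")
}
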