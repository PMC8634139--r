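# Small fixtures shared across test files; everything is built in code.

# Minimal PSM table with explicit reporter values; channels beyond the
# values given are filled with 100.
make_psm <- function(peptide_id, fraction_id, values,
                     modified_sequence = "AAARPAS(ph)AKAA",
                     protein_id = "PROT0001", ptm_probability = 0.99) {
  n <- length(peptide_id)
  rep_mat <- matrix(100, n, 10)
  for (i in seq_len(n)) rep_mat[i, seq_along(values[[i]])] <- values[[i]]
  out <- data.frame(peptide_id = peptide_id,
                    modified_sequence = modified_sequence,
                    protein_id = protein_id, fraction_id = fraction_id,
                    charge = 2L, ptm_probability = ptm_probability,
                    stringsAsFactors = FALSE)
  out <- cbind(out, stats::setNames(as.data.frame(rep_mat),
                                    paste0("reporter_", 1:10)))
  class(out) <- c("psm_table", class(out))
  out
}

# Independent regex oracle for the consensus scan (built from scratch in
# the tests, sharing no code with the package scanner).
regex_scan_oracle <- function(records) {
  hits <- list()
  for (id in names(records)) {
    s <- records[[id]]
    for (m in gregexpr("(?=RP.[ST][AGPS])", s, perl = TRUE)) {
      pos <- m[m > 0] + 3L   # acceptor is 4th character of the match
      if (length(pos) > 0)
        hits[[length(hits) + 1]] <- data.frame(protein_id = id,
                                               position = pos)
    }
  }
  if (length(hits) == 0)
    return(data.frame(protein_id = character(), position = integer()))
  do.call(rbind, hits)
}

# Brute-force hypergeometric upper-tail sum from binomial coefficients.
hyper_tail_oracle <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}
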