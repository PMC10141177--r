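# brute-force oracle: best (single-intron or intronless) spliced score by
# exhaustive enumeration of GT..AG excisions, each scored with a plain
# protein-to-DNA codon DP (global in query, local in genome, no introns)
codon_dp_score <- function(query, dna, mat, gap) {
  qv <- strsplit(query, "")[[1]]
  m <- length(qv); n <- nchar(dna)
  aa <- rep(NA_character_, n)
  for (f in 0:2) {
    tr <- translate_dna(dna, f)
    if (nchar(tr) > 0) {
      ends <- seq.int(f + 3, by = 3, length.out = nchar(tr))
      aa[ends] <- strsplit(tr, "")[[1]]
    }
  }
  E <- matrix(-Inf, m + 1, n + 1)
  E[1, ] <- 0
  for (i in 2:(m + 1)) {
    for (j in 1:(n + 1)) {
      best <- E[i - 1, j] - gap
      if (j > 3) {
        if (!is.na(aa[j - 1])) best <- max(best, E[i - 1, j - 3] + mat[qv[i - 1], aa[j - 1]])
        best <- max(best, E[i, j - 3] - gap)
      }
      E[i, j] <- best
    }
  }
  max(E[m + 1, ])
}

single_intron_oracle <- function(query, dna, params) {
  mat <- dbdrescue:::.submat()
  best <- codon_dp_score(query, dna, mat, params$gap_residue)
  n <- nchar(dna)
  ch <- strsplit(dna, "")[[1]]
  donors <- which(ch == "G" & c(ch[-1], "") == "T")
  accs <- which(ch == "G" & c("", ch[-n]) == "A")  # intron end position
  for (d in donors) {
    for (a in accs[accs >= d + params$min_intron - 1]) {
      spliced <- paste0(substr(dna, 1, d - 1), substr(dna, a + 1, n))
      sc <- codon_dp_score(query, spliced, mat, params$gap_residue) -
        params$intron_open
      if (sc > best) best <- sc
    }
  }
  max(best, 0)
}

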