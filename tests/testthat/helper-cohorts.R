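# Shared fixtures, built once per test session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

random_protein <- function(n, c_freq = 0) {
  aa <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]
  if (c_freq > 0) {
    p <- c(rep((1 - c_freq) / length(aa), length(aa)), c_freq)
    paste(sample(c(aa, "C"), n, replace = TRUE, prob = p), collapse = "")
  } else {
    paste(sample(aa, n, replace = TRUE), collapse = "")
  }
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# independent brute-force Smith-Waterman (affine gaps, Biostrings-style
# cost gapOpening + L * gapExtension) returning only the optimal score
sw_oracle_score <- function(a, b, mat, go = 11, ge = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)   # match state
  X <- matrix(-Inf, n + 1, m + 1) # gap in b (a consumed)
  Y <- matrix(-Inf, n + 1, m + 1) # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      M[i, j] <- max(0, mat[av[i - 1], bv[j - 1]] +
                       max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

# brute-force Zn2C6 motif search: explicit enumeration of all spacer
# combinations in (s3, s5)-lexicographic order, first hit per start kept
zn2c6_oracle <- function(protein) {
  out <- list()
  n <- nchar(protein)
  for (i in seq_len(n)) {
    if (substr(protein, i, i) != "C") next
    found <- NULL
    for (s3 in 5:16) {
      for (s5 in 6:8) {
        len <- 16 + s3 + s5
        if (i + len - 1 > n) next
        pat <- sprintf("^C[A-Z]{2}C[A-Z]{6}C[A-Z]{%d}C[A-Z]{2}C[A-Z]{%d}C", s3, s5)
        if (regexpr(pat, substring(protein, i), perl = TRUE) == 1L) {
          found <- c(i, i + len - 1)
          break
        }
      }
      if (!is.null(found)) break
    }
    if (!is.null(found)) out[[length(out) + 1]] <- found
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

# cohorts reused across test files (fixed seeds = the study conditions)
sgd_cohort <- function(n = 200) {
  cached(paste0("sgd", n), function()
    make_cohort(sim_config(n_genes = n, error_spectrum = spectrum_sgd_errors(),
                           seed = 20423)))
}

rescue_cohort <- function(n = 200) {
  cached(paste0("rescue", n), function()
    make_cohort(sim_config(n_genes = n, error_spectrum = spectrum_rescue_cohort(),
                           intron_count_range = c(0L, 2L), seed = 90424)))
}

no_dbd_cohort <- function(n = 200) {
  cached(paste0("nodbd", n), function()
    make_cohort(sim_config(n_genes = n, error_spectrum = spectrum_no_dbd(),
                           intron_count_range = c(0L, 2L), seed = 30329)))
}

rescue_run <- function(n = 200, control = FALSE) {
  cached(paste0("rescue_run", n, control), function()
    recover_cohort(rescue_cohort(n), control = control))
}
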