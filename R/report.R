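# Summary tables: ortholog accounting, error-cause spectra, and
# domain-architecture distributions before/after rescue.

#' Ortholog accounting
#'
#' Given a set of reference genes expected once per strain, how many
#' orthologs should exist, and how many are missing from the annotations?
#'
#' @param n_reference_genes Reference genes per strain.
#' @param n_strains Number of strains.
#' @param n_found Orthologous sequences actually annotated.
#' @return List: \code{expected} (\code{n_reference_genes * n_strains}),
#'   \code{missing}, \code{missing_pct} (nearest integer percent; 0 when
#'   nothing was expected).
#' @examples
#' ortholog_accounting(44, 47, 1793)  # expected 2068, missing 275 (13%)
#' @export
ortholog_accounting <- function(n_reference_genes, n_strains, n_found) {
  stopifnot(n_reference_genes >= 0, n_strains >= 0, n_found >= 0)
  expected <- n_reference_genes * n_strains
  if (n_found > expected)
    stop("ortholog_accounting: found more orthologs than expected")
  missing <- expected - n_found
  pct <- if (expected == 0) 0L else as.integer(round(100 * missing / expected))
  list(expected = expected, missing = missing, missing_pct = pct)
}

#' Error-cause summary table
#'
#' Counts diagnoses per cause with integer percentages of the total
#' (full-precision percentages are kept in \code{pct_exact}).
#'
#' @param causes Character vector of causes (one per diagnosed gene), or a
#'   data frame with a \code{cause} column.
#' @return \code{data.frame(cause, n, pct, pct_exact)} ordered
#'   frameshift, assembly_split, wrong_start, undetermined (then others).
#' @examples
#' cause_table(rep(c("frameshift", "assembly_split", "wrong_start",
#'                   "undetermined"), c(190, 9, 46, 8)))
#' @export
cause_table <- function(causes) {
  if (is.data.frame(causes)) causes <- causes$cause
  if (length(causes) == 0) stop("cause_table: no diagnoses")
  lev <- c("frameshift", "assembly_split", "wrong_start", "undetermined")
  lev <- c(lev, setdiff(unique(causes), lev))
  tb <- table(factor(causes, levels = lev))
  data.frame(cause = names(tb), n = as.integer(tb),
             pct = as.integer(round(100 * as.integer(tb) / length(causes))),
             pct_exact = 100 * as.integer(tb) / length(causes),
             row.names = NULL)
}

#' Domain-architecture distribution before and after rescue
#'
#' Reassigns each accepted recovery from \code{MHD-only} to its recovered
#' DBD architecture and tabulates counts and percentages (denominator: all
#' MHD-containing proteins) before and after.
#'
#' @param architectures_before Named character vector: architecture label
#'   per protein id (\code{Zn2C6-MHD}, \code{C2H2-MHD}, \code{MHD-only},
#'   \code{other}).
#' @param recoveries Data frame with columns \code{protein_id} and
#'   \code{dbd_type} (accepted recoveries only); each id must be annotated
#'   \code{MHD-only} in \code{architectures_before}.
#' @return \code{data.frame(architecture, n_before, pct_before, n_after,
#'   pct_after)}; total counts are conserved exactly.
#' @export
rescue_table <- function(architectures_before, recoveries = NULL) {
  stopifnot(!is.null(names(architectures_before)))
  after <- architectures_before
  if (!is.null(recoveries) && nrow(recoveries) > 0) {
    for (i in seq_len(nrow(recoveries))) {
      id <- recoveries$protein_id[i]
      if (is.na(after[id]) || after[id] != "MHD-only")
        stop("rescue_table: recovery for protein '", id,
             "' which is not annotated MHD-only")
      after[id] <- paste0(recoveries$dbd_type[i], "-MHD")
    }
  }
  lev <- c("Zn2C6-MHD", "C2H2-MHD", "MHD-only", "other")
  mhd_total <- sum(architectures_before != "other")
  tb_b <- table(factor(architectures_before, levels = lev))
  tb_a <- table(factor(after, levels = lev))
  pct <- function(tb) ifelse(names(tb) == "other", NA,
                             100 * as.integer(tb) / mhd_total)
  data.frame(architecture = lev,
             n_before = as.integer(tb_b), pct_before = pct(tb_b),
             n_after = as.integer(tb_a), pct_after = pct(tb_a),
             row.names = NULL)
}
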