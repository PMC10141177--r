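# Cohort-level drivers: run the error-tracking or rescue protocol over a
# whole (synthetic or real) cohort and tabulate the outcomes.

#' Run the error-tracking protocol over a cohort
#'
#' For every gene, screens the annotated protein for the full Zn2C6 motif
#' and, when absent, diagnoses the cause against the reference protein with
#' \code{\link{diagnose_missing_dbd}} and attempts motif reconstruction.
#'
#' @param cohort A \code{\link{make_cohort}} object, or a list with
#'   \code{models}, \code{proteome}, \code{references} (named
#'   \code{R_<gene_id>}) and \code{genome}.
#' @param thresholds \code{\link{dbd_thresholds}}.
#' @param params \code{\link{scoring_params}}.
#' @return Data frame, one row per gene (columns of
#'   \code{\link{track_errors}} plus \code{gene_id}).
#' @export
diagnose_cohort <- function(cohort, thresholds = dbd_thresholds(),
                            params = scoring_params()) {
  rows <- lapply(names(cohort$models), function(gid) {
    m <- cohort$models[[gid]]
    ref <- as.character(cohort$references[[paste0("R_", gid)]])
    ann <- as.character(cohort$proteome[[m$protein_id]])
    scafs <- grep(paste0("^", gid, "(_[ab])?$"), names(cohort$genome), value = TRUE)
    out <- track_errors(ref, ann, cohort$genome[scafs], thresholds, params,
                        reference_id = m$protein_id)
    cbind(gene_id = gid, out)
  })
  do.call(rbind, rows)
}

#' Run the DBD rescue protocol over a cohort
#'
#' Builds the reference panel and validation profile once, then applies
#' \code{\link{recover_dbd}} to every annotated MHD-only gene (genes whose
#' annotated architecture is not MHD-only are skipped).
#'
#' @inheritParams diagnose_cohort
#' @param dbd_type Panel/profile DBD type.
#' @param control Also run the \code{\link{cterm_control}} on each gene and
#'   report the outcome in \code{control_recovered}.
#' @return List: \code{results} (data frame, one row per processed gene:
#'   \code{gene_id, protein_id, status, reason, dbd_type, method, peptide,
#'   genomic_start, genomic_end, rel_start, neighbor_id, profile_evalue,
#'   patterns_ok, control_recovered}), \code{panel}, \code{profile}.
#' @export
recover_cohort <- function(cohort, thresholds = dbd_thresholds(),
                           params = scoring_params(), dbd_type = "Zn2C6",
                           control = FALSE) {
  panel <- build_reference_panel(cohort$panel_proteins, cohort$panel_domains,
                                 dbd_type)
  profile <- build_dbd_profile(panel, params)
  profiles <- setNames(list(profile), dbd_type)
  rows <- lapply(names(cohort$models), function(gid) {
    m <- cohort$models[[gid]]
    qp <- as.character(cohort$proteome[[m$protein_id]])
    qd <- cohort$domains[cohort$domains$protein_id == m$protein_id, , drop = FALSE]
    if (classify_architecture(qd) != "MHD-only") return(NULL)
    nb <- .best_neighbor(qp, list(panel), thresholds, params)
    r <- recover_dbd(m, qp, qd, cohort$genome, panel, profiles, thresholds,
                     params, neighbor = nb)
    ctl <- NA
    if (control) {
      cr <- cterm_control(m, qp, qd, cohort$genome, panel, profiles,
                          thresholds, params, neighbor = nb)
      ctl <- !is.null(cr) && cr$status == "recovered"
    }
    data.frame(
      gene_id = gid, protein_id = m$protein_id, status = r$status,
      reason = if (r$status == "failed") r$reason else NA_character_,
      dbd_type = if (!is.null(r$dbd_type)) r$dbd_type else NA_character_,
      method = if (r$status == "recovered") r$method else NA_character_,
      peptide = if (r$status == "recovered") r$peptide else NA_character_,
      genomic_start = if (r$status == "recovered") r$genomic_span[1] else NA_integer_,
      genomic_end = if (r$status == "recovered") r$genomic_span[2] else NA_integer_,
      rel_start = if (r$status == "recovered") r$rel_start else NA_integer_,
      neighbor_id = if (!is.null(r$neighbor_id)) r$neighbor_id else NA_character_,
      profile_evalue = if (r$status == "recovered") r$profile_evalue else NA_real_,
      patterns_ok = if (r$status == "recovered") r$patterns_ok else NA,
      control_recovered = ctl)
  })
  list(results = do.call(rbind, rows), panel = panel, profile = profile)
}
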