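# Reference panels of full-architecture proteins.

#' Build a reference panel of full-architecture proteins
#'
#' Filters a protein set to those whose domain architecture is exactly
#' \code{<dbd_type>-MHD} under \code{\link{classify_architecture}} (so a
#' protein with both Zn2C6 and C2H2 fingers belongs to the Zn2C6 panel).
#'
#' @param proteins \link[Biostrings]{AAStringSet}.
#' @param domains Domain-hit data frame (see \code{\link{read_domain_tsv}}).
#' @param dbd_type \code{"Zn2C6"} or \code{"C2H2"}.
#' @return A list of class \code{reference_panel}: \code{proteins} (the
#'   retained AAStringSet), \code{domains} (their hits), \code{dbd_type}.
#'   An empty panel is an error.
#' @export
build_reference_panel <- function(proteins, domains, dbd_type = c("Zn2C6", "C2H2")) {
  dbd_type <- match.arg(dbd_type)
  arch <- vapply(names(proteins), function(id)
    classify_architecture(domains[domains$protein_id == id, , drop = FALSE]),
    character(1))
  keep <- names(proteins)[arch == paste0(dbd_type, "-MHD")]
  if (length(keep) == 0)
    stop("build_reference_panel: no ", dbd_type, "-MHD proteins in input")
  structure(list(proteins = proteins[keep],
                 domains = domains[domains$protein_id %in% keep, , drop = FALSE],
                 dbd_type = dbd_type),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("<reference_panel> %s-MHD, %d proteins\n",
              x$dbd_type, length(x$proteins)))
  invisible(x)
}

#' Find the nearest full-architecture neighbor of a query protein
#'
#' Local alignment of the query against every panel entry; entries whose
#' Karlin-Altschul E-value (search space = total panel residues) is below
#' the neighbor threshold qualify, and the best is chosen by E-value, then
#' bitscore, then lexicographic id.
#'
#' @param query Amino-acid string.
#' @param panel \code{\link{build_reference_panel}} object.
#' @param thresholds \code{\link{dbd_thresholds}}.
#' @param params \code{\link{scoring_params}}.
#' @return A list \code{(neighbor_id, hit)} where \code{hit} is a one-row
#'   hit data frame, or \code{NULL} if no entry qualifies.
#' @export
find_nearest_neighbor <- function(query, panel, thresholds = dbd_thresholds(),
                                  params = scoring_params()) {
  sc <- .align_vs_set(query, panel$proteins, params)
  n_space <- sum(BiocGenerics::width(panel$proteins))
  sc$bitscore <- .bitscore_ka(sc$score, params)
  sc$evalue <- evalue_ka(sc$score, nchar(query), n_space, params)
  sc <- sc[sc$evalue < thresholds$neighbor_evalue, , drop = FALSE]
  if (nrow(sc) == 0) return(NULL)
  sc <- sc[order(sc$evalue, -sc$bitscore, sc$target_id), , drop = FALSE]
  best <- sc[1, , drop = FALSE]
  hit <- local_align_protein(query, as.character(panel$proteins[[best$target_id]]),
                             params, query_id = "query",
                             target_id = best$target_id,
                             search_space = n_space)
  list(neighbor_id = best$target_id, hit = hit)
}
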