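# Rescue protocol for MHD-only proteins: locate the missing DBD in the
# gene body plus upstream window via a nearest full-architecture neighbor,
# using complementary local (translated search) and global (spliced
# alignment) routes, then validate candidates by profile score and
# conserved-residue patterns.

#' Extract the genomic context of a gene
#'
#' Returns the gene span plus up to \code{window} upstream nucleotides
#' (5' of the annotated start, in transcript orientation; for a minus-strand
#' gene "upstream" is the 3' side in scaffold coordinates and the context is
#' reverse-complemented).  A gene too close to the scaffold edge yields a
#' truncated context, recorded in \code{upstream}.
#'
#' @param model \code{\link{gene_model}}.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param window Upstream nucleotides requested (default 1000).
#' @param downstream If nonzero, also extend this many nucleotides past the
#'   3' end (used by the C-terminal control).
#' @return List of class \code{genomic_context}: \code{seq} (transcript
#'   orientation), \code{scaffold_id}, \code{strand}, \code{region_start},
#'   \code{region_end} (scaffold coords), \code{upstream} (upstream
#'   nucleotides actually available), \code{truncated}, and
#'   \code{gene_offset} (context position of the annotated gene start).
#' @export
extract_genomic_context <- function(model, genome, window = 1000, downstream = 0) {
  if (!model$scaffold_id %in% names(genome))
    stop("extract_genomic_context: unknown scaffold ", model$scaffold_id)
  scaf <- genome[[model$scaffold_id]]
  L <- length(scaf)
  span <- range(model$exons)
  if (model$strand == "+") {
    rs <- max(1L, span[1] - as.integer(window))
    re <- min(L, span[2] + as.integer(downstream))
    up <- span[1] - rs
    s <- as.character(Biostrings::subseq(scaf, rs, re))
  } else {
    rs <- max(1L, span[1] - as.integer(downstream))
    re <- min(L, span[2] + as.integer(window))
    up <- re - span[2]
    s <- reverse_complement(as.character(Biostrings::subseq(scaf, rs, re)))
  }
  structure(list(seq = s, scaffold_id = model$scaffold_id,
                 strand = model$strand, region_start = rs, region_end = re,
                 upstream = as.integer(up),
                 truncated = up < window, gene_offset = as.integer(up) + 1L),
            class = "genomic_context")
}

# Map a context interval (1-based, transcript orientation) to forward
# scaffold coordinates.
.ctx_to_scaffold <- function(ctx, cs, ce) {
  if (ctx$strand == "+") c(ctx$region_start + cs - 1L, ctx$region_start + ce - 1L)
  else c(ctx$region_end - ce + 1L, ctx$region_end - cs + 1L)
}

# Genomic (scaffold, forward) span of a protein interval of a gene model.
.protein_to_genomic <- function(model, pstart, pend) {
  ex <- model$exons
  tx <- if (model$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  widths <- ex[tx, 2] - ex[tx, 1] + 1L
  cum <- cumsum(widths)
  nt <- c(3L * (pstart - 1L) + 1L, 3L * pend)
  pos <- vapply(nt, function(p) {
    k <- which(cum >= p)[1]
    off <- p - c(0L, cum)[k] - 1L
    if (model$strand == "+") ex[tx[k], 1] + off else ex[tx[k], 2] - off
  }, numeric(1))
  c(min(pos), max(pos))
}

.longest_n_runs <- function(seq) {
  m <- gregexpr("N+", seq)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Candidate DBD peptides from the local route: translated search of the
# neighbor's DBD segment against the context (plus frames only -- the
# context is already in transcript orientation), hits below the local
# E-value cutoff, expanded by `slack` residues each side.
.local_candidates <- function(nb_dbd, ctx, thresholds, params, slack = 6L) {
  hits <- translated_search(nb_dbd, ctx$seq, params, strands = "+",
                            max_evalue = 10, min_len = 10, trim_ends = FALSE)
  hits <- hits[hits$evalue < thresholds$local_evalue, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(hits))) {
    f <- hits$frame[i] - 1L
    taa <- translate_dna(ctx$seq, f, params$code)
    as_ <- (hits$sstart[i] - 1L - f) / 3L + 1L
    ae <- (hits$send[i] - f) / 3L
    as2 <- max(1L, as_ - slack); ae2 <- min(nchar(taa), ae + slack)
    pep <- substring(taa, as2, ae2)
    out[[length(out) + 1L]] <- list(
      peptide = pep, method = "local",
      ctx_span = c(f + 3L * (as2 - 1L) + 1L, f + 3L * ae2),
      source_evalue = hits$evalue[i])
  }
  out
}

# Candidate from the global route: spliced alignment of the full neighbor
# protein; the candidate is the peptide aligned opposite the neighbor's DBD
# coordinates, +/- slack residues.
.global_candidate <- function(nb_protein, nb_dbd_coords, ctx, params, slack = 6L) {
  sa <- spliced_align(nb_protein, ctx$seq, params)
  if (nrow(sa$blocks) == 0) return(NULL)
  ds <- max(1L, nb_dbd_coords[1] - slack)
  de <- min(nchar(nb_protein), nb_dbd_coords[2] + slack)
  g <- sa$gpos[ds:de]
  g <- g[!is.na(g)]
  if (length(g) < 10L) return(NULL)
  pep <- paste(vapply(g, function(j)
    translate_dna(substring(ctx$seq, j - 2L, j), 0, params$code), character(1)),
    collapse = "")
  list(peptide = pep, method = "global",
       ctx_span = c(min(g) - 2L, max(g)), source_evalue = NA_real_,
       alignment = sa)
}

.spans_overlap <- function(a, b) a[1] <= b[2] && b[1] <= a[2]

# Validate candidates and integrate the two routes over one context.
.recover_core <- function(candidates, ctx, profile, mhd_genomic, thresholds) {
  nrun <- .longest_n_runs(ctx$seq)
  nrun <- nrun[nrun$end - nrun$start + 1L >= thresholds$n_run_min, , drop = FALSE]
  has_nrun <- nrow(nrun) > 0
  for (k in seq_along(candidates)) {
    cand <- candidates[[k]]
    gsp <- .ctx_to_scaffold(ctx, cand$ctx_span[1], cand$ctx_span[2])
    cand$genomic_span <- gsp
    cand$mhd_overlap <- !is.null(mhd_genomic) && .spans_overlap(gsp, mhd_genomic)
    cand$profile_evalue <- profile_evalue(cand$peptide, profile)
    cand$profile_score <- score_profile(cand$peptide, profile)
    cand$patterns_ok <- check_validation_patterns(cand$peptide, profile$dbd_type)
    cand$n_overlap <- has_nrun && any(vapply(seq_len(nrow(nrun)), function(i)
      .spans_overlap(cand$ctx_span, c(nrun$start[i], nrun$end[i])), logical(1)))
    cand$accepted <- cand$profile_evalue < thresholds$profile_evalue &&
      cand$patterns_ok && !cand$mhd_overlap
    candidates[[k]] <- cand
  }
  acc <- Filter(function(x) x$accepted, candidates)
  if (length(acc)) {
    best <- acc[[order(vapply(acc, `[[`, numeric(1), "profile_score"),
                       decreasing = TRUE)[1]]]
    other <- Filter(function(x) x$accepted && x$method != best$method, candidates)
    method <- best$method
    if (any(vapply(other, function(x)
      .spans_overlap(x$ctx_span, best$ctx_span), logical(1)))) method <- "both"
    best$method <- method
    return(list(status = "recovered", best = best, candidates = candidates))
  }
  # failure triage; the distance probe (caller) runs before partial_hit is
  # claimed, so a candidate that only looks DBD-like by chance does not
  # mask a DBD sitting beyond the search window
  reason <- if (!length(candidates)) {
    if (has_nrun) "n_region" else NA_character_  # caller refines
  } else if (all(vapply(candidates, `[[`, logical(1), "n_overlap")) && has_nrun) {
    "n_region"
  } else {
    NA_character_
  }
  has_partial <- any(vapply(candidates, function(x)
    x$profile_evalue < thresholds$profile_evalue && !x$patterns_ok, logical(1)))
  list(status = "failed", reason = reason, has_partial = has_partial,
       candidates = candidates)
}

.failure <- function(protein_id, reason, detail = "") {
  structure(list(protein_id = protein_id, status = "failed",
                 reason = reason, detail = detail),
            class = "dbd_recovery")
}

# best neighbor across panels; returns list(neighbor_id, hit, panel) or NULL
.best_neighbor <- function(query_protein, panels, thresholds, params) {
  nb <- NULL
  for (p in panels) {
    cand <- find_nearest_neighbor(query_protein, p, thresholds, params)
    if (!is.null(cand)) {
      cand$panel <- p
      if (is.null(nb) || cand$hit$evalue < nb$hit$evalue) nb <- cand
    }
  }
  nb
}

#' Recover the missing DBD of an MHD-only protein
#'
#' Runs the full rescue protocol for one annotated MHD-only gene: find the
#' nearest full-architecture neighbor in the reference panel(s); extract the
#' gene plus upstream window; search for the neighbor's DBD segment by
#' translated local alignment (E < \code{local_evalue}) and by global
#' spliced alignment of the whole neighbor protein; validate each candidate
#' peptide against the DBD profile (empirical E < \code{profile_evalue}) and
#' the conserved cysteine/histidine patterns; reject candidates overlapping
#' the annotated MHD; keep the best-scoring validated candidate (method
#' \code{both} when the two routes agree on the region).  An accepted Zn2C6
#' peptide is trimmed to its full-motif span (C2H2: to the span from the
#' first C-pattern to the last H-pattern).
#'
#' @param model \code{\link{gene_model}} of the MHD-only gene.
#' @param query_protein Its annotated protein sequence.
#' @param query_domains Domain hits of the annotated protein (must include
#'   the MHD row; used to mask the MHD region).
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param panels A single \code{\link{build_reference_panel}} or a list of
#'   panels (one per DBD type); the best neighbor across panels is used.
#' @param profiles Named list of \code{\link{build_dbd_profile}} objects
#'   keyed by DBD type.
#' @param thresholds \code{\link{dbd_thresholds}}.
#' @param params \code{\link{scoring_params}}.
#' @param neighbor Optional precomputed neighbor (the value of an earlier
#'   internal panel search for the same query) to avoid repeating the
#'   panel-wide alignment; leave \code{NULL} to search.
#' @return A list of class \code{dbd_recovery}.  On success: \code{status
#'   = "recovered"}, \code{dbd_type}, \code{peptide}, \code{genomic_span}
#'   (forward scaffold coordinates), \code{rel_start} (nucleotides relative
#'   to the annotated gene start; negative = upstream), \code{method}
#'   (\code{local}/\code{global}/\code{both}), \code{profile_evalue},
#'   \code{patterns_ok}, \code{neighbor_id}.  On failure: \code{status =
#'   "failed"} and \code{reason} in \code{no_neighbor},
#'   \code{no_genomic_sequence}, \code{n_region}, \code{partial_hit},
#'   \code{too_distant}, \code{low_similarity}.
#' @export
recover_dbd <- function(model, query_protein, query_domains, genome, panels,
                        profiles, thresholds = dbd_thresholds(),
                        params = scoring_params(), neighbor = NULL) {
  if (inherits(panels, "reference_panel")) panels <- list(panels)
  pid <- model$protein_id
  if (classify_architecture(query_domains) != "MHD-only")
    stop("recover_dbd: query architecture must be MHD-only")
  if (!model$scaffold_id %in% names(genome))
    return(.failure(pid, "no_genomic_sequence",
                    paste("scaffold", model$scaffold_id, "absent")))

  nb <- if (is.null(neighbor))
    .best_neighbor(query_protein, panels, thresholds, params) else neighbor
  if (is.null(nb)) return(.failure(pid, "no_neighbor"))
  panel <- nb$panel
  dbd_type <- panel$dbd_type
  profile <- profiles[[dbd_type]]
  if (is.null(profile)) stop("recover_dbd: no profile for ", dbd_type)
  nb_protein <- as.character(panel$proteins[[nb$neighbor_id]])
  nd <- panel$domains
  nd <- nd[nd$protein_id == nb$neighbor_id & nd$domain_type == dbd_type, , drop = FALSE]
  if (nrow(nd) == 0) return(.failure(pid, "no_neighbor", "neighbor lacks DBD annotation"))
  nb_dbd_coords <- c(nd$start[1], nd$end[1])
  nb_dbd <- substring(nb_protein, nd$start[1], nd$end[1])

  ctx <- extract_genomic_context(model, genome, thresholds$upstream_window)
  mhd <- query_domains[query_domains$domain_type == "MHD", , drop = FALSE]
  mhd_genomic <- if (nrow(mhd)) .protein_to_genomic(model, mhd$start[1], mhd$end[1]) else NULL

  cands <- .local_candidates(nb_dbd, ctx, thresholds, params)
  gc <- .global_candidate(nb_protein, nb_dbd_coords, ctx, params)
  if (!is.null(gc)) cands[[length(cands) + 1L]] <- gc

  res <- .recover_core(cands, ctx, profile, mhd_genomic, thresholds)
  if (res$status == "recovered") {
    best <- res$best
    # trim the peptide to the DBD core
    core <- .dbd_core_span(best$peptide, dbd_type)
    if (!is.null(core)) {
      cs <- best$ctx_span[1] + 3L * (core[1] - 1L)
      ce <- best$ctx_span[1] + 3L * core[2] - 1L
      best$peptide <- substring(best$peptide, core[1], core[2])
      best$ctx_span <- c(cs, ce)
      best$genomic_span <- .ctx_to_scaffold(ctx, cs, ce)
    }
    rel <- best$ctx_span[1] - ctx$gene_offset
    return(structure(list(protein_id = pid, status = "recovered",
                          dbd_type = dbd_type, peptide = best$peptide,
                          genomic_span = best$genomic_span,
                          rel_start = rel, method = best$method,
                          profile_evalue = best$profile_evalue,
                          patterns_ok = best$patterns_ok,
                          neighbor_id = nb$neighbor_id),
                     class = "dbd_recovery"))
  }
  reason <- res$reason
  if (is.na(reason)) {
    # probe a wider window: is the DBD simply further upstream?
    ctx2 <- extract_genomic_context(model, genome, thresholds$extended_window)
    far <- translated_search(nb_dbd, ctx2$seq, params, strands = "+",
                             trim_ends = FALSE)
    far <- far[far$evalue < thresholds$local_evalue &
                 far$sstart < ctx2$gene_offset - thresholds$upstream_window, , drop = FALSE]
    reason <- if (nrow(far) > 0) "too_distant"
    else if (isTRUE(res$has_partial)) "partial_hit"
    else "low_similarity"
  }
  f <- .failure(pid, reason)
  f$neighbor_id <- nb$neighbor_id
  f$dbd_type <- dbd_type
  f$candidates <- res$candidates
  f
}

#' C-terminal false-positive control
#'
#' Applies the identical rescue machinery to the region downstream of the
#' annotated MHD (gene 3' end plus the same-size window), where no DBD is
#' expected.  Used to estimate the protocol's over-prediction rate.
#'
#' @inheritParams recover_dbd
#' @return A \code{dbd_recovery} object (\code{status = "recovered"} counts
#'   as a false positive on clean data), or \code{NULL} when there is no
#'   usable downstream region or no qualifying neighbor.
#' @export
cterm_control <- function(model, query_protein, query_domains, genome, panels,
                          profiles, thresholds = dbd_thresholds(),
                          params = scoring_params(), neighbor = NULL) {
  if (inherits(panels, "reference_panel")) panels <- list(panels)
  pid <- model$protein_id
  mhd <- query_domains[query_domains$domain_type == "MHD", , drop = FALSE]
  if (nrow(mhd) == 0) stop("cterm_control: query has no annotated MHD")
  nb <- if (is.null(neighbor))
    .best_neighbor(query_protein, panels, thresholds, params) else neighbor
  if (is.null(nb)) return(NULL)
  panel <- nb$panel
  dbd_type <- panel$dbd_type
  profile <- profiles[[dbd_type]]
  nb_protein <- as.character(panel$proteins[[nb$neighbor_id]])
  nd <- panel$domains
  nd <- nd[nd$protein_id == nb$neighbor_id & nd$domain_type == dbd_type, , drop = FALSE]
  if (nrow(nd) == 0) return(NULL)
  nb_dbd <- substring(nb_protein, nd$start[1], nd$end[1])

  # context: from just past the MHD 3' end to gene end + window
  mhd_genomic <- .protein_to_genomic(model, mhd$start[1], mhd$end[1])
  scaf <- genome[[model$scaffold_id]]
  span <- range(model$exons)
  if (model$strand == "+") {
    rs <- mhd_genomic[2] + 1L
    re <- min(length(scaf), span[2] + thresholds$upstream_window)
    if (re - rs + 1L < 30L) return(NULL)
    s <- as.character(Biostrings::subseq(scaf, rs, re))
  } else {
    re <- mhd_genomic[1] - 1L
    rs <- max(1L, span[1] - thresholds$upstream_window)
    if (re - rs + 1L < 30L) return(NULL)
    s <- reverse_complement(as.character(Biostrings::subseq(scaf, rs, re)))
  }
  ctx <- structure(list(seq = s, scaffold_id = model$scaffold_id,
                        strand = model$strand, region_start = rs,
                        region_end = re, upstream = 0L, truncated = FALSE,
                        gene_offset = 1L),
                   class = "genomic_context")
  cands <- .local_candidates(nb_dbd, ctx, thresholds, params)
  gc <- .global_candidate(nb_protein, c(nd$start[1], nd$end[1]), ctx, params)
  if (!is.null(gc)) cands[[length(cands) + 1L]] <- gc
  res <- .recover_core(cands, ctx, profile, NULL, thresholds)
  if (res$status == "recovered") {
    best <- res$best
    structure(list(protein_id = pid, status = "recovered",
                   dbd_type = dbd_type, peptide = best$peptide,
                   genomic_span = best$genomic_span, method = best$method,
                   profile_evalue = best$profile_evalue,
                   patterns_ok = best$patterns_ok,
                   neighbor_id = nb$neighbor_id),
              class = "dbd_recovery")
  } else {
    NULL
  }
}

#' @export
print.dbd_recovery <- function(x, ...) {
  if (x$status == "recovered") {
    cat(sprintf("<dbd_recovery> %s: recovered %s DBD (%s), %d aa, profile E %.2g\n",
                x$protein_id, x$dbd_type, x$method, nchar(x$peptide),
                x$profile_evalue))
  } else {
    cat(sprintf("<dbd_recovery> %s: failed (%s)\n", x$protein_id, x$reason))
  }
  invisible(x)
}
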