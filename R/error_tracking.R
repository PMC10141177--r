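# SGD-style protocol: given a reference full-architecture protein and a
# target genome assembly, explain why the annotated ortholog lost its
# zinc-finger motif, and rebuild a corrected protein from the genomic hits.

#' Diagnose the cause of a missing DBD
#'
#' Runs a six-frame translated search of the reference protein against every
#' scaffold, keeps hits exceeding the identity and length thresholds, and
#' applies the classification rules in fixed order: (1) qualifying hits on
#' two or more scaffolds imply a genome assembly split; (2) hits on a single
#' scaffold in two or more reading frames imply a frameshift (a 1-2 nt
#' insertion); (3) a single hit covering 100\% of the reference implies a
#' wrongly predicted start codon; otherwise the cause is undetermined.
#' The outcome is independent of hit ordering.
#'
#' @param reference Reference amino-acid sequence (character scalar); it is
#'   expected to carry the full Zn2C6 motif.
#' @param genome \link[Biostrings]{DNAStringSet} of scaffolds.
#' @param thresholds \code{\link{dbd_thresholds}}.
#' @param params \code{\link{scoring_params}}.
#' @param reference_id Id carried into the result.
#' @return A list of class \code{error_diagnosis}: \code{protein_id},
#'   \code{cause} (\code{assembly_split}, \code{frameshift},
#'   \code{wrong_start} or \code{undetermined}), \code{scaffold_count},
#'   \code{frame_count}, \code{coverage} (integer percent of reference
#'   residues inside the union of qualifying hit spans), and
#'   \code{evidence} (the qualifying hit table).
#' @export
diagnose_missing_dbd <- function(reference, genome,
                                 thresholds = dbd_thresholds(),
                                 params = scoring_params(),
                                 reference_id = "reference") {
  hits <- .empty_hits()
  if (length(genome) > 0) {
    all <- lapply(names(genome), function(sid)
      translated_search(reference, as.character(genome[[sid]]), params,
                        query_id = reference_id, target_id = sid))
    hits <- do.call(rbind, all)
  }
  qual <- hits[hits$pident > thresholds$identity_min &
                 hits$length > thresholds$hit_len_min, , drop = FALSE]
  cov <- .query_coverage(qual, nchar(reference))
  n_scaf <- length(unique(qual$sseqid))
  n_frame <- if (n_scaf == 1) length(unique(qual$frame)) else
    length(unique(paste(qual$sseqid, qual$frame)))
  cause <- if (nrow(qual) == 0) "undetermined"
  else if (n_scaf >= 2) "assembly_split"
  else if (n_frame >= 2) "frameshift"
  else if (nrow(qual) == 1 && cov == 100) "wrong_start"
  else "undetermined"
  structure(list(protein_id = reference_id, cause = cause,
                 scaffold_count = n_scaf, frame_count = n_frame,
                 coverage = cov, evidence = qual),
            class = "error_diagnosis")
}

.query_coverage <- function(hits, qlen) {
  if (nrow(hits) == 0) return(0L)
  iv <- IRanges::reduce(IRanges::IRanges(hits$qstart, hits$qend))
  as.integer(round(100 * sum(IRanges::width(iv)) / qlen))
}

#' @export
print.error_diagnosis <- function(x, ...) {
  cat(sprintf("<error_diagnosis> %s: %s (%d scaffold(s), %d frame(s), coverage %d%%, %d hit(s))\n",
              x$protein_id, x$cause, x$scaffold_count, x$frame_count,
              x$coverage, nrow(x$evidence)))
  invisible(x)
}

#' Reconstruct a corrected protein from diagnostic hits
#'
#' Orders the qualifying hits of one scaffold by genomic position (in
#' transcript orientation), translates each in its own frame, resolves
#' overlaps in favour of the higher-scoring hit, and concatenates the
#' pieces.  For an assembly split the per-scaffold fragments are returned
#' and flagged partial.
#'
#' @param diagnosis A \code{\link{diagnose_missing_dbd}} result.
#' @param genome \link[Biostrings]{DNAStringSet} of scaffolds.
#' @param params \code{\link{scoring_params}}.
#' @return A list of class \code{corrected_protein}: \code{protein_id},
#'   \code{sequence} (fragments joined for assembly splits),
#'   \code{fragments} (per-scaffold sequences), \code{source_blocks}
#'   (genomic intervals used), \code{partial}, and \code{motif_found}
#'   (full Zn2C6 motif present in the reconstruction).
#' @export
reconstruct_protein <- function(diagnosis, genome, params = scoring_params()) {
  hits <- diagnosis$evidence
  if (nrow(hits) == 0) stop("reconstruct_protein: no qualifying hits to build from")
  partial <- diagnosis$cause == "assembly_split"
  frags <- character(0)
  blocks <- list()
  for (sid in unique(hits$sseqid)) {
    h <- hits[hits$sseqid == sid, , drop = FALSE]
    minus <- h$frame[1] < 0
    h <- h[order(if (minus) -h$sstart else h$sstart), , drop = FALSE]
    # trim genomic overlaps, keeping the higher-scoring hit's residues
    keep_q <- cbind(h$qstart, h$qend)
    for (i in seq_len(nrow(h))[-1]) {
      prev <- i - 1L
      ov <- keep_q[prev, 2] - keep_q[i, 1] + 1L
      if (ov > 0) {
        if (h$score[i] >= h$score[prev]) keep_q[prev, 2] <- keep_q[prev, 2] - ov
        else keep_q[i, 1] <- keep_q[i, 1] + ov
      }
    }
    scaf <- as.character(genome[[sid]])
    pieces <- character(nrow(h))
    for (i in seq_len(nrow(h))) {
      if (keep_q[i, 1] > keep_q[i, 2]) next
      aa <- .hit_subject_peptide(h[i, ], scaf, params)
      # clip to the retained query residues
      off1 <- keep_q[i, 1] - h$qstart[i]
      off2 <- h$qend[i] - keep_q[i, 2]
      pieces[i] <- substring(aa, 1L + off1, nchar(aa) - off2)
      blocks[[length(blocks) + 1L]] <-
        data.frame(scaffold_id = sid, start = h$sstart[i], end = h$send[i])
    }
    frags <- c(frags, paste(pieces, collapse = ""))
  }
  seqn <- paste(frags, collapse = "")
  structure(list(protein_id = diagnosis$protein_id, sequence = seqn,
                 fragments = frags,
                 source_blocks = do.call(rbind, blocks),
                 partial = partial,
                 motif_found = nrow(find_zn2c6_motif(seqn)) > 0),
            class = "corrected_protein")
}

# Ungapped translation of a hit's subject span in its own frame; gaps in the
# alignment are ignored (the genomic residues are what we reconstruct from).
.hit_subject_peptide <- function(hit, scaf, params) {
  s <- substring(scaf, hit$sstart, hit$send)
  if (hit$frame < 0) s <- reverse_complement(s)
  translate_dna(s, 0, params$code)
}

#' Screen an annotated ortholog and track its error
#'
#' The protocol entry point for one reference/ortholog pair: an annotated
#' protein that already carries the full Zn2C6 motif is reported as
#' \code{"ok"}; otherwise the genome is diagnosed with
#' \code{\link{diagnose_missing_dbd}} and a corrected protein is
#' reconstructed.
#'
#' @param reference Reference (full-architecture) protein sequence.
#' @param annotated Annotated ortholog protein sequence, or \code{NA} if the
#'   ortholog was not predicted at all.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @inheritParams diagnose_missing_dbd
#' @return One-row data frame: \code{protein_id}, \code{status} (\code{ok},
#'   \code{missing}, or \code{error}), \code{cause}, \code{scaffold_count},
#'   \code{frame_count}, \code{coverage}, \code{n_hits},
#'   \code{motif_recovered}, \code{corrected_sequence}.
#' @export
track_errors <- function(reference, annotated, genome,
                         thresholds = dbd_thresholds(),
                         params = scoring_params(),
                         reference_id = "reference") {
  base <- data.frame(protein_id = reference_id, status = NA_character_,
                     cause = NA_character_, scaffold_count = NA_integer_,
                     frame_count = NA_integer_, coverage = NA_integer_,
                     n_hits = NA_integer_, motif_recovered = NA,
                     corrected_sequence = NA_character_)
  if (is.na(annotated)) { base$status <- "missing"; return(base) }
  if (nrow(find_zn2c6_motif(annotated)) > 0) {
    base$status <- "ok"; base$cause <- "none"
    return(base)
  }
  d <- diagnose_missing_dbd(reference, genome, thresholds, params, reference_id)
  base$status <- "error"
  base$cause <- d$cause
  base$scaffold_count <- d$scaffold_count
  base$frame_count <- d$frame_count
  base$coverage <- d$coverage
  base$n_hits <- nrow(d$evidence)
  if (nrow(d$evidence) > 0) {
    cp <- reconstruct_protein(d, genome, params)
    base$motif_recovered <- cp$motif_found
    base$corrected_sequence <- cp$sequence
  } else {
    base$motif_recovered <- FALSE
  }
  base
}
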