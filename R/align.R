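# Protein-protein and translated protein-DNA local alignment with
# Karlin-Altschul score statistics.  These are desk-scale stand-ins for
# BLASTP/TBLASTN: full Smith-Waterman (no word seeding), BLOSUM62 with
# BLAST default gap penalties, and E-values from the gapped Karlin-Altschul
# parameters so that the protocol's E-value thresholds operate on the scale
# they were defined for.  Exact parity with NCBI BLAST is a non-goal.

.pkg_cache <- new.env(parent = emptyenv())

# BLOSUM62 with '*' scored as a mismatch (-4) against everything, itself
# included: a stop codon can never support homology evidence here.
.submat <- function() {
  if (is.null(.pkg_cache$submat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    m["*", ] <- -4L
    m[, "*"] <- -4L
    .pkg_cache$submat <- m
  }
  .pkg_cache$submat
}

#' Alignment scoring parameters
#'
#' @param gap_open,gap_extend Affine gap penalties (BLAST protein defaults
#'   11 and 1; a gap of length L costs \code{gap_open + L * gap_extend}).
#' @param lambda,K Karlin-Altschul parameters for gapped BLOSUM62
#'   (0.267, 0.041).
#' @param gap_residue Linear per-residue gap penalty of the spliced
#'   protein-to-genome aligner.
#' @param intron_open Penalty for opening a GT-AG intron in the spliced
#'   aligner.
#' @param min_intron Minimum intron length (nt).
#' @param code Genetic code used when translating DNA targets.
#' @return A list of class \code{scoring_params}.
#' @export
scoring_params <- function(gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041,
                           gap_residue = 4, intron_open = 20, min_intron = 20,
                           code = "standard") {
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0,
            gap_residue > 0, intron_open > 0, min_intron >= 4)
  structure(list(matrix = "BLOSUM62", gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 gap_residue = gap_residue, intron_open = intron_open,
                 min_intron = as.integer(min_intron), code = code),
            class = "scoring_params")
}

#' Acceptance thresholds of the error-tracking protocol
#'
#' Defaults are the protocol's operating points: nearest-neighbor BLASTP-like
#' E < 0.005; local translated search E < 0.0001; profile E < 0.1; evidence
#' hits must exceed 95\% identity and 20 aligned residues; the upstream
#' search window is 1000 nt.
#'
#' @param neighbor_evalue,local_evalue,profile_evalue E-value cutoffs.
#' @param identity_min Percent identity a diagnostic hit must exceed.
#' @param hit_len_min Aligned length (residues) a diagnostic hit must exceed.
#' @param upstream_window Upstream nucleotides searched for the missing DBD.
#' @param extended_window Wider window used only to triage failures as
#'   "DBD further upstream than the search window".
#' @param n_run_min Length of an undetermined-base run that flags a genomic
#'   region as unusable.
#' @return A list of class \code{dbd_thresholds}.
#' @export
dbd_thresholds <- function(neighbor_evalue = 0.005, local_evalue = 1e-4,
                           profile_evalue = 0.1, identity_min = 95,
                           hit_len_min = 20, upstream_window = 1000,
                           extended_window = 2000, n_run_min = 10) {
  stopifnot(neighbor_evalue > 0, local_evalue > 0, profile_evalue > 0,
            identity_min > 0, identity_min <= 100, hit_len_min > 0,
            upstream_window > 0, extended_window >= upstream_window)
  structure(list(neighbor_evalue = neighbor_evalue, local_evalue = local_evalue,
                 profile_evalue = profile_evalue, identity_min = identity_min,
                 hit_len_min = hit_len_min, upstream_window = as.integer(upstream_window),
                 extended_window = as.integer(extended_window),
                 n_run_min = as.integer(n_run_min)),
            class = "dbd_thresholds")
}

#' Karlin-Altschul E-value for a raw local alignment score
#'
#' \eqn{E = K m n e^{-\lambda S}} with \code{m} the query length and
#' \code{n} the effective search space.
#'
#' @param score Raw alignment score.
#' @param m,n Query length and effective target size.
#' @param params \code{\link{scoring_params}}.
#' @export
evalue_ka <- function(score, m, n, params = scoring_params()) {
  params$K * m * n * exp(-params$lambda * score)
}

.bitscore_ka <- function(score, params) {
  (params$lambda * score - log(params$K)) / log(2)
}

.empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0), frame = integer(0),
             pident = numeric(0), length = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             score = numeric(0), bitscore = numeric(0), evalue = numeric(0))
}

.hit_row <- function(aln, qid, sid, frame, m, n, params) {
  alen <- Biostrings::nchar(aln)  # alignment length incl. gaps
  sc <- Biostrings::score(aln)
  data.frame(
    qseqid = qid, sseqid = sid, frame = frame,
    pident = 100 * Biostrings::nmatch(aln) / alen,
    length = alen,
    qstart = IRanges::start(Biostrings::pattern(aln)),
    qend = IRanges::end(Biostrings::pattern(aln)),
    sstart = IRanges::start(Biostrings::subject(aln)),
    send = IRanges::end(Biostrings::subject(aln)),
    score = sc, bitscore = .bitscore_ka(sc, params),
    evalue = evalue_ka(sc, m, n, params))
}

#' Optimal local protein-protein alignment
#'
#' Smith-Waterman under BLOSUM62 with affine gaps; the E-value uses the
#' product of the two sequence lengths as search space unless
#' \code{search_space} is given (e.g. total panel residues).
#'
#' @param query,target Amino-acid strings (character scalars).
#' @param params \code{\link{scoring_params}}.
#' @param query_id,target_id Ids carried into the hit record.
#' @param search_space Effective target size in residues.
#' @return A one-row hit data frame (BLAST outfmt-6-like columns
#'   \code{qseqid, sseqid, frame, pident, length, qstart, qend, sstart,
#'   send, score, bitscore, evalue}), or \code{NULL} if the optimal score
#'   is not positive.
#' @export
local_align_protein <- function(query, target, params = scoring_params(),
                                query_id = "query", target_id = "target",
                                search_space = NULL) {
  stopifnot(nchar(query) > 0, nchar(target) > 0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = .submat(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  if (Biostrings::score(aln) <= 0) return(NULL)
  n <- if (is.null(search_space)) nchar(target) else search_space
  .hit_row(aln, query_id, target_id, 0L, nchar(query), n, params)
}

# HSP end trimming: Smith-Waterman keeps any net-positive extension, so a
# hit can creep across a frameshift boundary into unrelated translation and
# dilute its identity.  As BLAST's X-drop does in effect, drop terminal
# alignment columns while the 15-column end window falls below 75%
# identity, then recompute score and statistics on the kept columns.
.trim_hit_ends <- function(aln, params, window = 15L, min_id = 0.75) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  L <- length(p)
  m <- p == s & p != "-"
  lo <- 1L; hi <- L
  repeat {
    changed <- FALSE
    while (hi - lo + 1L >= window &&
           mean(m[(hi - window + 1L):hi]) < min_id) { hi <- hi - 1L; changed <- TRUE }
    while (hi - lo + 1L >= window &&
           mean(m[lo:(lo + window - 1L)]) < min_id) { lo <- lo + 1L; changed <- TRUE }
    # short creeps: a 5-column end window below 70% identity
    while (hi - lo + 1L >= 5L &&
           mean(m[(hi - 4L):hi]) < 0.7) { hi <- hi - 1L; changed <- TRUE }
    while (hi - lo + 1L >= 5L &&
           mean(m[lo:(lo + 4L)]) < 0.7) { lo <- lo + 1L; changed <- TRUE }
    if (!changed) break
  }
  # never end on a gap or mismatch-free? just avoid gap columns at the ends
  while (hi >= lo && (p[hi] == "-" || s[hi] == "-")) hi <- hi - 1L
  while (lo <= hi && (p[lo] == "-" || s[lo] == "-")) lo <- lo + 1L
  if (lo == 1L && hi == L)
    return(list(trimmed = FALSE))
  if (hi < lo) return(NULL)
  pk <- p[lo:hi]; sk <- s[lo:hi]
  mat <- .submat()
  both <- pk != "-" & sk != "-"
  sc <- sum(mat[cbind(pk[both], sk[both])])
  gap_runs <- function(x) {
    r <- rle(x == "-")
    list(n = sum(r$values), len = sum(r$lengths[r$values]))
  }
  gp <- gap_runs(pk); gs <- gap_runs(sk)
  sc <- sc - (gp$n + gs$n) * params$gap_open -
    (gp$len + gs$len) * params$gap_extend
  list(trimmed = TRUE, score = sc,
       nmatch = sum(pk == sk & pk != "-"),
       length = hi - lo + 1L,
       q_off1 = sum(p[seq_len(lo - 1L)] != "-"),
       q_off2 = sum(p[seq_len(L)] != "-") - sum(p[seq_len(hi)] != "-"),
       s_off1 = sum(s[seq_len(lo - 1L)] != "-"),
       s_off2 = sum(s[seq_len(L)] != "-") - sum(s[seq_len(hi)] != "-"))
}

# Iterated optimal local alignments of a query against one translated frame:
# find the best hit, then recurse into the unaligned flanks, keeping hits
# with evalue <= max_evalue and >= min_len aligned residues.
.frame_hits <- function(qaa, taa, m, n, params, max_evalue, min_len,
                        trim_ends = TRUE) {
  res <- list()
  stack <- list(c(1L, nchar(taa)))
  q <- Biostrings::AAString(qaa)
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (iv[2] - iv[1] + 1L < min_len) next
    seg <- substring(taa, iv[1], iv[2])
    aln <- Biostrings::pairwiseAlignment(
      q, Biostrings::AAString(seg), type = "local",
      substitutionMatrix = .submat(),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    sc <- Biostrings::score(aln)
    if (sc <= 0) next
    h <- .hit_row(aln, "q", "t", 0L, m, n, params)
    tr <- if (trim_ends) .trim_hit_ends(aln, params) else list(trimmed = FALSE)
    if (is.null(tr)) next
    if (isTRUE(tr$trimmed)) {
      if (tr$score <= 0) next
      h$score <- tr$score
      h$length <- tr$length
      h$pident <- 100 * tr$nmatch / tr$length
      h$qstart <- h$qstart + tr$q_off1; h$qend <- h$qend - tr$q_off2
      h$sstart <- h$sstart + tr$s_off1; h$send <- h$send - tr$s_off2
      h$bitscore <- .bitscore_ka(tr$score, params)
      h$evalue <- evalue_ka(tr$score, m, n, params)
    }
    # segment-local -> frame coordinates
    h$sstart <- h$sstart + iv[1] - 1L
    h$send <- h$send + iv[1] - 1L
    if (h$evalue <= max_evalue && h$length >= min_len) {
      res[[length(res) + 1L]] <- h
      stack[[length(stack) + 1L]] <- c(iv[1], h$sstart - 1L)
      stack[[length(stack) + 1L]] <- c(h$send + 1L, iv[2])
    }
  }
  res
}

#' Six-frame translated local search of a protein against DNA
#'
#' Translates both strands of the target in all three frames and performs
#' iterated Smith-Waterman local alignments in each, so that several
#' separated homologous segments on one scaffold (e.g. the two sides of a
#' frameshift, in different frames) are all reported.  Stop codons score
#' -4 against every residue.
#'
#' @param query Amino-acid string.
#' @param target DNA string (a scaffold or extracted genomic context).
#' @param params \code{\link{scoring_params}}.
#' @param query_id,target_id Ids carried into the hit table.
#' @param max_evalue Keep hits with E-value at or below this (BLAST-like
#'   report cutoff; the protocol filters further downstream).
#' @param min_len Minimum aligned residues per reported hit.
#' @param strands \code{c("+","-")} by default; restrict to \code{"+"} when
#'   the target is already in transcript orientation.
#' @param trim_ends Trim low-identity hit ends (see Details).  Keep on for
#'   near-identical diagnostic searches; turn off when querying diverged
#'   homologs, whose alignments legitimately contain low-identity windows.
#' @return Hit data frame (possibly empty) sorted by increasing E-value;
#'   \code{frame} is BLAST-style (+1,+2,+3,-1,-2,-3); \code{sstart <= send}
#'   are forward-strand nucleotide positions, 1-based closed.
#' @export
translated_search <- function(query, target, params = scoring_params(),
                              query_id = "query", target_id = "target",
                              max_evalue = 10, min_len = 10,
                              strands = c("+", "-"), trim_ends = TRUE) {
  stopifnot(nchar(target) >= 3)
  m <- nchar(query)
  n <- nchar(target)
  frames <- .six_frames(target, params$code)
  keep <- substr(names(frames), 1, 1) %in% strands
  frames <- frames[keep]
  out <- list()
  for (fl in names(frames)) {
    taa <- frames[[fl]]
    if (nchar(taa) < min_len) next
    hs <- .frame_hits(query, taa, m, n, params, max_evalue, min_len, trim_ends)
    for (h in hs) {
      nt <- .frame_to_nt(h$sstart, h$send, fl, n)
      h$sstart <- nt[1]; h$send <- nt[2]
      h$frame <- as.integer(fl)
      h$qseqid <- query_id; h$sseqid <- target_id
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(.empty_hits())
  hits <- do.call(rbind, out)
  hits[order(hits$evalue, -hits$score), , drop = FALSE]
}

# Vectorised local alignment scores of one query against a whole panel
# (one C-level call, scores only -- full alignments are built downstream
# for the winning entry alone).
.align_vs_set <- function(query, set, params) {
  sc <- Biostrings::pairwiseAlignment(
    set, Biostrings::AAString(query), type = "local",
    substitutionMatrix = .submat(),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  data.frame(target_id = names(set), score = sc)
}
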