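# Position-specific scoring profiles for DBD validation.
#
# The accept/reject contract mirrors an hmmsearch step: a candidate peptide
# is scored against a log-odds profile built from the reference panel's own
# DBD segments, and its "E-value" is the empirical upper-tail probability of
# that score under a null of random background peptides.  Zn2C6 profiles are
# anchored on the six motif cysteines (spacers left-aligned into max-width
# slots); C2H2 profiles use a star alignment to the longest panel segment.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.zn2c6_columns <- function() {
  # canonical layout: C1 s1(2) C2 s2(6) C3 s3(<=16) C4 s4(2) C5 s5(<=8) C6
  widths <- c(1, 2, 1, 6, 1, 16, 1, 2, 1, 8, 1)
  lab <- rep(c("C1", "s1", "C2", "s2", "C3", "s3", "C4", "s4", "C5", "s5", "C6"),
             widths)
  lab
}

# Place one Zn2C6 motif segment onto the canonical 40 columns.
.zn2c6_place <- function(peptide) {
  m <- find_zn2c6_motif(peptide)
  if (nrow(m) == 0) return(NULL)
  seg <- substring(peptide, m$start[1], m$end[1])
  ch <- strsplit(seg, "")[[1]]
  len <- length(ch)
  # anchor positions follow from the matched spacing: cysteines at
  # 1, 4, 11, 12+s3, 15+s3, 16+s3+s5 with len = 16+s3+s5; recover (s3,s5)
  # from the total length, widest fifth spacer first
  s3 <- NA
  anchors <- NULL
  for (s5 in 8:6) {
    s3v <- len - 16L - s5
    if (s3v < 5L || s3v > 16L) next
    pos <- c(1L, 4L, 11L, 12L + s3v, 15L + s3v, len)
    if (all(ch[pos] == "C")) { anchors <- pos; s3 <- s3v; break }
  }
  if (is.null(anchors)) return(NULL)
  cols <- .zn2c6_columns()
  out <- rep(NA_character_, length(cols))
  cyst <- which(cols %in% c("C1", "C2", "C3", "C4", "C5", "C6"))
  out[cyst] <- "C"
  sp <- list(s1 = ch[2:3], s2 = ch[5:10], s3 = ch[12:(11 + s3)],
             s4 = ch[(13 + s3):(14 + s3)], s5 = ch[(16 + s3):(len - 1)])
  for (nm in names(sp)) {
    slots <- which(cols == nm)
    v <- sp[[nm]]
    out[slots[seq_along(v)]] <- v
  }
  out
}

# Star alignment of segments onto the longest one; returns a character
# matrix with one row per segment, NA where a segment has no residue.
.star_columns <- function(segments, params) {
  ref <- segments[[which.max(nchar(segments))]]
  L <- nchar(ref)
  rows <- lapply(segments, function(s) {
    if (identical(s, ref)) return(strsplit(ref, "")[[1]])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(s), Biostrings::AAString(ref), type = "global",
      substitutionMatrix = .submat(),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    r <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    out <- rep(NA_character_, L)
    out[cumsum(r != "-")[r != "-"]] <- p[r != "-"]
    out[out == "-"] <- NA
    out
  })
  do.call(rbind, rows)
}

#' Build a validation profile from a reference panel
#'
#' Extracts the panel's DBD segments (per its domain annotations), stacks
#' them into aligned columns, converts the column counts into log2-odds
#' against a uniform background with +1 pseudocounts, and calibrates an
#' empirical null score distribution on random background peptides.
#'
#' @param panel A \code{\link{build_reference_panel}} object.
#' @param params \code{\link{scoring_params}}.
#' @param n_null Number of random peptides for the null (default 10000).
#' @param null_seed Seed of the null-generation RNG stream (kept separate
#'   from the caller's RNG state).
#' @return A list of class \code{dbd_profile}: \code{dbd_type},
#'   \code{pssm} (20 x L log-odds matrix), \code{length}, sorted
#'   \code{null_scores}, and the gap penalty used for scoring.
#' @export
build_dbd_profile <- function(panel, params = scoring_params(),
                              n_null = 10000, null_seed = 101) {
  stopifnot(inherits(panel, "reference_panel"))
  dom <- panel$domains
  segs <- character(0)
  for (i in seq_len(nrow(dom))) {
    if (dom$domain_type[i] != panel$dbd_type) next
    p <- as.character(panel$proteins[[dom$protein_id[i]]])
    segs <- c(segs, substring(p, dom$start[i], dom$end[i]))
  }
  if (length(segs) < 5)
    stop("build_dbd_profile: need at least 5 panel DBD segments, got ", length(segs))
  rows <- if (panel$dbd_type == "Zn2C6") {
    placed <- Filter(Negate(is.null), lapply(segs, .zn2c6_place))
    if (length(placed) < 5)
      stop("build_dbd_profile: fewer than 5 panel segments carry the Zn2C6 motif")
    do.call(rbind, placed)
  } else {
    .star_columns(segs, params)
  }
  L <- ncol(rows)
  counts <- matrix(0, nrow = 20, ncol = L, dimnames = list(.AA20, NULL))
  for (j in seq_len(L)) {
    tb <- table(factor(rows[, j][rows[, j] %in% .AA20], levels = .AA20))
    counts[, j] <- as.numeric(tb)
  }
  ncol_obs <- colSums(counts)
  pssm <- log2(sweep(counts + 1 / 20, 2, ncol_obs + 1, "/") / (1 / 20))
  # information-content column weights (small-sample bias corrected):
  # non-conserved columns carry ~0 usable log-odds, as they would in a
  # profile HMM whose emissions match the background
  freq <- sweep(counts + 1 / 20, 2, ncol_obs + 1, "/")
  ic <- colSums(freq * log2(freq / (1 / 20)))
  bias <- 19 / (2 * log(2) * pmax(ncol_obs, 1))
  w <- pmin(1, pmax(0, ic - bias) / 2)
  pssm <- sweep(pssm, 2, w, "*")
  # skipping a sparsely occupied column (a variable-spacer slot) is cheap,
  # like passing through an HMM insert state; skipping a core column is not
  occupancy <- ncol_obs / max(ncol_obs)
  del_cost <- 0.2 + (params$gap_residue - 0.2) * occupancy
  prof <- structure(list(dbd_type = panel$dbd_type, pssm = pssm, length = L,
                         del_cost = del_cost, ins_cost = params$gap_residue,
                         null_scores = NULL,
                         n_null = as.integer(n_null)),
                    class = "dbd_profile")
  prof$null_scores <- .profile_null(prof, n_null, null_seed)
  prof
}

.profile_null <- function(profile, n_null, null_seed) {
  plen <- max(10L, round(1.5 * profile$length))
  peps <- withr::with_seed(null_seed, {
    matrix(sample.int(20L, n_null * plen, replace = TRUE), nrow = n_null)
  })
  sort(.pssm_null_scores_cpp(peps, profile$pssm, profile$del_cost,
                             profile$ins_cost))
}

#' Score a candidate peptide against a profile
#'
#' @param peptide Amino-acid string.
#' @param profile A \code{\link{build_dbd_profile}} object.
#' @return \code{score_profile}: best local peptide-vs-profile score;
#'   \code{profile_evalue}: its empirical upper-tail probability under the
#'   calibrated null (in (0, 1]; smaller is stronger).
#' @export
score_profile <- function(peptide, profile) {
  idx <- match(strsplit(toupper(peptide), "")[[1]], .AA20)
  idx[is.na(idx)] <- 0L
  .pssm_local_score_cpp(idx, profile$pssm, profile$del_cost, profile$ins_cost)
}

#' @rdname score_profile
#' @export
profile_evalue <- function(peptide, profile) {
  s <- score_profile(peptide, profile)
  ns <- profile$null_scores
  (1 + sum(ns >= s)) / (length(ns) + 1)
}

#' @export
print.dbd_profile <- function(x, ...) {
  cat(sprintf("<dbd_profile> %s, %d columns, null n=%d (median %.1f, max %.1f)\n",
              x$dbd_type, x$length, length(x$null_scores),
              stats::median(x$null_scores), max(x$null_scores)))
  invisible(x)
}
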