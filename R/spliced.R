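# Spliced protein-to-genome alignment (a desk-scale ProSplign stand-in).

.aa_alphabet <- function() rownames(.submat())

# 1-based submat row index of the codon ending at each genomic position j;
# -1 where no complete codon ends (j < 3) or for the row lookup of unknowns.
.codon_rows <- function(dna, code = "standard") {
  n <- nchar(dna)
  if (n < 3) return(integer(0))
  aa <- rep(NA_character_, n)
  for (f in 0:2) {
    tr <- translate_dna(dna, f, code)
    if (nchar(tr) == 0) next
    ends <- seq.int(f + 3L, by = 3L, length.out = nchar(tr))
    aa[ends] <- strsplit(tr, "")[[1]]
  }
  idx <- match(aa, .aa_alphabet())
  idx[is.na(idx)] <- 0L
  idx - 1L  # 0-based for C++; -1 = no codon
}

#' Spliced alignment of a protein to genomic DNA
#'
#' Aligns a full protein to a genomic sequence, global in the query (every
#' residue is aligned to a codon or explicitly deleted) and local in the
#' genome, allowing GT-AG introns of at least \code{params$min_intron}
#' nucleotides between codon-aligned blocks.  Introns are placed at codon
#' boundaries only; frameshifts are deliberately not modelled (they are the
#' translated-search diagnostic's job).  On ties the alignment with fewer
#' introns, then the leftmost genomic end, is preferred.
#'
#' @param query Amino-acid string.
#' @param genomic DNA string (e.g. an extracted gene context in transcript
#'   orientation).
#' @param params \code{\link{scoring_params}}; uses the BLOSUM62 matrix,
#'   \code{gap_residue} as linear gap penalty and \code{intron_open}.
#' @return A list of class \code{spliced_alignment}: \code{score};
#'   \code{blocks} (data frame \code{qstart,qend,gstart,gend}, genomic block
#'   length always 3x the protein block length); \code{introns} (data frame
#'   \code{start,end,donor,acceptor}); \code{gpos} (per query residue, the
#'   genomic position of the last base of its codon; \code{NA} if deleted).
#'   A degenerate alignment (no positive-scoring chain) has empty blocks
#'   and score 0.
#' @export
spliced_align <- function(query, genomic, params = scoring_params()) {
  stopifnot(nchar(genomic) >= 3, nchar(query) >= 1)
  query <- toupper(query); genomic <- toupper(genomic)
  alpha <- .aa_alphabet()
  qidx <- match(strsplit(query, "")[[1]], alpha)
  qidx[is.na(qidx)] <- match("X", alpha)
  chars <- strsplit(genomic, "")[[1]]
  n <- length(chars)
  donor <- c(chars[-n] == "G" & chars[-1] == "T", FALSE)
  accend <- c(FALSE, chars[-n] == "A" & chars[-1] == "G")
  res <- .spliced_align_cpp(qidx - 1L, .codon_rows(genomic, params$code),
                            donor, accend, .submat(),
                            params$gap_residue, params$intron_open,
                            params$min_intron)
  gpos <- res$gpos
  gpos[gpos == 0L] <- NA_integer_
  blocks <- .gpos_blocks(gpos)
  intr <- res$introns
  introns <- if (nrow(intr)) {
    data.frame(start = intr[, 1], end = intr[, 2],
               donor = substring(genomic, intr[, 1], intr[, 1] + 1L),
               acceptor = substring(genomic, intr[, 2] - 1L, intr[, 2]))
  } else {
    data.frame(start = integer(0), end = integer(0),
               donor = character(0), acceptor = character(0))
  }
  structure(list(score = res$score, blocks = blocks, introns = introns,
                 gpos = gpos, query_length = nchar(query)),
            class = "spliced_alignment")
}

.gpos_blocks <- function(gpos) {
  m <- length(gpos)
  qs <- integer(0); qe <- integer(0)
  i <- 1L
  while (i <= m) {
    if (is.na(gpos[i])) { i <- i + 1L; next }
    j <- i
    while (j < m && !is.na(gpos[j + 1L]) && gpos[j + 1L] == gpos[j] + 3L) j <- j + 1L
    qs <- c(qs, i); qe <- c(qe, j)
    i <- j + 1L
  }
  data.frame(qstart = qs, qend = qe,
             gstart = gpos[qs] - 2L, gend = gpos[qe])
}

#' @export
print.spliced_alignment <- function(x, ...) {
  cat(sprintf("<spliced_alignment> score %.1f, %d block(s), %d intron(s), %d/%d residues aligned\n",
              x$score, nrow(x$blocks), nrow(x$introns),
              sum(!is.na(x$gpos)), x$query_length))
  invisible(x)
}
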