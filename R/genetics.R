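# Genetic-code translation and strand arithmetic.
#
# Translation is implemented directly over the standard codon table rather
# than delegated, because the pipeline fixes two behaviours that matter for
# error tracking: any codon containing an undetermined base (N) translates
# to 'X', and stop codons are rendered as '*' and kept in-frame (stops inside
# a frameshifted region are informative, not terminal).

.codon_table <- function(code = c("standard", "ctg_ser")) {
  code <- match.arg(code)
  tab <- Biostrings::GENETIC_CODE
  if (code == "ctg_ser") tab["CTG"] <- "S"  # CTG-clade (e.g. Candida) decoding
  tab
}

#' Translate DNA in a given frame
#'
#' @param dna A DNA string over \code{A,C,G,T,N} (character scalar).
#' @param frame Offset in \code{0,1,2}: translation starts at position
#'   \code{frame + 1}.
#' @param code Genetic code: \code{"standard"} (table 1) or \code{"ctg_ser"}
#'   (CTG decoded as Ser, for CTG-clade yeasts).
#' @return Amino-acid string. Stops are \code{'*'}; codons containing
#'   \code{N} give \code{'X'}; a trailing partial codon is dropped.
#' @examples
#' translate_dna("ATGAAATAA", 0)  # "MK*"
#' translate_dna("ATNAAA", 0)     # "XK"
#' @export
translate_dna <- function(dna, frame = 0, code = "standard") {
  stopifnot(length(dna) == 1L, frame %in% 0:2)
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n - frame < 3L) return("")
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(.codon_table(code)[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#'
#' @param dna DNA string over \code{A,C,G,T,N}.
#' @return The reverse complement, same alphabet.
#' @export
reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

# All six frame translations of a scaffold: list with elements named
# "+1","+2","+3","-1","-2","-3" (BLAST frame convention).
.six_frames <- function(dna, code = "standard") {
  rc <- reverse_complement(dna)
  out <- c(
    lapply(0:2, function(f) translate_dna(dna, f, code)),
    lapply(0:2, function(f) translate_dna(rc, f, code))
  )
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# Map an amino-acid interval [as, ae] (1-based, in the translation of a
# frame) back to forward-strand nucleotide coordinates (1-based closed).
.frame_to_nt <- function(as_, ae, frame_label, scaffold_len) {
  f <- abs(as.integer(frame_label)) - 1L  # 0,1,2 offset
  s <- f + 3L * (as_ - 1L) + 1L
  e <- f + 3L * ae
  if (as.integer(frame_label) > 0L) c(s, e) else {
    c(scaffold_len - e + 1L, scaffold_len - s + 1L)
  }
}
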