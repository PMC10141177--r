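# Zinc-finger motif detection and domain-architecture classification.

# Full Zn2C6 binuclear-cluster motif: six cysteines with spacers
# x2, x6, x(5-16), x2, x(6-8).  Spacer positions accept any amino acid
# except '*' (a stop can never sit inside a folded domain) -- note 'X'
# is allowed in spacers but never satisfies a fixed C position.
.ZN2C6_ANCHORED <- "^C[A-Z]{2}C[A-Z]{6}C[A-Z]{5,16}?C[A-Z]{2}C[A-Z]{6,8}?C"

#' Find Zn2C6 binuclear cluster motifs
#'
#' Scans a protein for the full \code{CX\{2\}CX\{6\}CX\{5,16\}CX\{2\}CX\{6,8\}C}
#' motif.  Every cysteine position that can anchor a match is reported once;
#' among alternative spacer lengths at one start, the leftmost-shortest match
#' is kept (the third spacer minimised first, then the fifth).
#'
#' @param protein Amino-acid string.
#' @return \code{data.frame(start, end)} of matches, 1-based closed
#'   coordinates; zero rows if none.
#' @export
find_zn2c6_motif <- function(protein) {
  stopifnot(length(protein) == 1L)
  protein <- toupper(protein)
  cpos <- gregexpr("C", protein, fixed = TRUE)[[1]]
  out <- list()
  if (cpos[1] != -1L) {
    for (i in cpos) {
      m <- regexpr(.ZN2C6_ANCHORED, substring(protein, i), perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        out[[length(out) + 1L]] <- c(i, i + len - 1L)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}

#' Check conserved-residue validation patterns
#'
#' Applies the false-positive filters used when accepting a candidate DBD:
#' a Zn2C6 candidate must contain two non-overlapping occurrences of
#' \code{C-x(2)-C} (counted greedily left to right); a C2H2 candidate must
#' contain one \code{C-x(2,4)-C} and one \code{H-x(3,5)-H}.
#'
#' @param peptide Amino-acid string.
#' @param domain_type \code{"Zn2C6"} or \code{"C2H2"}.
#' @return Logical scalar.
#' @export
check_validation_patterns <- function(peptide, domain_type = c("Zn2C6", "C2H2")) {
  domain_type <- match.arg(domain_type)
  peptide <- toupper(peptide)
  if (domain_type == "Zn2C6") {
    m <- gregexpr("C[A-Z]{2}C", peptide, perl = TRUE)[[1]]
    sum(m != -1L) >= 2L
  } else {
    grepl("C[A-Z]{2,4}C", peptide, perl = TRUE) &&
      grepl("H[A-Z]{3,5}H", peptide, perl = TRUE)
  }
}

# Core span of a validated candidate: for Zn2C6 the full motif match, for
# C2H2 from the first C-x(2,4)-C to the last H-x(3,5)-H.  NULL if absent.
.dbd_core_span <- function(peptide, domain_type) {
  if (domain_type == "Zn2C6") {
    m <- find_zn2c6_motif(peptide)
    if (nrow(m) == 0) return(NULL)
    c(m$start[1], m$end[1])
  } else {
    c1 <- regexpr("C[A-Z]{2,4}C", peptide, perl = TRUE)
    hs <- gregexpr("H[A-Z]{3,5}H", peptide, perl = TRUE)[[1]]
    if (c1 == -1L || hs[1] == -1L) return(NULL)
    last <- length(hs)
    c(as.integer(c1), as.integer(hs[last]) + attr(hs, "match.length")[last] - 1L)
  }
}

#' Classify the domain architecture of one protein
#'
#' @param domain_types Character vector of domain labels for one protein
#'   (from \code{"Zn2C6"}, \code{"C2H2"}, \code{"MHD"}), or a domain-hit
#'   data frame with a \code{domain_type} column.
#' @return One of \code{"Zn2C6-MHD"}, \code{"C2H2-MHD"}, \code{"MHD-only"},
#'   \code{"other"}.  A protein with an MHD and at least one Zn2C6 is
#'   \code{"Zn2C6-MHD"} regardless of additional C2H2 fingers.
#' @export
classify_architecture <- function(domain_types) {
  if (is.data.frame(domain_types)) domain_types <- domain_types$domain_type
  has <- function(x) any(domain_types == x)
  if (!has("MHD")) return("other")
  if (has("Zn2C6")) return("Zn2C6-MHD")
  if (has("C2H2")) return("C2H2-MHD")
  "MHD-only"
}

#' Motif specifications for the supported DBD types
#'
#' @return A list with, per type, the full-motif pattern (Zn2C6) and the
#'   validation patterns with their required occurrence counts.
#' @export
motif_spec <- function() {
  list(
    Zn2C6 = list(full = "CX{2}CX{6}CX{5,16}CX{2}CX{6,8}C",
                 validation = c("C-x(2)-C" = 2L)),
    C2H2 = list(full = NA_character_,
                validation = c("C-x(2,4)-C" = 1L, "H-x(3,5)-H" = 1L))
  )
}
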