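# Synthetic fungal-like benchmark cohorts with planted annotation errors
# and full truth labels.
#
# Each synthetic gene is a compact fungal-style locus:
#   M + leader (8-20 aa) + DBD (Zn2C6 27-40 aa or C2H2 23-28 aa)
#     + linker (25-45 aa) + MHD (250 aa, a cohort-shared conserved block
#     mutated per gene) + tail (10-25 aa)
# encoded with uniformly sampled synonymous codons, optional short GT-AG
# introns at codon boundaries, and generous intergenic flanks.  Planted
# errors follow the mechanisms the protocol diagnoses: 1-2 nt frameshift
# insertions, scaffold splits, wrongly predicted start codons, a missing
# upstream (DBD-coding) exon, a truly DBD-less locus, and an undetermined
# class where the DBD-coding DNA is absent altogether.

.AA19 <- setdiff(.AA20, "C")          # C-free background (spacers, MHD)
.AA18 <- setdiff(.AA20, c("C", "H"))  # also H-free (C2H2 spacers)

.rand_aa <- function(n, alphabet = .AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

.codons_by_aa <- function() {
  if (is.null(.pkg_cache$codons_by_aa)) {
    tab <- Biostrings::GENETIC_CODE
    .pkg_cache$codons_by_aa <- split(names(tab), tab)
  }
  .pkg_cache$codons_by_aa
}

# Encode a protein as DNA with uniformly sampled synonymous codons.
.encode_protein <- function(protein) {
  cb <- .codons_by_aa()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cs <- cb[[a]]
    if (length(cs) == 1) cs else sample(cs, 1)
  }, character(1)), collapse = "")
}

# Substitute a fraction of residues (never at protected positions).
.mutate_protein <- function(protein, rate, protect = integer(0)) {
  aa <- strsplit(protein, "")[[1]]
  idx <- setdiff(which(stats::runif(length(aa)) < rate), protect)
  for (i in idx) aa[i] <- sample(setdiff(.AA20, aa[i]), 1)
  paste(aa, collapse = "")
}

#' Generate a synthetic DNA-binding domain peptide
#'
#' Zn2C6: the six cysteines are fixed and the spacers are sampled uniformly
#' from the allowed ranges (x2, x6, x5-16, x2, x6-8), spacer residues drawn
#' from a cysteine-free background so the planted motif span is the unique
#' match.  C2H2: a 23-28 aa peptide guaranteed to satisfy both the
#' C-x(2,4)-C and H-x(3,5)-H validation patterns.
#'
#' @param dbd_type \code{"Zn2C6"} or \code{"C2H2"}.
#' @return Amino-acid string.
#' @export
make_dbd <- function(dbd_type = c("Zn2C6", "C2H2")) {
  dbd_type <- match.arg(dbd_type)
  if (dbd_type == "Zn2C6") {
    s3 <- sample(5:16, 1)
    s5 <- sample(6:8, 1)
    paste0("C", .rand_aa(2, .AA19), "C", .rand_aa(6, .AA19),
           "C", .rand_aa(s3, .AA19), "C", .rand_aa(2, .AA19),
           "C", .rand_aa(s5, .AA19), "C")
  } else {
    core <- paste0("C", .rand_aa(sample(2:4, 1), .AA18), "C",
                   .rand_aa(sample(8:12, 1), .AA18),
                   "H", .rand_aa(sample(3:5, 1), .AA18), "H")
    pad <- 23L - nchar(core)
    if (pad > 0) core <- paste0(core, .rand_aa(pad + sample(0:3, 1), .AA18))
    core
  }
}

#' Simulation configuration
#'
#' @param n_genes Number of genes in the cohort.
#' @param error_spectrum Named probabilities over planted error classes
#'   (\code{none}, \code{frameshift}, \code{assembly_split},
#'   \code{wrong_start}, \code{missing_upstream_exon}, \code{undetermined},
#'   \code{no_dbd}); must sum to 1.
#' @param dbd_type DBD type planted in every gene.
#' @param intron_count_range Range of introns per gene body (drawn
#'   uniformly), planted at codon boundaries inside the MHD-coding region.
#' @param intron_len_range Intron length range (nt).
#' @param upstream_dbd_distance_range For \code{missing_upstream_exon}
#'   genes, the gap (an intron) between the DBD-coding exon and the
#'   annotated gene start.
#' @param neighbor_identity Target percent identity of the reference-panel
#'   homolog derived from each gene.
#' @param strain_divergence Amino-acid divergence of the genome-encoded
#'   ("strain") protein from the clean reference protein.
#' @param seed Mandatory RNG seed: cohorts are byte-identical given a seed.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 200,
                       error_spectrum = spectrum_sgd_errors(),
                       dbd_type = "Zn2C6",
                       intron_count_range = c(0L, 0L),
                       intron_len_range = c(30L, 80L),
                       upstream_dbd_distance_range = c(30L, 700L),
                       neighbor_identity = 70,
                       strain_divergence = 0.01,
                       seed) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  allowed <- c("none", "frameshift", "assembly_split", "wrong_start",
               "missing_upstream_exon", "undetermined", "no_dbd")
  if (is.null(names(error_spectrum)) || !all(names(error_spectrum) %in% allowed))
    stop("sim_config: error_spectrum must be named over ", paste(allowed, collapse = ","))
  if (abs(sum(error_spectrum) - 1) > 1e-8)
    stop("sim_config: error_spectrum must sum to 1")
  structure(list(n_genes = as.integer(n_genes), error_spectrum = error_spectrum,
                 dbd_type = dbd_type,
                 intron_count_range = as.integer(intron_count_range),
                 intron_len_range = as.integer(intron_len_range),
                 upstream_dbd_distance_range = as.integer(upstream_dbd_distance_range),
                 neighbor_identity = neighbor_identity,
                 strain_divergence = strain_divergence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset error spectra
#'
#' \code{spectrum_sgd_errors} mirrors the observed error-cause spectrum in
#' closely related yeast strain assemblies (frameshift 75\%, scaffold split
#' 4\%, wrong start codon 18\%, undetermined 3\%).
#' \code{spectrum_rescue_cohort} emulates MHD-only genes whose DBD lies
#' within the upstream window, dominated by wrong start codons and missing
#' upstream exons with a minority of frameshifts.
#' \code{spectrum_no_dbd} is the null cohort of genuinely DBD-less loci.
#'
#' @return Named probability vector usable as \code{error_spectrum}.
#' @export
spectrum_sgd_errors <- function() {
  c(frameshift = 0.75, assembly_split = 0.04, wrong_start = 0.18,
    undetermined = 0.03)
}

#' @rdname spectrum_sgd_errors
#' @export
spectrum_rescue_cohort <- function() {
  c(wrong_start = 0.4, missing_upstream_exon = 0.4, frameshift = 0.2)
}

#' @rdname spectrum_sgd_errors
#' @export
spectrum_no_dbd <- function() c(no_dbd = 1)

# Random intergenic DNA.
.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# A GT...AG intron with the requested length (>= 6 nt).
.make_intron <- function(len) {
  stopifnot(len >= 6)
  paste0("GT", .rand_dna(len - 4L), "AG")
}

#' Generate one synthetic gene with a planted error
#'
#' Builds the clean reference protein, a strain variant encoded in the
#' genome, applies the planted error to genome and/or annotation, and
#' returns all records plus the truth label.  Used by
#' \code{\link{make_cohort}}; exported for unit-level use.  Consumes the
#' caller's RNG stream.
#'
#' @param gene_id Gene identifier.
#' @param error One of the classes of \code{error_spectrum}.
#' @param config \code{\link{sim_config}}.
#' @param mhd_consensus Cohort-level 250-aa MHD consensus block.
#' @return A list with \code{scaffolds} (named character), \code{model}
#'   (\code{\link{gene_model}} of the annotated gene), \code{annotated_protein},
#'   \code{reference_protein}, \code{panel_protein}, \code{domains} and
#'   \code{panel_domains} (data frames), and \code{truth} (one-row data
#'   frame with the planted label, the true DBD peptide and its genomic
#'   span).
#' @export
make_gene <- function(gene_id, error, config, mhd_consensus) {
  window <- 1000L
  leader_len <- sample(8:20, 1)
  leader <- paste0("M", .rand_aa(leader_len - 1L))
  dbd <- if (error == "no_dbd") "" else make_dbd(config$dbd_type)
  linker <- .rand_aa(sample(25:45, 1))
  mhd <- .mutate_protein(mhd_consensus, 0.10)
  tail_ <- .rand_aa(sample(10:25, 1))
  ref_protein <- paste0(leader, dbd, linker, mhd, tail_)

  # protein coordinates (reference = strain layout; substitutions only)
  dbd_s <- leader_len + 1L
  dbd_e <- leader_len + nchar(dbd)
  linker_e <- dbd_e + nchar(linker)
  mhd_s <- linker_e + 1L
  mhd_e <- linker_e + nchar(mhd)
  plen <- nchar(ref_protein)

  protect <- if (nchar(dbd)) {
    off <- dbd_s - 1L
    if (config$dbd_type == "Zn2C6") {
      s3 <- nchar(dbd) - 16L  # includes s5; recover cysteine anchors
      # anchors: 1,4,11,12+s3',15+s3',len with s3'+s5 = len-16
      # protect every cysteine/histidine position instead (simpler, exact)
      off + which(strsplit(dbd, "")[[1]] == "C")
    } else {
      off + which(strsplit(dbd, "")[[1]] %in% c("C", "H"))
    }
  } else integer(0)

  strain_protein <- .mutate_protein(ref_protein, config$strain_divergence, protect)
  cds <- paste0(.encode_protein(strain_protein), "TAA")
  cds_len <- nchar(cds)

  # introns in the gene body (MHD-coding region), codon boundaries
  n_intr <- if (diff(config$intron_count_range) > 0)
    sample(config$intron_count_range[1]:config$intron_count_range[2], 1)
  else config$intron_count_range[1]
  intron_at <- sort(sample(seq(3L * mhd_s, 3L * (mhd_e - 2L), by = 3L),
                           n_intr))  # after this CDS position
  introns <- lapply(seq_len(n_intr), function(i)
    .make_intron(sample(config$intron_len_range[1]:config$intron_len_range[2], 1)))

  # structural gap for a missing upstream exon: an intron right after the
  # DBD-coding region, omitted from the annotation
  gap_len <- 0L
  if (error == "missing_upstream_exon") {
    r <- config$upstream_dbd_distance_range
    gap_len <- max(30L, sample(r[1]:r[2], 1))
    intron_at <- c(3L * dbd_e, intron_at)
    introns <- c(list(.make_intron(gap_len)), introns)
  }

  # frameshift insertion at a codon boundary inside the linker
  ins_at <- 0L; ins_len <- 0L
  if (error == "frameshift") {
    lo <- dbd_e + 2L
    hi <- linker_e - 2L
    ins_aa <- sample(lo:hi, 1)
    ins_at <- 3L * ins_aa             # insert after this CDS position
    ins_len <- sample(1:2, 1)
  }

  if (error %in% c("undetermined")) {
    # the DBD-coding DNA is simply absent from this assembly
    strain_nodbd <- paste0(substr(strain_protein, 1, dbd_s - 1L),
                           substr(strain_protein, dbd_e + 1L, plen))
    cds <- paste0(.encode_protein(strain_nodbd), "TAA")
    cds_len <- nchar(cds)
  }

  upflank <- window + 600L
  downflank <- 300L

  # assemble genomic gene: apply introns, then the frameshift insertion
  events <- data.frame(pos = intron_at, len = vapply(introns, nchar, integer(1)))
  if (ins_len > 0) events <- rbind(events, data.frame(pos = ins_at, len = ins_len))
  events <- events[order(events$pos), , drop = FALSE]
  seqs <- list()
  cur <- 1L
  ins_seq_all <- c(introns, if (ins_len > 0) list(.rand_dna(ins_len)))
  names(ins_seq_all) <- c(intron_at, if (ins_len > 0) ins_at)
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]
    seqs[[length(seqs) + 1L]] <- substr(cds, cur, p)
    seqs[[length(seqs) + 1L]] <- ins_seq_all[[as.character(p)]]
    cur <- p + 1L
  }
  seqs[[length(seqs) + 1L]] <- substr(cds, cur, cds_len)
  gene_dna <- paste(unlist(seqs), collapse = "")

  # CDS position -> scaffold position (before any scaffold split)
  cds2scaf <- function(p) {
    shift <- 0L
    for (i in seq_len(nrow(events)))
      if (events$pos[i] < p) shift <- shift + events$len[i]
    upflank + p + shift
  }

  scaffold <- paste0(.rand_dna(upflank), gene_dna, .rand_dna(downflank))

  # ---- annotation -------------------------------------------------------
  # annotated CDS interval(s) in CDS coordinates, then mapped to scaffold
  annot_aa_start <- 1L
  if (error == "wrong_start") {
    annot_aa_start <- sample((dbd_e + 3L):(linker_e - 5L), 1)
  } else if (error == "missing_upstream_exon") {
    annot_aa_start <- dbd_e + 1L
  } else if (error == "frameshift") {
    annot_aa_start <- ins_at / 3L + 1L
  } else if (error == "assembly_split") {
    annot_aa_start <- sample((dbd_e + 3L):(linker_e - 5L), 1)
  } else if (error == "undetermined") {
    # coordinates now refer to the DBD-less protein
    annot_aa_start <- 1L
  }

  if (error == "undetermined") {
    ann_protein <- sub("\\*$", "", translate_dna(cds, 0))
    ann_cds_iv <- c(1L, cds_len)
  } else {
    ann_protein <- substr(strain_protein, annot_aa_start, plen)
    ann_cds_iv <- c(3L * (annot_aa_start - 1L) + 1L, cds_len)
  }

  # exons: split the annotated CDS interval at introns inside it
  exon_iv <- list()
  cur <- ann_cds_iv[1]
  for (i in seq_len(nrow(events))) {
    p <- events$pos[i]
    is_intron <- as.character(p) %in% names(ins_seq_all)[seq_along(introns)] &&
      !(ins_len > 0 && p == ins_at)
    if (!is_intron) next  # frameshift insertion stays inside the exon
    if (p < ann_cds_iv[1] || p >= ann_cds_iv[2]) next
    if (p >= cur) {
      exon_iv[[length(exon_iv) + 1L]] <- c(cur, p)
      cur <- p + 1L
    }
  }
  exon_iv[[length(exon_iv) + 1L]] <- c(cur, ann_cds_iv[2])
  exons <- do.call(rbind, lapply(exon_iv, function(iv) {
    s <- cds2scaf(iv[1]); e <- cds2scaf(iv[2])
    # interior events with pos < iv start already shifted; an intron at the
    # exon's 5' boundary must not be included: cds2scaf maps the first base
    # after all insertions at positions < p, which is what we want
    c(s, e)
  }))

  scaffolds <- setNames(list(scaffold), gene_id)
  scaffold_id <- gene_id
  truth_scaffold <- gene_id

  if (error == "assembly_split") {
    cut_aa <- annot_aa_start - 1L      # split just upstream of the annotation
    cut <- cds2scaf(3L * cut_aa)
    scafA <- substr(scaffold, 1L, cut)
    scafB <- substr(scaffold, cut + 1L, nchar(scaffold))
    scaffolds <- setNames(list(scafA, scafB), paste0(gene_id, c("_a", "_b")))
    exons[, 1] <- exons[, 1] - cut
    exons[, 2] <- exons[, 2] - cut
    scaffold_id <- paste0(gene_id, "_b")
    truth_scaffold <- paste0(gene_id, "_a")
  }

  pid <- paste0(gene_id, "_p")
  model <- gene_model(gene_id, scaffold_id, "+", exons, protein_id = pid)

  # domain annotations of the annotated protein
  shift <- if (error == "undetermined") dbd_e - dbd_s + 1L else annot_aa_start - 1L
  dom <- data.frame(protein_id = pid, domain_type = "MHD",
                    start = mhd_s - shift, end = mhd_e - shift, score = NA_real_)
  if (error == "none") {
    dom <- rbind(data.frame(protein_id = pid, domain_type = config$dbd_type,
                            start = dbd_s, end = dbd_e, score = NA_real_), dom)
  }

  # panel homolog: full architecture at the target identity
  panel_base <- if (nchar(dbd)) ref_protein else
    paste0(leader, make_dbd(config$dbd_type), linker, mhd, tail_)
  if (!nchar(dbd)) {  # fresh DBD inserted for DBD-less loci
    pb_dbd_s <- leader_len + 1L
    pb_dbd_e <- leader_len + (nchar(panel_base) - plen)
  } else {
    pb_dbd_s <- dbd_s; pb_dbd_e <- dbd_e
  }
  pb_chars <- strsplit(panel_base, "")[[1]]
  pb_protect <- (pb_dbd_s:pb_dbd_e)[pb_chars[pb_dbd_s:pb_dbd_e] %in% c("C", "H")]
  panel_protein <- .mutate_protein(panel_base, 1 - config$neighbor_identity / 100,
                                  pb_protect)
  panel_id <- paste0("P_", gene_id)
  pb_len <- nchar(panel_base)
  panel_dom <- data.frame(
    protein_id = panel_id,
    domain_type = c(config$dbd_type, "MHD"),
    start = c(pb_dbd_s, pb_len - nchar(tail_) - nchar(mhd) + 1L),
    end = c(pb_dbd_e, pb_len - nchar(tail_)),
    score = NA_real_)

  # truth
  has_dbd_in_genome <- !(error %in% c("no_dbd", "undetermined"))
  truth <- data.frame(
    gene_id = gene_id, protein_id = pid, planted_error = error,
    dbd_type = if (has_dbd_in_genome) config$dbd_type else NA_character_,
    true_dbd_peptide = if (has_dbd_in_genome)
      substr(strain_protein, dbd_s, dbd_e) else NA_character_,
    scaffold_id = if (has_dbd_in_genome) truth_scaffold else NA_character_,
    dbd_start = if (has_dbd_in_genome) cds2scaf(3L * (dbd_s - 1L) + 1L) else NA_integer_,
    dbd_end = if (has_dbd_in_genome) cds2scaf(3L * dbd_e) else NA_integer_)

  list(scaffolds = scaffolds, model = model,
       annotated_protein = ann_protein,
       reference_protein = ref_protein,
       panel_protein = setNames(panel_protein, panel_id),
       domains = dom, panel_domains = panel_dom, truth = truth)
}

#' Generate a synthetic cohort
#'
#' Draws the planted-error class of each gene from the configured spectrum,
#' builds every gene with \code{\link{make_gene}}, and optionally writes the
#' standard files (genome FASTA, GFF3, annotated proteome, domain TSV,
#' reference proteome, panel FASTA + domain TSV, truth TSV).  Output is
#' byte-identical across runs with equal seeds.
#'
#' @param config \code{\link{sim_config}}.
#' @param out_dir Optional directory to write the cohort files into.
#' @return Invisibly, a list of class \code{synthetic_cohort}:
#'   \code{genome} (DNAStringSet), \code{models}, \code{proteome}
#'   (annotated proteins, AAStringSet), \code{domains},
#'   \code{references} (clean reference proteins), \code{panel_proteins},
#'   \code{panel_domains}, \code{truth}, \code{config}.
#' @export
make_cohort <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  mhd_consensus <- .rand_aa(250, .AA19)
  errors <- sample(names(config$error_spectrum), config$n_genes,
                   replace = TRUE, prob = config$error_spectrum)
  ids <- sprintf("g%03d", seq_len(config$n_genes))
  genes <- lapply(seq_len(config$n_genes), function(i)
    make_gene(ids[i], errors[i], config, mhd_consensus))

  genome <- Biostrings::DNAStringSet(unlist(lapply(genes, `[[`, "scaffolds")))
  models <- lapply(genes, `[[`, "model")
  names(models) <- ids
  proteome <- Biostrings::AAStringSet(setNames(
    vapply(genes, `[[`, character(1), "annotated_protein"),
    vapply(models, `[[`, character(1), "protein_id")))
  references <- Biostrings::AAStringSet(setNames(
    vapply(genes, `[[`, character(1), "reference_protein"),
    paste0("R_", ids)))
  panel_proteins <- Biostrings::AAStringSet(unlist(lapply(genes, `[[`, "panel_protein")))
  domains <- do.call(rbind, lapply(genes, `[[`, "domains"))
  panel_domains <- do.call(rbind, lapply(genes, `[[`, "panel_domains"))
  truth <- do.call(rbind, lapply(genes, `[[`, "truth"))

  cohort <- structure(list(genome = genome, models = models,
                           proteome = proteome, domains = domains,
                           references = references,
                           panel_proteins = panel_proteins,
                           panel_domains = panel_domains,
                           truth = truth, config = config),
                      class = "synthetic_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(genome, file.path(out_dir, "genome.fna"))
    write_gff3(models, file.path(out_dir, "genes.gff3"))
    write_fasta(proteome, file.path(out_dir, "proteome.faa"))
    write_fasta(references, file.path(out_dir, "reference.faa"))
    write_fasta(panel_proteins, file.path(out_dir, "panel.faa"))
    write_domain_tsv(domains, file.path(out_dir, "domains.tsv"))
    write_domain_tsv(panel_domains, file.path(out_dir, "panel_domains.tsv"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(cohort)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d genes, %d scaffolds, seed %d\n",
              length(x$models), length(x$genome), x$config$seed))
  print(table(x$truth$planted_error))
  invisible(x)
}
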