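# Sequence and annotation I/O.
#
# Genomes are held as Biostrings::DNAStringSet (one element per scaffold),
# proteomes as AAStringSet.  Gene models are lightweight S3 records with
# 1-based closed exon intervals in ascending scaffold order.

.DNA_OK <- c("A", "C", "G", "T", "N")
.AA_OK <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

.validate_alphabet <- function(x, ok, path, kind) {
  seqs <- as.character(x)
  for (i in seq_along(seqs)) {
    bad <- setdiff(unique(strsplit(seqs[[i]], "")[[1]]), ok)
    if (length(bad)) {
      stop(sprintf("%s: illegal %s character(s) '%s' in record '%s' (record %d)",
                   path, kind, paste(bad, collapse = ""), names(seqs)[i] %||% i, i),
           call. = FALSE)
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Read a genome FASTA
#'
#' Sequences are upper-cased and validated against the \code{A,C,G,T,N}
#' alphabet; records are returned in file order with unique scaffold ids.
#'
#' @param path FASTA file.
#' @return A \link[Biostrings]{DNAStringSet}, one element per scaffold.
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop(path, ": no FASTA records")
  x <- Biostrings::BStringSet(toupper(as.character(x)))
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) stop(path, ": duplicate scaffold id")
  .validate_alphabet(x, .DNA_OK, path, "DNA")
  as(x, "DNAStringSet")
}

#' Read a protein FASTA
#'
#' @param path FASTA file.
#' @return A \link[Biostrings]{AAStringSet} (20 amino acids plus X and *).
#' @export
read_protein_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) stop(path, ": no FASTA records")
  x <- Biostrings::BStringSet(toupper(as.character(x)))
  names(x) <- sub("\\s.*$", "", names(x))
  .validate_alphabet(x, .AA_OK, path, "amino-acid")
  as(x, "AAStringSet")
}

#' Write sequences to FASTA
#'
#' @param x A named character vector or XStringSet.
#' @param path Output file.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Construct a gene model
#'
#' @param gene_id,scaffold_id,protein_id Identifiers.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons Two-column matrix (start, end) of CDS intervals, 1-based
#'   closed, ascending scaffold order, non-overlapping.
#' @return An object of class \code{gene_model}.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, exons, protein_id = gene_id) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(as.matrix(exons)), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (any(exons[, 2] < exons[, 1])) stop("gene_model: exon end < start")
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("gene_model: overlapping CDS intervals in one model")
  structure(list(gene_id = gene_id, scaffold_id = scaffold_id, strand = strand,
                 exons = exons, protein_id = protein_id),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s) %d exon(s), span %d-%d, protein %s\n",
              x$gene_id, x$scaffold_id, x$strand, nrow(x$exons),
              min(x$exons), max(x$exons), x$protein_id))
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/CDS features; returns one \code{\link{gene_model}} per
#' mRNA, with CDS intervals in ascending scaffold order (1-based closed, as
#' in GFF3).  A CDS without a parent, or overlapping CDS within one mRNA,
#' is an error.
#'
#' @param path GFF3 file.
#' @return A named list of \code{gene_model} objects, in file order.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  mrna <- gr[typ == "mRNA"]
  cds <- gr[typ == "CDS"]
  if (length(cds) == 0) stop(path, ": no CDS features")
  parents <- gr$Parent[typ == "CDS"]
  if (is.null(parents) || any(lengths(parents) == 0))
    stop(path, ": CDS feature without Parent")
  parent <- vapply(parents, `[`, character(1), 1L)
  ids <- as.character(mrna$ID)
  models <- vector("list", length(mrna))
  for (i in seq_along(mrna)) {
    sel <- parent == ids[i]
    if (!any(sel)) next
    ci <- cds[sel]
    pid <- mrna$protein_id[i] %||% ids[i]
    models[[i]] <- gene_model(
      gene_id = ids[i],
      scaffold_id = as.character(GenomicRanges::seqnames(ci))[1],
      strand = as.character(GenomicRanges::strand(mrna))[i],
      exons = cbind(GenomicRanges::start(ci), GenomicRanges::end(ci)),
      protein_id = pid
    )
  }
  models <- models[!vapply(models, is.null, logical(1))]
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

#' Write gene models to GFF3
#'
#' @param models List of \code{\link{gene_model}} objects.
#' @param path Output file.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- range(m$exons)
    writeLines(sprintf("%s\tdbdrescue\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
                       m$scaffold_id, span[1], span[2], m$strand, m$gene_id), con)
    writeLines(sprintf("%s\tdbdrescue\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=gene:%s;protein_id=%s",
                       m$scaffold_id, span[1], span[2], m$strand,
                       m$gene_id, m$gene_id, m$protein_id), con)
    ex <- m$exons
    tx_order <- if (m$strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    phase <- 0L
    phases <- integer(nrow(ex))
    for (k in tx_order) {
      phases[k] <- phase
      phase <- (3L - (ex[k, 2] - ex[k, 1] + 1L - phase) %% 3L) %% 3L
    }
    for (k in seq_len(nrow(ex))) {
      writeLines(sprintf("%s\tdbdrescue\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s;Parent=%s",
                         m$scaffold_id, ex[k, 1], ex[k, 2], m$strand, phases[k],
                         m$gene_id, m$gene_id), con)
    }
  }
  invisible(path)
}

#' CDS and protein sequence of a gene model
#'
#' @param model A \code{\link{gene_model}}.
#' @param genome A \link[Biostrings]{DNAStringSet} containing the scaffold.
#' @return \code{cds_sequence}: the spliced CDS in transcript orientation;
#'   \code{model_protein}: its translation.
#' @export
cds_sequence <- function(model, genome) {
  scaf <- genome[[model$scaffold_id]]
  if (max(model$exons) > length(scaf)) stop("gene_model exceeds scaffold bounds")
  parts <- apply(model$exons, 1L, function(iv)
    as.character(Biostrings::subseq(scaf, iv[1], iv[2])))
  s <- paste(parts, collapse = "")
  if (model$strand == "-") s <- reverse_complement(s)
  s
}

#' @rdname cds_sequence
#' @param code Genetic code passed to \code{\link{translate_dna}}.
#' @export
model_protein <- function(model, genome, code = "standard") {
  sub("\\*$", "", translate_dna(cds_sequence(model, genome), 0, code))
}

#' Read / write a protein domain annotation table
#'
#' Tab-separated with header \code{protein_id, domain_type, start, end,
#' score}; coordinates are 1-based closed protein positions, score is
#' numeric or \code{"."} for annotation-derived hits.
#'
#' @param path TSV file.
#' @return \code{data.frame} with columns \code{protein_id},
#'   \code{domain_type}, \code{start}, \code{end}, \code{score}.
#' @export
read_domain_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("protein_id", "domain_type", "start", "end", "score")
  if (!all(need %in% names(d))) stop(path, ": domain TSV must have columns ",
                                     paste(need, collapse = ", "))
  d$start <- as.integer(d$start)
  d$end <- as.integer(d$end)
  d$score <- suppressWarnings(as.numeric(ifelse(d$score == ".", NA, d$score)))
  bad <- d$domain_type[!d$domain_type %in% c("Zn2C6", "C2H2", "MHD")]
  if (length(bad)) stop(path, ": unknown domain_type ", paste(unique(bad), collapse = ","))
  if (any(d$start < 1L | d$end < d$start)) stop(path, ": invalid domain coordinates")
  d[need]
}

#' @rdname read_domain_tsv
#' @param d Domain hit data frame.
#' @export
write_domain_tsv <- function(d, path) {
  d$score <- ifelse(is.na(d$score), ".", format(d$score))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
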