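test_that("genomic context extraction windows, clamps and flips strand", {
  genome <- Biostrings::DNAStringSet(c(s = random_dna(8000)))
  m <- gene_model("g", "s", "+", rbind(c(5001, 6200)))
  ctx <- extract_genomic_context(m, genome, 1000)
  expect_equal(c(ctx$region_start, ctx$region_end), c(4001L, 6200L))
  expect_equal(ctx$upstream, 1000L)
  expect_false(ctx$truncated)
  expect_equal(ctx$seq, as.character(Biostrings::subseq(genome[[1]], 4001, 6200)))

  m2 <- gene_model("g2", "s", "+", rbind(c(201, 800)))
  ctx2 <- extract_genomic_context(m2, genome, 1000)
  expect_equal(ctx2$region_start, 1L)
  expect_equal(ctx2$upstream, 200L)
  expect_true(ctx2$truncated)

  m3 <- gene_model("g3", "s", "-", rbind(c(5001, 6200)))
  ctx3 <- extract_genomic_context(m3, genome, 1000)
  expect_equal(c(ctx3$region_start, ctx3$region_end), c(5001L, 7200L))
  expect_equal(ctx3$seq, reverse_complement(
    as.character(Biostrings::subseq(genome[[1]], 5001, 7200))))
})

test_that("nearest-neighbor search picks the strongest qualifying homolog", {
  set.seed(20)
  base <- paste0("M", random_protein(300))
  mut <- dbdrescue:::.mutate_protein(base, 0.10)
  far <- dbdrescue:::.mutate_protein(base, 0.55)
  prots <- Biostrings::AAStringSet(c(A = mut, B = far, Z = mut))
  doms <- do.call(rbind, lapply(c("A", "B", "Z"), function(id)
    data.frame(protein_id = id, domain_type = c("Zn2C6", "MHD"),
               start = c(2L, 45L), end = c(40L, 290L), score = NA_real_)))
  panel <- build_reference_panel(prots, doms, "Zn2C6")
  nn <- find_nearest_neighbor(base, panel)
  expect_equal(nn$neighbor_id, "A")  # tie with Z broken lexicographically
  expect_lt(nn$hit$evalue, 0.005)
  # random query: nothing qualifies
  expect_null(find_nearest_neighbor(random_protein(80), panel))
})

test_that("a planted upstream DBD is recovered exactly, wrong-start case", {
  co <- make_cohort(sim_config(n_genes = 8, error_spectrum = c(wrong_start = 1),
                               seed = 777))
  run <- recover_cohort(co)
  res <- run$results
  expect_true(all(res$status == "recovered"))
  expect_equal(res$peptide, co$truth$true_dbd_peptide)
  expect_true(all(res$rel_start < 0))  # DBD upstream of the annotated start
  expect_true(all(res$patterns_ok))
  # reported genomic span matches the planted truth span
  expect_equal(res$genomic_start, co$truth$dbd_start)
  expect_equal(res$genomic_end, co$truth$dbd_end)
})

test_that("a DBD beyond the upstream window is triaged as too distant", {
  co <- make_cohort(sim_config(n_genes = 6,
                               error_spectrum = c(missing_upstream_exon = 1),
                               upstream_dbd_distance_range = c(1400L, 1500L),
                               seed = 778))
  run <- recover_cohort(co)
  expect_true(all(run$results$status == "failed"))
  expect_true(all(run$results$reason == "too_distant"))
})

test_that("an undetermined-base run over the target region is reported", {
  co <- make_cohort(sim_config(n_genes = 6, error_spectrum = c(wrong_start = 1),
                               seed = 779))
  m <- co$models[[1]]
  tr <- co$truth[1, ]
  scaf <- as.character(co$genome[[m$scaffold_id]])
  # blank the DBD region with Ns
  substr(scaf, tr$dbd_start - 20, tr$dbd_end + 20) <-
    strrep("N", tr$dbd_end - tr$dbd_start + 41)
  genome <- co$genome
  genome[[m$scaffold_id]] <- Biostrings::DNAString(scaf)
  panel <- build_reference_panel(co$panel_proteins, co$panel_domains, "Zn2C6")
  prof <- build_dbd_profile(panel)
  qd <- co$domains[co$domains$protein_id == m$protein_id, ]
  r <- recover_dbd(m, as.character(co$proteome[[m$protein_id]]), qd,
                   genome, panel, list(Zn2C6 = prof))
  expect_equal(r$status, "failed")
  expect_equal(r$reason, "n_region")
})

test_that("recovery is invariant to strand flipping", {
  co <- make_cohort(sim_config(n_genes = 6, error_spectrum = c(wrong_start = 1),
                               seed = 780))
  panel <- build_reference_panel(co$panel_proteins, co$panel_domains, "Zn2C6")
  prof <- build_dbd_profile(panel)
  profs <- list(Zn2C6 = prof)
  for (i in 1:3) {
    m <- co$models[[i]]
    qp <- as.character(co$proteome[[m$protein_id]])
    qd <- co$domains[co$domains$protein_id == m$protein_id, ]
    r1 <- recover_dbd(m, qp, qd, co$genome, panel, profs)
    # flip the scaffold and the gene model
    L <- length(co$genome[[m$scaffold_id]])
    flipped <- co$genome
    flipped[[m$scaffold_id]] <- Biostrings::reverseComplement(flipped[[m$scaffold_id]])
    ex <- m$exons
    ex2 <- cbind(L - ex[, 2] + 1L, L - ex[, 1] + 1L)
    m2 <- gene_model(m$gene_id, m$scaffold_id, "-", ex2, m$protein_id)
    r2 <- recover_dbd(m2, qp, qd, flipped, panel, profs)
    expect_equal(r1$status, "recovered")
    expect_equal(r2$status, "recovered")
    expect_identical(r1$peptide, r2$peptide)
    expect_equal(r1$genomic_span, L - rev(r2$genomic_span) + 1L)
  }
})

test_that("C-terminal control stays silent on clean genes, catches a decoy", {
  co <- make_cohort(sim_config(n_genes = 6, error_spectrum = c(none = 1),
                               seed = 781))
  panel <- build_reference_panel(co$panel_proteins, co$panel_domains, "Zn2C6")
  prof <- build_dbd_profile(panel)
  profs <- list(Zn2C6 = prof)
  m <- co$models[[1]]
  qp <- as.character(co$proteome[[m$protein_id]])
  qd <- co$domains[co$domains$protein_id == m$protein_id, ]
  qd_mhd <- qd[qd$domain_type == "MHD", ]
  r <- cterm_control(m, qp, qd_mhd, co$genome, panel, profs)
  expect_true(is.null(r) || r$status != "recovered")

  # plant a decoy DBD downstream of the gene: the control must catch it
  set.seed(1)
  decoy_src <- as.character(panel$proteins[[1]])
  nd <- panel$domains[panel$domains$protein_id == names(panel$proteins)[1] &
                        panel$domains$domain_type == "Zn2C6", ]
  decoy <- substring(decoy_src, nd$start, nd$end)
  scaf <- as.character(co$genome[[m$scaffold_id]])
  ins_at <- max(m$exons) + 50L
  scaf2 <- paste0(substr(scaf, 1, ins_at), dbdrescue:::.encode_protein(decoy),
                  substr(scaf, ins_at + 1, nchar(scaf)))
  genome2 <- co$genome
  genome2[[m$scaffold_id]] <- Biostrings::DNAString(scaf2)
  r2 <- cterm_control(m, qp, qd_mhd, genome2, panel, profs)
  expect_false(is.null(r2))
  expect_equal(r2$status, "recovered")
})

test_that("a found-by-both candidate is never rejected when one route suffices", {
  run <- rescue_run(40)
  res <- run$results
  rec <- res[res$status == "recovered", ]
  expect_gt(nrow(rec), 0)
  # methods reported from the closed set; "both" dominates when routes agree
  expect_true(all(rec$method %in% c("local", "global", "both")))
})
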