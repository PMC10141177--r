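test_that("generated DBD peptides satisfy their own detectors by construction", {
  set.seed(60)
  for (i in 1:50) {
    z <- make_dbd("Zn2C6")
    m <- find_zn2c6_motif(z)
    expect_equal(nrow(m), 1L)
    expect_equal(c(m$start, m$end), c(1L, nchar(z)))
    expect_true(nchar(z) >= 27 && nchar(z) <= 40)  # 16 + (5..16) + (6..8)
    expect_true(check_validation_patterns(z, "Zn2C6"))
    c2 <- make_dbd("C2H2")
    expect_true(check_validation_patterns(c2, "C2H2"))
    expect_true(nchar(c2) >= 23 && nchar(c2) <= 28)
  }
})

test_that("cohorts are byte-identical across runs with the same seed", {
  cfg <- sim_config(n_genes = 6, error_spectrum = spectrum_rescue_cohort(),
                    intron_count_range = c(0L, 2L), seed = 424)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  make_cohort(cfg, d1)
  make_cohort(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  d3 <- withr::local_tempdir()
  make_cohort(sim_config(n_genes = 6, error_spectrum = spectrum_rescue_cohort(),
                         intron_count_range = c(0L, 2L), seed = 425), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "genome.fna"))),
                         unname(tools::md5sum(file.path(d3, "genome.fna")))))
})

test_that("planted error counts follow the configured spectrum", {
  co <- sgd_cohort(200)
  counts <- table(factor(co$truth$planted_error,
                         levels = names(spectrum_sgd_errors())))
  p <- spectrum_sgd_errors()
  for (cls in names(p)) {
    ci <- stats::qbinom(c(0.0005, 0.9995), 200, p[[cls]])
    expect_gte(counts[[cls]], ci[1])
    expect_lte(counts[[cls]], ci[2])
  }
})

test_that("panel homologs sit at the configured identity", {
  co <- rescue_cohort(40)
  set.seed(61)
  ids <- sample(names(co$models), 15)
  pid <- vapply(ids, function(gid) {
    ref <- co$references[[paste0("R_", gid)]]
    pan <- co$panel_proteins[[paste0("P_", gid)]]
    aln <- Biostrings::pairwiseAlignment(ref, pan, type = "global",
                                         substitutionMatrix = dbdrescue:::.submat(),
                                         gapOpening = 11, gapExtension = 1)
    Biostrings::pid(aln)
  }, numeric(1))
  expect_gt(mean(pid), 67)
  expect_lt(mean(pid), 73)
})

test_that("truth spans round-trip: the genomic DBD span encodes the truth peptide", {
  co <- rescue_cohort(40)
  tr <- co$truth
  for (i in seq_len(nrow(tr))) {
    if (is.na(tr$dbd_start[i])) next
    seg <- as.character(Biostrings::subseq(co$genome[[tr$scaffold_id[i]]],
                                           tr$dbd_start[i], tr$dbd_end[i]))
    expect_equal(translate_dna(seg, 0), tr$true_dbd_peptide[i], info = tr$gene_id[i])
  }
})

test_that("annotated proteins agree with their gene models and error labels", {
  co <- rescue_cohort(40)
  for (gid in names(co$models)) {
    m <- co$models[[gid]]
    expect_equal(model_protein(m, co$genome),
                 as.character(co$proteome[[m$protein_id]]), info = gid)
  }
  # planted-error proteins lack the motif; clean ones carry it
  clean <- make_cohort(sim_config(n_genes = 5, error_spectrum = c(none = 1),
                                  seed = 62))
  for (i in seq_len(5)) {
    expect_equal(nrow(find_zn2c6_motif(as.character(clean$proteome[[i]]))), 1L)
  }
  for (i in which(co$truth$planted_error != "none")) {
    expect_equal(nrow(find_zn2c6_motif(
      as.character(co$proteome[[co$truth$protein_id[i]]]))), 0L,
      info = co$truth$gene_id[i])
  }
})
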