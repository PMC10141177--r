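# hand-built single-gene scenarios with known ground truth
build_scenario <- function(error = c("none", "frameshift", "wrong_start", "split"),
                           seed = 1) {
  error <- match.arg(error)
  set.seed(seed)
  lead <- paste0("M", random_protein(14))
  dbd <- make_dbd("Zn2C6")
  linker <- random_protein(30)
  mhd <- random_protein(250)
  prot <- paste0(lead, dbd, linker, mhd)
  cds <- dbdrescue:::.encode_protein(prot)
  flank <- random_dna(400)
  list(prot = prot, cds = cds, flank = flank,
       dbd_end_nt = 3 * (15 + nchar(dbd)))
}

test_that("diagnosis applies the multi-scaffold, frame and coverage rules", {
  sc <- build_scenario()
  th <- dbd_thresholds()
  # frameshift: 1-nt insertion downstream of the DBD
  pos <- sc$dbd_end_nt + 33
  g_fs <- Biostrings::DNAStringSet(c(s1 = paste0(
    sc$flank, substr(sc$cds, 1, pos), "A",
    substr(sc$cds, pos + 1, nchar(sc$cds)), sc$flank)))
  d <- diagnose_missing_dbd(sc$prot, g_fs, th)
  expect_equal(d$cause, "frameshift")
  expect_equal(d$scaffold_count, 1L)
  expect_gte(d$frame_count, 2L)

  # split over two scaffolds
  cut <- sc$dbd_end_nt + 60
  g_sp <- Biostrings::DNAStringSet(c(
    s1 = paste0(sc$flank, substr(sc$cds, 1, cut)),
    s2 = paste0(substr(sc$cds, cut + 1, nchar(sc$cds)), sc$flank)))
  d <- diagnose_missing_dbd(sc$prot, g_sp, th)
  expect_equal(d$cause, "assembly_split")
  expect_equal(d$scaffold_count, 2L)

  # intact genome, wrong annotation: single 100%-coverage hit
  g_ok <- Biostrings::DNAStringSet(c(s1 = paste0(sc$flank, sc$cds, sc$flank)))
  d <- diagnose_missing_dbd(sc$prot, g_ok, th)
  expect_equal(d$cause, "wrong_start")
  expect_equal(d$coverage, 100L)

  # nothing alignable
  d <- diagnose_missing_dbd(sc$prot,
                            Biostrings::DNAStringSet(c(s1 = random_dna(2000))), th)
  expect_equal(d$cause, "undetermined")
  d <- diagnose_missing_dbd(sc$prot, Biostrings::DNAStringSet(), th)
  expect_equal(d$cause, "undetermined")
  expect_equal(nrow(d$evidence), 0L)
})

test_that("diagnosis is invariant to scaffold ordering", {
  sc <- build_scenario(seed = 2)
  cut <- sc$dbd_end_nt + 45
  g <- Biostrings::DNAStringSet(c(
    s1 = paste0(sc$flank, substr(sc$cds, 1, cut)),
    s2 = paste0(substr(sc$cds, cut + 1, nchar(sc$cds)), sc$flank)))
  d1 <- diagnose_missing_dbd(sc$prot, g, dbd_thresholds())
  d2 <- diagnose_missing_dbd(sc$prot, rev(g), dbd_thresholds())
  expect_equal(d1$cause, d2$cause)
  expect_equal(d1$coverage, d2$coverage)
})

test_that("reconstruction restores the motif across a frameshift", {
  sc <- build_scenario(seed = 3)
  pos <- sc$dbd_end_nt + 30  # insertion upstream of the MHD, downstream of the motif
  g <- Biostrings::DNAStringSet(c(s1 = paste0(
    sc$flank, substr(sc$cds, 1, pos), "GA",
    substr(sc$cds, pos + 1, nchar(sc$cds)), sc$flank)))
  d <- diagnose_missing_dbd(sc$prot, g, dbd_thresholds())
  expect_equal(d$cause, "frameshift")
  cp <- reconstruct_protein(d, g)
  expect_true(cp$motif_found)
  expect_false(cp$partial)

  # error-free genome: the reconstruction is the reference translation
  g_ok <- Biostrings::DNAStringSet(c(s1 = paste0(sc$flank, sc$cds, sc$flank)))
  d_ok <- diagnose_missing_dbd(sc$prot, g_ok, dbd_thresholds())
  cp_ok <- reconstruct_protein(d_ok, g_ok)
  expect_equal(cp_ok$sequence, sc$prot)

  # split: fragments returned, flagged partial
  cut <- sc$dbd_end_nt + 21
  g_sp <- Biostrings::DNAStringSet(c(
    s1 = paste0(sc$flank, substr(sc$cds, 1, cut)),
    s2 = paste0(substr(sc$cds, cut + 1, nchar(sc$cds)), sc$flank)))
  d_sp <- diagnose_missing_dbd(sc$prot, g_sp, dbd_thresholds())
  cp_sp <- reconstruct_protein(d_sp, g_sp)
  expect_true(cp_sp$partial)
  expect_equal(length(cp_sp$fragments), 2L)
})

test_that("track_errors screens motif-bearing orthologs as ok", {
  sc <- build_scenario(seed = 4)
  g <- Biostrings::DNAStringSet(c(s1 = paste0(sc$flank, sc$cds, sc$flank)))
  out <- track_errors(sc$prot, sc$prot, g)
  expect_equal(out$status, "ok")
  out2 <- track_errors(sc$prot, NA, g)
  expect_equal(out2$status, "missing")
  trunc <- substring(sc$prot, 60)
  out3 <- track_errors(sc$prot, trunc, g)
  expect_equal(out3$status, "error")
  expect_equal(out3$cause, "wrong_start")
  expect_true(out3$motif_recovered)
})

test_that("clean no-error genes in a cohort all screen as ok", {
  co <- make_cohort(sim_config(n_genes = 15, error_spectrum = c(none = 1),
                               seed = 555))
  out <- diagnose_cohort(co)
  expect_true(all(out$status == "ok"))
  expect_true(all(out$cause == "none"))
})
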