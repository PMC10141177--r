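make_test_panel <- function(n = 12, dbd_type = "Zn2C6", seed = 99) {
  set.seed(seed)
  prots <- character(n); doms <- list()
  for (i in seq_len(n)) {
    lead <- paste0("M", random_protein(10))
    dbd <- make_dbd(dbd_type)
    mhd <- random_protein(250)
    prots[i] <- paste0(lead, dbd, mhd)
    doms[[i]] <- data.frame(
      protein_id = sprintf("pp%02d", i),
      domain_type = c(dbd_type, "MHD"),
      start = c(12L, 12L + nchar(dbd)),
      end = c(11L + nchar(dbd), 11L + nchar(dbd) + 250L),
      score = NA_real_)
  }
  names(prots) <- sprintf("pp%02d", seq_len(n))
  build_reference_panel(Biostrings::AAStringSet(prots), do.call(rbind, doms),
                        dbd_type)
}

test_that("panel filtering follows architecture classification", {
  panel <- make_test_panel(10)
  expect_equal(length(panel$proteins), 10L)
  # MHD-only proteins are excluded; wrong type errors out
  prots <- as.character(panel$proteins)
  doms <- panel$domains
  extra <- Biostrings::AAStringSet(c(prots, only = random_protein(300)))
  doms2 <- rbind(doms, data.frame(protein_id = "only", domain_type = "MHD",
                                  start = 20L, end = 280L, score = NA_real_))
  p2 <- build_reference_panel(extra, doms2, "Zn2C6")
  expect_equal(length(p2$proteins), 10L)
  expect_error(build_reference_panel(extra, doms2, "C2H2"), "no C2H2-MHD")
  # a protein with both DBD types goes to the Zn2C6 panel only
  both <- rbind(doms2, data.frame(protein_id = "only", domain_type = c("Zn2C6", "C2H2"),
                                  start = c(1L, 10L), end = c(8L, 16L),
                                  score = NA_real_))
  p3 <- build_reference_panel(extra, both, "Zn2C6")
  expect_true("only" %in% names(p3$proteins))
  expect_error(build_reference_panel(extra, both, "C2H2"), "no C2H2-MHD")
})

test_that("Zn2C6 profile separates true domains from background", {
  panel <- make_test_panel(12)
  prof <- build_dbd_profile(panel)
  expect_equal(prof$length, 40L)
  expect_equal(length(prof$null_scores), 10000L)
  set.seed(100)
  # fresh (unseen) DBDs score far into the null tail
  ev_true <- replicate(20, profile_evalue(make_dbd("Zn2C6"), prof))
  expect_lt(max(ev_true), 0.05)
  # random peptides do not
  ev_null <- replicate(50, profile_evalue(random_protein(45, c_freq = 0.05), prof))
  expect_gt(mean(ev_null > 0.1), 0.8)
})

test_that("C2H2 profile accepts fresh C2H2 domains", {
  panel <- make_test_panel(10, dbd_type = "C2H2", seed = 101)
  prof <- build_dbd_profile(panel)
  set.seed(102)
  ev_true <- replicate(20, profile_evalue(make_dbd("C2H2"), prof))
  expect_lt(stats::median(ev_true), 0.1)
})

test_that("the profile null is reproducible and a small panel errors", {
  panel <- make_test_panel(12)
  p1 <- build_dbd_profile(panel, null_seed = 5)
  p2 <- build_dbd_profile(panel, null_seed = 5)
  expect_identical(p1$null_scores, p2$null_scores)
  small <- panel
  small$proteins <- small$proteins[1:3]
  small$domains <- small$domains[small$domains$protein_id %in% names(small$proteins), ]
  expect_error(build_dbd_profile(small), "at least 5")
})
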