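test_that("translation follows the standard code with stop, frame and N rules", {
  expect_equal(translate_dna("ATGAAATAA", 0), "MK*")
  expect_equal(translate_dna("ATGAAA", 1), "*")     # TGA read, trailing AA dropped
  expect_equal(translate_dna("ATNAAA", 0), "XK")
  expect_equal(translate_dna("AT", 0), "")
  expect_equal(translate_dna("ctgctg", 0), "LL")
  expect_equal(translate_dna("CTGCTG", 0, code = "ctg_ser"), "SS")
})

test_that("reverse-strand translation agrees with an independent oracle", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_dna(sample(30:120, 1))
    mine <- translate_dna(reverse_complement(s), 0)
    oracle <- suppressWarnings(as.character(Biostrings::translate(
      Biostrings::reverseComplement(Biostrings::DNAString(s)),
      if.fuzzy.codon = "solve", no.init.codon = TRUE)))
    # oracle keeps a trailing partial codon off as well
    expect_equal(mine, substr(oracle, 1, nchar(mine)), info = s)
  }
})

test_that("Zn2C6 motif search handles the spacing bounds", {
  minimal <- paste0("C", "AA", "C", strrep("A", 6), "C", strrep("A", 5),
                    "C", "AA", "C", strrep("A", 6), "C")
  m <- find_zn2c6_motif(minimal)
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(1L, 27L))

  toolong <- paste0("C", "AA", "C", strrep("A", 6), "C", strrep("A", 17),
                    "C", "AA", "C", strrep("A", 6), "C")
  expect_equal(nrow(find_zn2c6_motif(toolong)), 0L)

  expect_equal(nrow(find_zn2c6_motif(strrep("ADE", 60))), 0L)

  # X can sit in a spacer but never at a cysteine anchor
  xsp <- paste0("C", "XX", "C", strrep("X", 6), "C", strrep("A", 5),
                "C", "AA", "C", strrep("A", 6), "C")
  expect_equal(nrow(find_zn2c6_motif(xsp)), 1L)
  xanchor <- sub("^C", "X", minimal)
  expect_equal(nrow(find_zn2c6_motif(xanchor)), 0L)
})

test_that("motif search equals brute-force spacer enumeration on random proteins", {
  set.seed(7)
  for (i in 1:150) {
    p <- random_protein(sample(30:200, 1), c_freq = 0.15)
    expect_equal(find_zn2c6_motif(p), zn2c6_oracle(p), info = p)
  }
})

test_that("validation patterns are counted greedily and non-overlapping", {
  expect_true(check_validation_patterns("CAACDDDCAAC", "Zn2C6"))
  expect_false(check_validation_patterns("CAAC", "Zn2C6"))
  expect_false(check_validation_patterns("CAACAAC", "Zn2C6"))  # shared C
  expect_true(check_validation_patterns("CAACHAAAH", "C2H2"))
  expect_false(check_validation_patterns("CAACHAH", "C2H2"))
  expect_false(check_validation_patterns("HAAAH", "C2H2"))
})

test_that("architecture classification is total and follows precedence", {
  expect_equal(classify_architecture("MHD"), "MHD-only")
  expect_equal(classify_architecture(c("Zn2C6", "MHD")), "Zn2C6-MHD")
  expect_equal(classify_architecture(c("C2H2", "C2H2", "MHD")), "C2H2-MHD")
  expect_equal(classify_architecture(c("Zn2C6", "C2H2", "MHD")), "Zn2C6-MHD")
  expect_equal(classify_architecture(c("Zn2C6", "C2H2")), "other")
  expect_equal(classify_architecture(character(0)), "other")
  # total over all multisets of size <= 3
  types <- c("Zn2C6", "C2H2", "MHD")
  combos <- unlist(lapply(0:3, function(k)
    if (k == 0) list(character(0)) else
      apply(expand.grid(rep(list(types), k)), 1, as.character, simplify = FALSE)),
    recursive = FALSE)
  labs <- vapply(combos, classify_architecture, character(1))
  expect_true(all(labs %in% c("Zn2C6-MHD", "C2H2-MHD", "MHD-only", "other")))
})
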