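test_that("an intronless exact gene aligns as one block with the local score", {
  set.seed(11)
  prot <- random_protein(80)
  cds <- dbdrescue:::.encode_protein(prot)
  g <- paste0("ACGTAC", cds, "TTAACC")
  sa <- spliced_align(prot, g)
  expect_equal(nrow(sa$blocks), 1L)
  expect_equal(nrow(sa$introns), 0L)
  expect_equal(sum(is.na(sa$gpos)), 0L)
  expect_equal(sa$blocks$gstart, 7L)
  expect_equal(sa$blocks$gend, 6L + nchar(cds))
  expect_equal(sa$score, local_align_protein(prot, prot)$score)
})

test_that("a planted GT-AG intron is recovered at its exact boundaries", {
  set.seed(12)
  for (i in 1:10) {
    prot <- random_protein(60)
    cds <- dbdrescue:::.encode_protein(prot)
    cut <- 3 * sample(15:45, 1)
    ilen <- sample(25:40, 1)
    intron <- paste0("GT", random_dna(ilen - 4), "AG")
    g <- paste0("AAAC", substr(cds, 1, cut), intron,
                substr(cds, cut + 1, nchar(cds)), "GGTT")
    sa <- spliced_align(prot, g)
    expect_equal(nrow(sa$introns), 1L)
    expect_equal(sa$introns$start, 4L + cut + 1L)
    expect_equal(sa$introns$end, 4L + cut + ilen)
    expect_equal(sa$introns$donor, "GT")
    expect_equal(sa$introns$acceptor, "AG")
    # genomic blocks stay codon-complete
    expect_true(all(sa$blocks$gend - sa$blocks$gstart + 1L ==
                      3L * (sa$blocks$qend - sa$blocks$qstart + 1L)))
  }
})

test_that("spliced score matches exhaustive single-intron enumeration on toys", {
  set.seed(13)
  params <- scoring_params()
  for (i in 1:12) {
    prot <- random_protein(sample(15:25, 1))
    cds <- dbdrescue:::.encode_protein(prot)
    has_intron <- i %% 2 == 0
    g <- if (has_intron) {
      cut <- 3 * sample(5:(nchar(prot) - 5), 1)
      paste0(random_dna(6), substr(cds, 1, cut),
             paste0("GT", random_dna(sample(18:26, 1)), "AG"),
             substr(cds, cut + 1, nchar(cds)), random_dna(6))
    } else {
      paste0(random_dna(6), cds, random_dna(6))
    }
    if (nchar(g) > 300) next
    expect_equal(spliced_align(prot, g, params)$score,
                 single_intron_oracle(prot, g, params), info = paste(i))
  }
})

test_that("degenerate inputs give an empty zero-score alignment", {
  sa <- spliced_align("WWWWWWWW", "AAAAAAAAAAAA")
  expect_equal(sa$score, 0)
  expect_equal(nrow(sa$blocks), 0L)
  expect_true(all(is.na(sa$gpos)))
})

test_that("a micro-exon chain never scores below the chain that skips it", {
  # 2-aa exon between two introns: hard to place, but the returned score
  # must at least match deleting those two residues
  set.seed(14)
  protA <- random_protein(30); micro <- "WD"; protB <- random_protein(30)
  prot <- paste0(protA, micro, protB)
  cdsA <- dbdrescue:::.encode_protein(protA)
  cdsM <- dbdrescue:::.encode_protein(micro)
  cdsB <- dbdrescue:::.encode_protein(protB)
  i1 <- paste0("GT", random_dna(24), "AG")
  i2 <- paste0("GT", random_dna(24), "AG")
  g <- paste0(random_dna(10), cdsA, i1, cdsM, i2, cdsB, random_dna(10))
  params <- scoring_params()
  sa <- spliced_align(prot, g, params)
  skip <- spliced_align(paste0(protA, protB), g, params)
  expect_gte(sa$score, skip$score - 2 * params$gap_residue)
})
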