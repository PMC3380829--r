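two_fams <- function() {
  dplyr::bind_rows(
    satellite_family("S1", monomer_length = 50, at_content = 0.72,
                     n_loci = 2, copies_per_locus = 30, divergence = 0.02,
                     fold_enrichment = 20),
    retroelement_family("R1", element_length = 1000, ltr_length = 100,
                        n_insertions = 3, at_content = 0.60,
                        fold_enrichment = 20))
}

test_that("genome length, annotations and proportions are conserved", {
  g <- build_genome(two_fams(), background_length = 5e4, seed = 7)
  ann_bp <- sum(g$annotations$end - g$annotations$start)
  expect_equal(g$genome_length, 5e4 + 2 * 30 * 50 + 3 * 1000)
  expect_equal(nchar(g$sequence), g$genome_length)
  expect_equal(ann_bp, 2 * 30 * 50 + 3 * 1000)
  p <- genome_proportions(g)
  expect_equal(sum(p$annotated_bp), ann_bp)
  # coordinates are 0-based half-open, in range, non-overlapping
  a <- dplyr::arrange(g$annotations, start)
  expect_true(all(a$start >= 0) && all(a$end <= g$genome_length))
  expect_true(all(a$start[-1] >= a$end[-nrow(a)]))
  expect_true(all(a$strand %in% c("+", "-")))
})

test_that("annotated blocks actually contain the family sequence", {
  g <- build_genome(two_fams(), background_length = 5e4, seed = 8)
  a <- g$annotations[g$annotations$family_id == "S1", ][1, ]
  block <- substr(g$sequence, a$start + 1, a$end)
  if (a$strand == "-") block <- censat:::str_revcomp(block)
  cons <- g$consensus[["S1"]]
  # a 2%-diverged tandem array: the first monomer matches the consensus
  # within a generous mismatch margin
  mono <- substr(block, 1, 50)
  mm <- sum(strsplit(mono, "")[[1]] != strsplit(cons, "")[[1]])
  expect_lt(mm / 50, 0.15)
})

test_that("satellite AT content of the consensus is exact within 0.02", {
  for (at in c(0.5, 0.65, 0.72, 0.8)) {
    fam <- satellite_family("X", monomer_length = 50, at_content = at,
                            copies_per_locus = 10)
    g <- build_genome(fam, background_length = 1e4, seed = 9)
    expect_equal(at_content(g$consensus[["X"]]), at, tolerance = 0.021)
  }
})

test_that("genome build is deterministic in the seed", {
  g1 <- build_genome(two_fams(), background_length = 2e4, seed = 10)
  g2 <- build_genome(two_fams(), background_length = 2e4, seed = 10)
  g3 <- build_genome(two_fams(), background_length = 2e4, seed = 11)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$annotations, g2$annotations)
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("background too small for gaps raises a capacity error", {
  fam <- satellite_family("X", monomer_length = 100, at_content = 0.6,
                          n_loci = 50, copies_per_locus = 10)
  expect_error(build_genome(fam, background_length = 1000, seed = 1),
               "background")
})

test_that("expected enrichment is fold over the mixture average", {
  g <- build_genome(two_fams(), background_length = 5e4, seed = 12)
  ee <- expected_enrichment(g)
  p <- genome_proportions(g)$proportion
  denom <- sum(p * 20) + (1 - sum(p))
  expect_equal(ee$expected_enrichment, rep(20 / denom, 2))
  # a fold-1 genome has expected enrichment exactly 1 everywhere
  fams1 <- dplyr::mutate(two_fams(), fold_enrichment = 1)
  ee1 <- expected_enrichment(build_genome(fams1, 5e4, seed = 13))
  expect_equal(ee1$expected_enrichment, c(1, 1))
})

test_that("reference reads have the right count, length and truth labels", {
  g <- build_genome(two_fams(), background_length = 5e4, seed = 14)
  refs <- simulate_reference_reads(g, coverage = 0.48, read_length = 100,
                                   seed = 15)
  expect_equal(nrow(refs), round(0.48 * g$genome_length / 100))
  expect_true(all(nchar(refs$sequence) == 100))
  expect_true(all(refs$start >= 0 &
                    refs$start + 100 <= g$genome_length))
  # a read fully inside an annotated block must carry that family label
  a <- g$annotations[1, ]
  inside <- refs$start >= a$start & refs$start + 100 <= a$end
  if (any(inside)) {
    expect_true(all(refs$truth_family[inside] == a$family_id))
  }
  # majority rule: background reads are labelled background
  expect_true("background" %in% refs$truth_family)
})

test_that("ChIP reads are enriched in annotated families, input is not", {
  g <- build_genome(two_fams(), background_length = 1e5, seed = 16)
  rs <- simulate_chip_and_input(g, n_chip = 2e4, n_input = 2e4, seed = 17)
  expect_equal(nrow(rs$chip), 2e4)
  expect_true(all(nchar(rs$chip$sequence) == 36))
  p_fam <- sum(genome_proportions(g)$proportion)
  frac_chip <- mean(rs$chip$truth_family != "background")
  frac_input <- mean(rs$input$truth_family != "background")
  expect_equal(frac_input, p_fam, tolerance = 0.25)
  expect_gt(frac_chip, 3 * frac_input)
  # empirical enrichment close to the analytic expectation
  ee <- expected_enrichment(g)
  for (f in ee$family_id) {
    emp <- mean(rs$chip$truth_family == f) /
      mean(rs$input$truth_family == f)
    expect_equal(emp, ee$expected_enrichment[ee$family_id == f],
                 tolerance = 0.25)
  }
})

test_that("quality strings are valid Phred+33 with the configured rate", {
  g <- build_genome(two_fams(), background_length = 5e4, seed = 18)
  rs <- simulate_chip_and_input(g, n_chip = 5000, n_input = 100, seed = 19)
  qv <- utf8ToInt(paste(rs$chip$quality, collapse = ""))
  expect_true(all(qv >= 33 + 2 & qv <= 33 + 60))
  low_rate <- mean(qv - 33 < 20)
  expect_equal(low_rate, 0.01, tolerance = 0.3)
})

test_that("seeds outside the 32-bit range are rejected", {
  expect_error(build_genome(two_fams(), 1e4, seed = 2^31), "seed")
})
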