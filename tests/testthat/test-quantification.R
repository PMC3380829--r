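test_that("genome proportion converts to Mbp with half-up rounding", {
  expect_equal(genome_proportion_to_mbp(0.01), 0.43)
  expect_equal(genome_proportion_to_mbp(0.012), 0.52)
  # 0.012 / 100 * 4300 = 0.516: must round half up, not to even
  expect_equal(genome_proportion_to_mbp(0.012, digits = NULL),
               0.012 / 100 * 4300)
  expect_equal(genome_proportion_to_mbp(0), 0)
  expect_equal(genome_proportion_to_mbp(100), 4300)
  expect_error(genome_proportion_to_mbp(101))
  expect_error(genome_proportion_to_mbp(-1))
})

test_that("Mbp conversion is linear in proportion and genome size", {
  p <- c(0.5, 1.5, 7)
  raw <- genome_proportion_to_mbp(p, digits = NULL)
  expect_equal(raw, p / 100 * 4300)
  expect_equal(genome_proportion_to_mbp(p, genome_size_mbp = 8600,
                                        digits = NULL), 2 * raw)
})

test_that("chromosome and centromere sizes compose", {
  expect_equal(chromosome_size_mbp(14.3), 614.9)
  expect_equal(centromere_segment_mbp(0.5, 600), 300)
  m <- tibble::tibble(chromosome_id = c("1", "2"),
                      relative_length = c(14.3, 13.1),
                      centromere_density_fraction = c(0.12, 0.15))
  res <- centromere_sizes(m)
  expect_equal(res$chromosome_mbp, c(614.9, 563.3))
  expect_equal(res$centromere_mbp, res$chromosome_mbp *
                 m$centromere_density_fraction)
  # centromere can never exceed its chromosome
  expect_true(all(res$centromere_mbp <= res$chromosome_mbp))
})

test_that("karyotype proportions conserve the genome size", {
  set.seed(5)
  r <- diff(c(0, sort(runif(6)), 1)) * 100
  expect_equal(sum(chromosome_size_mbp(r)), 4300)
})
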