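test_that("enrichment is the ratio of mapped-read proportions", {
  expect_equal(compute_enrichment(5, 100, 50, 1000), 1)
  expect_equal(compute_enrichment(20, 100, 10, 1000), 20)
  expect_equal(compute_enrichment(0, 100, 5, 1000), 0)
})

test_that("enrichment is invariant to rescaling both totals", {
  set.seed(21)
  c_cnt <- rpois(50, 40)
  i_cnt <- rpois(50, 40) + 1
  e1 <- compute_enrichment(c_cnt, 1e4, i_cnt, 2e4)
  # scaling both totals by the same factor leaves E unchanged
  expect_equal(compute_enrichment(c_cnt, 1e4 * 7, i_cnt, 2e4 * 7), e1)
  expect_equal(compute_enrichment(c_cnt, 2e4, i_cnt, 4e4), e1)
  # scaling only the chip total by s divides E by s
  expect_equal(compute_enrichment(c_cnt, 1e4 * 7, i_cnt, 2e4), e1 / 7)
})

test_that("zero input counts follow the chosen policy", {
  expect_equal(compute_enrichment(3, 100, 0, 1000), Inf)
  expect_true(is.na(compute_enrichment(0, 100, 0, 1000)))
  e <- compute_enrichment(3, 100, 0, 1000, zero_policy = "pseudocount")
  expect_equal(e, (4 / 100) / (1 / 1000))
  expect_error(compute_enrichment(1, 0, 1, 10), "positive")
})

test_that("selection threshold is inclusive and Inf is always selected", {
  rec <- tibble::tibble(unit_id = c("a", "b", "c", "d"),
                        enrichment = c(10, 9.99, Inf, NA))
  sel <- select_enriched_reads(rec, threshold = 10)
  expect_equal(sel$unit_id, c("a", "c"))
  s <- attr(sel, "selection_summary")
  expect_equal(s$n_selected, 2)
  expect_equal(s$n_total, 4)
  expect_equal(s$percent, 50)
})

test_that("selection percentage is rounded half-up to two decimals", {
  rec <- tibble::tibble(enrichment = c(rep(100, 173), rep(0, 9827)))
  s <- attr(select_enriched_reads(rec), "selection_summary")
  expect_equal(s$percent, 1.73)
  # half-up at the boundary: 1/800 = 0.125% -> 0.13, not banker's 0.12
  rec2 <- tibble::tibble(enrichment = c(100, rep(0, 799)))
  expect_equal(attr(select_enriched_reads(rec2),
                    "selection_summary")$percent, 0.13)
})

test_that("enrichment summary bins zeros, Inf and depleted units", {
  rec <- tibble::tibble(enrichment = c(0, 0.5, 0.99, 1, 2, 12, Inf, NA))
  s <- enrichment_summary(rec)
  expect_equal(s$n_units, 7)
  expect_equal(sum(s$histogram$n), 7)
  expect_equal(s$histogram$n[1], 1)                     # the zero
  expect_equal(s$histogram$n[nrow(s$histogram)], 1)     # the Inf
  expect_equal(s$frac_depleted, 3 / 7)
  expect_s3_class(ggplot2::autoplot(s), "ggplot")
})

test_that("every unit lands in exactly one histogram bin", {
  set.seed(33)
  rec <- tibble::tibble(enrichment = c(10^runif(500, -4, 5), 0, Inf))
  s <- enrichment_summary(rec)
  expect_equal(sum(s$histogram$n), 502)
})
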