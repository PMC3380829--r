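set.seed(404)
mapper_refs <- vapply(1:25, function(i) random_dna_str(100), "")
names(mapper_refs) <- sprintf("ref%02d", 1:25)

test_that("matcher agrees with the brute-force DP oracle", {
  idx <- reference_index(mapper_refs)
  set.seed(405)
  for (t in 1:120) {
    q <- make_query(mapper_refs)
    hits <- match_reads(c(q1 = q), idx)
    got <- sort(match(unique(hits$reference_id), names(mapper_refs)))
    want <- sort(unname(oracle_match_set(q, mapper_refs)))
    expect_identical(got, want)
  }
})

test_that("matching is strand-symmetric", {
  idx <- reference_index(mapper_refs)
  set.seed(406)
  for (t in 1:25) {
    q <- make_query(mapper_refs)
    h1 <- match_reads(c(q = q), idx)
    h2 <- match_reads(c(q = oracle_revcomp(q)), idx)
    expect_setequal(h1$reference_id, h2$reference_id)
    if (nrow(h1)) {
      # per-reference best difference counts agree
      b1 <- tapply(h1$n_differences, h1$reference_id, min)
      b2 <- tapply(h2$n_differences, h2$reference_id, min)
      expect_equal(b1[sort(names(b1))], b2[sort(names(b2))])
    }
  }
})

test_that("hit sets grow monotonically with the difference budget", {
  idx <- reference_index(mapper_refs)
  set.seed(407)
  for (t in 1:25) {
    q <- make_query(mapper_refs)
    h0 <- match_reads(c(q = q), idx, match_params(max_differences = 0))
    h1 <- match_reads(c(q = q), idx, match_params(max_differences = 1))
    h2 <- match_reads(c(q = q), idx, match_params(max_differences = 2))
    expect_true(all(h0$reference_id %in% h1$reference_id))
    expect_true(all(h1$reference_id %in% h2$reference_id))
  }
})

test_that("exact substrings always match with zero differences", {
  idx <- reference_index(mapper_refs)
  set.seed(408)
  for (t in 1:20) {
    ri <- sample(length(mapper_refs), 1)
    st <- sample(70, 1)
    q <- substr(mapper_refs[[ri]], st, st + 30)
    hits <- match_reads(c(q = q), idx)
    mine <- hits[hits$reference_id == names(mapper_refs)[ri], ]
    expect_gte(nrow(mine), 1)
    expect_equal(min(mine$n_differences), 0L)
    expect_true(any(mine$reference_offset == st - 1L &
                      mine$strand == "+"))
  }
})

test_that("N bases never match", {
  r <- c(ref = strrep("ACGTT", 20))
  idx <- reference_index(r)
  q <- substr(r[[1]], 1, 31)
  exact <- match_reads(c(q = q), idx)
  expect_equal(min(exact$n_differences), 0L)
  qn <- paste0("NNN", substr(q, 4, 31))
  hn <- match_reads(c(q = qn), idx)
  if (nrow(hn)) expect_gte(min(hn$n_differences), 3L - 2L)
  # an all-N query matches nothing
  expect_equal(nrow(match_reads(c(q = strrep("N", 31)), idx)), 0)
})

test_that("indel budget is enforced", {
  r <- c(ref = strrep("ACGGTTACAG", 10))
  idx <- reference_index(r)
  base <- substr(r[[1]], 11, 41)
  # delete 5 consecutive bases from the query: needs a 5-base insertion
  q5 <- paste0(substr(base, 1, 10), substr(base, 16, 31))
  # the 26-nt query is below the completeness bound, which warns
  hits <- suppressWarnings(match_reads(c(q = q5), idx))
  expect_true(all(hits$indel_bases <= 4))
  p <- match_params(max_total_indel_bases = 0)
  h0 <- suppressWarnings(match_reads(c(q = q5), idx, p))
  if (nrow(h0)) expect_true(all(h0$indel_bases == 0))
})

test_that("query length contracts are enforced", {
  idx <- reference_index(mapper_refs)
  expect_error(match_reads(c(q = "ACGTACGTACG"), idx), "12")
  expect_warning(match_reads(c(q = strrep("ACGTC", 4)), idx),
                 "complete")
  expect_error(match_reads(c(q = strrep("A", 70)), idx), "63")
  expect_error(match_params(max_differences = 3), "2")
})

test_that("count_reference_hits accounts for mapped and unmapped reads", {
  fx <- medium_fixture()
  idx <- reference_index(fx$reference[1:2000, ])
  chip <- qc_reads(fx$chip[1:3000, ])
  input <- qc_reads(fx$input[1:3000, ])
  counts <- count_reference_hits(chip, input, idx)
  expect_equal(nrow(counts), 2000)
  ms <- attr(counts, "mapping_summary")
  expect_equal(ms$n_reads, c(nrow(chip), nrow(input)))
  expect_true(all(ms$n_mapped <= ms$n_reads))
  expect_true(all(counts$chip_count >= 0 & counts$input_count >= 0))
})

test_that("fractional counting conserves each read's unit weight", {
  fx <- medium_fixture()
  idx <- reference_index(fx$reference[1:1500, ])
  chip <- qc_reads(fx$chip[1:1500, ])
  input <- qc_reads(fx$input[1:1500, ])
  frac <- count_reference_hits(chip, input, idx, policy = "fractional")
  ms <- attr(frac, "mapping_summary")
  expect_equal(sum(frac$chip_count), ms$n_mapped[1], tolerance = 1e-8)
  expect_equal(sum(frac$input_count), ms$n_mapped[2], tolerance = 1e-8)
})
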