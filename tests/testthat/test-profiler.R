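make_tandem <- function(monomer, n_copies, divergence = 0, seed = 61) {
  censat:::with_seed(seed,
    censat:::mutate_dna(strrep(monomer, n_copies), divergence))
}

test_that("monomer length is recovered exactly for clean tandem arrays", {
  set.seed(62)
  for (m in c(5, 17, 50, 120, 367)) {
    mono <- random_dna_str(m)
    est <- estimate_monomer_length(strrep(mono, max(3, ceiling(900 / m))))
    expect_equal(est$monomer_length, m)
    expect_equal(est$identity, 1)
    expect_true(est$periodic)
  }
})

test_that("shift identity matches the brute-force oracle", {
  set.seed(63)
  seqs <- c(strrep(random_dna_str(20), 10),
            make_tandem(random_dna_str(33), 8, divergence = 0.05),
            random_dna_str(150))
  for (s in seqs) {
    smax <- nchar(s) %/% 2
    got <- censat:::cpp_shift_identity(s, as.integer(smax))
    want <- vapply(seq_len(smax), function(k) oracle_shift_identity(s, k),
                   0)
    expect_equal(got, want)
  }
})

test_that("the smallest near-best period is reported, not a multiple", {
  mono <- random_dna_str(40)
  est <- estimate_monomer_length(strrep(mono, 20))
  expect_equal(est$monomer_length, 40)  # not 80 or 120
})

test_that("diverged arrays are periodic, random sequence is not", {
  set.seed(64)
  arr <- make_tandem(random_dna_str(100), 8, divergence = 0.05)
  est <- estimate_monomer_length(arr)
  expect_true(est$periodic)
  expect_equal(est$monomer_length, 100)
  rnd <- random_dna_str(800)
  expect_false(estimate_monomer_length(rnd)$periodic)
})

test_that("tandem organization is verified on arrays, rejected elsewhere", {
  set.seed(65)
  mono <- random_dna_str(60)
  arr <- make_tandem(mono, 10, divergence = 0.05)
  ok <- verify_tandem_organization(arr, mono)
  expect_true(as.logical(ok))
  expect_gte(attr(ok, "n_copies"), 8)
  # two distant copies are not a tandem array
  spaced <- paste0(mono, random_dna_str(500), mono)
  expect_false(as.logical(verify_tandem_organization(spaced, mono)))
  # minus-strand arrays verify too
  expect_true(as.logical(
    verify_tandem_organization(censat:::str_revcomp(arr), mono)))
})

test_that("assembly reconstructs a tandem consensus from short reads", {
  set.seed(66)
  mono <- random_dna_str(80)
  reads <- tandem_reads(mono, 60, divergence = 0.01, seed = 67)
  asm <- assemble_representative(reads)
  expect_gt(nchar(asm$contig), 200)
  expect_false(asm$low_confidence)
  est <- estimate_monomer_length(asm$contig)
  expect_equal(est$monomer_length, 80)
  # the contig is made of the monomer: high identity to a monomer dimer
  pid <- pairwise_identity(substr(asm$contig, 1, 160), strrep(mono, 3))
  expect_gt(pid, 0.95)
})

test_that("classification puts retroelements ahead of pseudo-periodicity", {
  set.seed(68)
  ltr <- random_dna_str(150)
  internal <- random_dna_str(1200)
  element <- paste0(ltr, internal, ltr)
  mono <- estimate_monomer_length(element)
  tand <- if (mono$periodic) {
    verify_tandem_organization(element,
                               substr(element, 1, mono$monomer_length))
  } else {
    structure(FALSE, n_copies = 0L)
  }
  cls <- classify_cluster(element, mono, tand, retro_library = element)
  expect_equal(cls$classification, "ltr_retroelement")
  # without a library the same contig must not be called a satellite
  cls2 <- classify_cluster(element, mono, tand, retro_library = NULL)
  expect_true(cls2$classification %in% c("unclassified"))
  # a genuine satellite stays a satellite
  arr <- strrep(random_dna_str(50), 12)
  m2 <- estimate_monomer_length(arr)
  t2 <- verify_tandem_organization(arr, substr(arr, 1, m2$monomer_length))
  expect_equal(classify_cluster(arr, m2, t2, NULL)$classification,
               "satellite")
})

test_that("AT content is exact and vectorized", {
  expect_equal(at_content("AATT"), 1)
  expect_equal(at_content("GGCC"), 0)
  expect_equal(at_content(c("ACGT", "AAAC")), c(0.5, 0.75))
  expect_true(is.na(at_content("NNN")))
})

test_that("pairwise identity reproduces the worked example", {
  expect_equal(as.numeric(pairwise_identity("ACGT", "ACGA")), 75)
  expect_equal(as.numeric(pairwise_identity("ACGT", "ACGT")), 100)
  # symmetric in its arguments
  a <- random_dna_str(80)
  b <- censat:::mutate_dna(a, 0.1)
  expect_equal(as.numeric(pairwise_identity(a, b)),
               as.numeric(pairwise_identity(b, a)))
})

test_that("dot plots are symmetric and detect periodicity", {
  set.seed(69)
  mono <- random_dna_str(60)
  arr <- strrep(mono, 5)
  dp <- dotplot(c(x = arr), window = 30, min_identity = 0.9)
  # self-comparison symmetry: (i, j) present iff (j, i) present
  fwd <- dp[dp$strand == "+", ]
  expect_setequal(paste(fwd$pos_a, fwd$pos_b), paste(fwd$pos_b, fwd$pos_a))
  # off-diagonal bands at multiples of the monomer length
  off <- fwd[fwd$pos_a != fwd$pos_b, ]
  expect_true(all((abs(off$pos_a - off$pos_b)) %% 60 == 0))
  # unrelated sequences produce no matches
  dp2 <- dotplot(c(a = random_dna_str(300), b = random_dna_str(300)),
                 window = 30)
  cross <- dp2[dp2$seq_a != dp2$seq_b, ]
  expect_equal(nrow(cross), 0)
})
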