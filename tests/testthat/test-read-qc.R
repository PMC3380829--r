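q40 <- function(n) strrep(intToUtf8(40 + 33), n)

make_reads <- function(seqs, quals = NULL) {
  out <- tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs)),
                        sequence = seqs)
  if (!is.null(quals)) out$quality <- quals
  out
}

test_that("default trimming yields exactly target_length (36 -> 31)", {
  reads <- make_reads(strrep("ACGT", 9), q40(36))  # 36 nt
  out <- trim_reads(reads)
  expect_equal(nchar(out$sequence), 31)
  expect_equal(nchar(out$quality), 31)
  # 5 excess bases: 3 off the 5' end, 2 off the 3' end
  expect_equal(out$sequence, substr(strrep("ACGT", 9), 4, 34))
})

test_that("trimming splits the excess 5'-heavy for odd excess", {
  s35 <- strrep("AC", 18) |> substr(1, 35)
  out <- trim_reads(make_reads(s35, q40(35)))
  expect_equal(out$sequence, substr(s35, 3, 33))  # 2 + 2 split
})

test_that("reads shorter than target are dropped and counted", {
  reads <- make_reads(c(strrep("A", 36), strrep("C", 20)),
                      c(q40(36), q40(20)))
  out <- trim_reads(reads)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "n_dropped_short"), 1)
})

test_that("explicit trim amounts override the default split", {
  p <- qc_params(trim_5p = 5, trim_3p = 0)
  s <- strrep("ACGT", 9)
  out <- trim_reads(make_reads(s, q40(36)), p)
  expect_equal(out$sequence, substr(s, 6, 36))
  expect_error(qc_params(trim_5p = 5), "trim_3p")
})

test_that("quality filter removes >1 base below Q20, keeps exactly 1", {
  qual <- function(bad) {
    v <- rep(40L, 31)
    v[seq_len(bad)] <- 19L
    intToUtf8(v + 33L)
  }
  reads <- make_reads(rep(strrep("A", 31), 3),
                      c(qual(0), qual(1), qual(2)))
  keep <- quality_filter(reads)
  expect_equal(keep, c(TRUE, TRUE, FALSE))
  # Q20 itself is not "below Q20"
  reads20 <- make_reads(strrep("A", 31), intToUtf8(rep(20L + 33L, 31)))
  expect_true(quality_filter(reads20))
})

test_that("quality filter requires qualities", {
  expect_error(quality_filter(make_reads(strrep("A", 31))), "quality")
})

test_that("qc_reads accounts for every input read", {
  set.seed(101)
  n <- 200
  seqs <- vapply(seq_len(n), function(i) random_dna_str(36), "")
  quals <- vapply(seq_len(n), function(i) {
    v <- sample(15:45, 36, TRUE)
    intToUtf8(v + 33L)
  }, "")
  # a few too-short reads
  seqs[1:5] <- substr(seqs[1:5], 1, 25)
  out <- qc_reads(make_reads(seqs, quals))
  s <- qc_summary(out)
  expect_equal(s$n_input, n)
  expect_equal(s$n_kept, nrow(out))
  expect_equal(s$n_input, s$n_kept + s$dropped_short + s$dropped_quality)
  expect_true(all(nchar(out$sequence) == 31))
  # filtering happens on the trimmed read: no survivor has >1 low base
  low <- vapply(out$quality, function(x) sum(utf8ToInt(x) - 33L < 20), 0L)
  expect_true(all(low <= 1))
})

test_that("qc is idempotent on already-clean reads", {
  reads <- make_reads(rep(strrep("ACGTACG", 5) |> substr(1, 31), 4),
                      rep(q40(31), 4))
  once <- qc_reads(reads)
  twice <- qc_reads(once)
  expect_equal(twice$sequence, once$sequence)
  expect_equal(qc_summary(twice)$n_kept, nrow(once))
})

test_that("qc_reads reads FASTQ files and reports malformed line numbers", {
  path <- withr::local_tempfile(fileext = ".fastq")
  reads <- make_reads(c(strrep("A", 36), strrep("C", 36)),
                      c(q40(36), q40(36)))
  write_fastq(reads, path)
  out <- qc_reads(path)
  expect_equal(nrow(out), 2)
  expect_equal(nchar(out$sequence), c(31, 31))

  bad <- withr::local_tempfile(fileext = ".fastq")
  lines <- readLines(path)
  lines[6] <- "not-a-sequence line with spaces"
  writeLines(lines, bad)
  expect_error(read_fastq(bad), "line")
})
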