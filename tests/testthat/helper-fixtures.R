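# Lazily built, cached fixtures shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, fn(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Medium three-family fixture (one short-monomer satellite, one
# medium-monomer satellite, one LTR retroelement), expected enrichment ~14.5.
medium_fixture <- function() {
  cached_fixture("medium", function() {
    fams <- dplyr::bind_rows(
      satellite_family("SAT-A", monomer_length = 50, at_content = 0.72,
                       n_loci = 2, copies_per_locus = 80, divergence = 0.02,
                       fold_enrichment = 50),
      satellite_family("SAT-B", monomer_length = 150, at_content = 0.68,
                       n_loci = 2, copies_per_locus = 27, divergence = 0.02,
                       fold_enrichment = 50),
      # a short element at high insertion count keeps the reference reads
      # dense along the element (same phase-coverage argument as the
      # pea-like fixture's satellites)
      retroelement_family("RTE-1", element_length = 400, ltr_length = 50,
                          n_insertions = 55, at_content = 0.60,
                          divergence = 0.02, fold_enrichment = 50))
    genome <- build_genome(fams, background_length = 6e5, seed = 301)
    reference <- simulate_reference_reads(genome, coverage = 0.48,
                                          read_length = 100, seed = 302)
    reads <- simulate_chip_and_input(genome, n_chip = 3e4, n_input = 3e4,
                                     seed = 303)
    list(genome = genome, reference = reference, chip = reads$chip,
         input = reads$input, expected = expected_enrichment(genome),
         retro_library = genome$consensus["RTE-1"])
  })
}

# Null fixture: same genome, no enrichment anywhere.
null_fixture <- function() {
  cached_fixture("null", function() {
    fams <- dplyr::bind_rows(
      satellite_family("SAT-A", monomer_length = 50, at_content = 0.72,
                       n_loci = 2, copies_per_locus = 80, divergence = 0.02,
                       fold_enrichment = 1),
      satellite_family("SAT-B", monomer_length = 150, at_content = 0.68,
                       n_loci = 2, copies_per_locus = 27, divergence = 0.02,
                       fold_enrichment = 1))
    genome <- build_genome(fams, background_length = 6e5, seed = 311)
    reference <- simulate_reference_reads(genome, coverage = 0.48,
                                          read_length = 100, seed = 312)
    reads <- simulate_chip_and_input(genome, n_chip = 2e4, n_input = 2e4,
                                     seed = 313)
    list(genome = genome, reference = reference, chip = reads$chip,
         input = reads$input)
  })
}

# The full pea-like fixture used by the acceptance test (built once).
acceptance_fixture <- function() {
  cached_fixture("acceptance", function() pea_like_fixture(seed = 42))
}

# Reads sampled from a mutated tandem array of `monomer`, random strands.
tandem_reads <- function(monomer, n, read_len = 100, divergence = 0.02,
                         seed = 1) {
  censat:::with_seed(seed, {
    arr <- strrep(monomer, ceiling((read_len + n * 10) / nchar(monomer)) + 2)
    starts <- sort(sample(nchar(arr) - read_len, n))
    reads <- substring(arr, starts, starts + read_len - 1)
    reads <- vapply(reads, censat:::mutate_dna, "", divergence,
                    USE.NAMES = FALSE)
    rc <- runif(n) < 0.5
    reads[rc] <- censat:::str_revcomp(reads[rc])
    stats::setNames(reads, sprintf("t%03d", seq_len(n)))
  })
}
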