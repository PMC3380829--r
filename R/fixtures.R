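#' Preset family table emulating the pea centromeric repeat landscape
#'
#' Thirteen enriched satellite families spanning the monomer-size range
#' observed in legume centromeric satellites (50 to roughly 2100 bp), with
#' AT contents between 0.67 and 0.77, 3% sequence divergence and 50-fold
#' ChIP enrichment, plus one dispersed LTR retroelement at the same
#' enrichment.
#'
#' Copy numbers balance two opposing requirements of the scaled-down
#' design.  (1) Phase density: at 0.48x coverage with 100-nt reads, read
#' starts land at rate 0.0048 per bp of family sequence, and two
#' same-family reads join one cluster only when their monomer phases differ
#' by at most 45 bp (55% minimum overlap); a family must tile its phase
#' space without large holes or it fragments.  (2) Selection margin:
#' per-read enrichment integrates ChIP/input hits over a 70-bp phase
#' window, so the enrichment field along the phase circle is autocorrelated
#' with roughly 70-bp correlation length, and when the expected enrichment
#' sits close to the threshold, sampling dips drop *contiguous* 50-90 bp
#' blocks of reference reads -- holes that no raw density can prevent.
#' Because the expected enrichment falls as total annotated bp grows
#' (E = 50 / (1 + 49 p_annotated) here), more copies buy density but
#' spend margin.  The compromise below (about 36 copies for the largest
#' monomers, 32 for mid-size ones, and an absolute floor of roughly 10 kb
#' of annotated sequence for the smallest) gives an expected enrichment
#' near 16 -- about 1.6 standard deviations of the per-read estimate above
#' the threshold of 10 -- while keeping the mean phase gap near 6 bp.  In
#' the real survey-scale experiment family abundances are megabases, which
#' makes both constraints non-binding.
#'
#' @param include_depleted Also include six non-enriched satellite families
#'   (fold enrichment 0.3--1.1) to exercise the selection step.
#' @return A family tibble accepted by [build_genome()].
#' @examples
#' pea_like_families()
#' @export
pea_like_families <- function(include_depleted = FALSE) {
  sat <- function(id, m, at, loci, copies) {
    satellite_family(id, monomer_length = m, at_content = at, n_loci = loci,
                     copies_per_locus = copies, divergence = 0.03,
                     fold_enrichment = 50)
  }
  fams <- dplyr::bind_rows(
    sat("SAT-01", 50, 0.72, 4, 50),
    sat("SAT-02", 867, 0.67, 2, 16),
    sat("SAT-03", 245, 0.76, 2, 21),
    sat("SAT-04", 164, 0.73, 2, 31),
    sat("SAT-05", 659, 0.74, 2, 16),
    sat("SAT-06", 510, 0.76, 2, 16),
    sat("SAT-07", 120, 0.69, 2, 42),
    sat("SAT-08", 1644, 0.74, 2, 18),
    sat("SAT-09", 2094, 0.77, 2, 18),
    sat("SAT-10", 867, 0.76, 2, 16),
    sat("SAT-11", 642, 0.73, 2, 16),
    sat("SAT-12", 881, 0.76, 2, 16),
    sat("SAT-13", 1813, 0.69, 2, 18),
    retroelement_family("RTE-01", element_length = 1000, ltr_length = 100,
                        n_insertions = 55, at_content = 0.62,
                        divergence = 0.03, fold_enrichment = 50)
  )
  if (include_depleted) {
    dep <- function(id, m, at, fold) {
      satellite_family(id, monomer_length = m, at_content = at, n_loci = 2,
                       copies_per_locus = max(10, round(20000 / m)),
                       divergence = 0.03, fold_enrichment = fold)
    }
    fams <- dplyr::bind_rows(
      fams,
      dep("DEP-01", 440, 0.68, 0.6),
      dep("DEP-02", 82, 0.79, 0.3),
      dep("DEP-03", 172, 0.67, 0.6),
      dep("DEP-04", 54, 0.65, 1.1),
      dep("DEP-05", 189, 0.79, 0.4),
      dep("DEP-06", 191, 0.74, 0.5)
    )
  }
  fams
}

#' Full pea-like simulation fixture
#'
#' Builds the [pea_like_families()] genome (about 10 Mbp with a 9.56 Mb
#' AT-rich background; expected family enrichment about 16), simulates
#' low-coverage reference reads (0.48x,
#' 100 nt) and ChIP/input read sets (36 nt), mirroring a survey-sequencing
#' plus ChIP-seq experiment scaled to desk size.
#'
#' @param seed Seed controlling the whole fixture.
#' @param n_chip,n_input ChIP and input read counts.
#' @param include_depleted Passed to [pea_like_families()].
#' @return List with `genome`, `reference` (read tibble), `chip`, `input`,
#'   and `expected` (per-family expected enrichment from
#'   [expected_enrichment()]).
#' @examples
#' \donttest{
#' fx <- pea_like_fixture(seed = 42, n_chip = 1000, n_input = 1000)
#' fx$genome
#' }
#' @export
pea_like_fixture <- function(seed = 1, n_chip = 1e5, n_input = 1e5,
                             include_depleted = FALSE) {
  genome <- build_genome(pea_like_families(include_depleted),
                         background_length = 9.56e6, seed = seed,
                         background_at = 0.62, min_gap = 100)
  reference <- simulate_reference_reads(genome, coverage = 0.48,
                                        read_length = 100, seed = seed + 1)
  reads <- simulate_chip_and_input(genome, n_chip = n_chip,
                                   n_input = n_input, read_length = 36,
                                   seed = seed + 2)
  list(genome = genome, reference = reference,
       chip = reads$chip, input = reads$input,
       expected = expected_enrichment(genome))
}

#' Small graded-enrichment fixture for estimator validation
#'
#' A compact genome (about 2 Mbp) carrying four satellite families of equal
#' genomic abundance (about 15 kb each) at fold enrichments 1, 5, 20 and 50.
#' Useful for checking that estimated enrichment tracks the simulated fold
#' across replicates.
#'
#' @param seed Fixture seed.
#' @param n_chip,n_input Read counts per set.
#' @return Same shape as [pea_like_fixture()].
#' @examples
#' \donttest{
#' fx <- graded_enrichment_fixture(seed = 7)
#' fx$expected
#' }
#' @export
graded_enrichment_fixture <- function(seed = 1, n_chip = 3e4,
                                      n_input = 3e4) {
  folds <- c(1, 5, 20, 50)
  fams <- dplyr::bind_rows(purrr::map(seq_along(folds), function(i) {
    satellite_family(sprintf("GRD-%02d", i), monomer_length = 150,
                     at_content = 0.70, n_loci = 2, copies_per_locus = 50,
                     divergence = 0.02, fold_enrichment = folds[i])
  }))
  genome <- build_genome(fams, background_length = 1.94e6, seed = seed,
                         background_at = 0.60, min_gap = 100)
  reference <- simulate_reference_reads(genome, coverage = 0.48,
                                        read_length = 100, seed = seed + 1)
  reads <- simulate_chip_and_input(genome, n_chip = n_chip,
                                   n_input = n_input, read_length = 36,
                                   seed = seed + 2)
  list(genome = genome, reference = reference,
       chip = reads$chip, input = reads$input,
       expected = expected_enrichment(genome))
}
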