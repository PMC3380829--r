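#' Convert a genome proportion to megabase pairs
#'
#' `mbp = p / 100 * G`, reported with half-up rounding to `digits` decimals
#' (`digits = NULL` returns the raw value).
#'
#' @param p Genome proportion in percent (0--100).
#' @param genome_size_mbp Genome size `G` in Mbp (pea default 4300).
#' @param digits Decimals for half-up rounding, or `NULL` for the raw value.
#' @return Mbp value(s).
#' @examples
#' genome_proportion_to_mbp(0.01)    # 0.43
#' genome_proportion_to_mbp(0.012)   # 0.52
#' @export
genome_proportion_to_mbp <- function(p, genome_size_mbp = 4300, digits = 2) {
  stopifnot(all(p >= 0), all(p <= 100), genome_size_mbp > 0)
  x <- p / 100 * genome_size_mbp
  if (is.null(digits)) x else round_half_up(x, digits)
}

#' Chromosome size from its relative karyotype length
#'
#' `size = G * r / 100`.
#'
#' @param r Relative chromosome length in percent of the karyotype.
#' @inheritParams genome_proportion_to_mbp
#' @return Chromosome size(s) in Mbp.
#' @examples
#' chromosome_size_mbp(14.3)  # 614.9
#' @export
chromosome_size_mbp <- function(r, genome_size_mbp = 4300) {
  stopifnot(all(r > 0), all(r <= 100), genome_size_mbp > 0)
  genome_size_mbp * r / 100
}

#' Centromere-segment size from an integrated-density fraction
#'
#' `segment = d * chromosome_mbp`, where `d` is the fraction of integrated
#' fluorescence density within the segment delimited by the outermost
#' CenH3-containing regions.
#'
#' @param d Density fraction in `(0, 1]`.
#' @param chromosome_mbp Chromosome size in Mbp.
#' @return Segment size(s) in Mbp.
#' @examples
#' centromere_segment_mbp(0.5, 600)  # 300
#' @export
centromere_segment_mbp <- function(d, chromosome_mbp) {
  stopifnot(all(d > 0), all(d <= 1), all(chromosome_mbp > 0))
  d * chromosome_mbp
}

#' Chromosome and centromere sizes from a measurements table
#'
#' Applies [chromosome_size_mbp()] and [centromere_segment_mbp()] row-wise.
#'
#' @param measurements Tibble with `chromosome_id`, `relative_length`
#'   (percent of karyotype) and `centromere_density_fraction`.
#' @inheritParams genome_proportion_to_mbp
#' @return The input tibble with `chromosome_mbp` and `centromere_mbp`
#'   columns added.
#' @examples
#' m <- tibble::tibble(chromosome_id = c("1", "2"),
#'                     relative_length = c(14.3, 13.1),
#'                     centromere_density_fraction = c(0.12, 0.15))
#' centromere_sizes(m)
#' @export
centromere_sizes <- function(measurements, genome_size_mbp = 4300) {
  stopifnot(is.data.frame(measurements),
            all(c("chromosome_id", "relative_length",
                  "centromere_density_fraction") %in% names(measurements)))
  measurements |>
    tibble::as_tibble() |>
    dplyr::mutate(
      chromosome_mbp = chromosome_size_mbp(.data$relative_length,
                                           genome_size_mbp),
      centromere_mbp = centromere_segment_mbp(
        .data$centromere_density_fraction, .data$chromosome_mbp)
    )
}
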