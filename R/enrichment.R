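#' Compute ChIP enrichment
#'
#' Enrichment is the ratio of the ChIP read proportion to the input read
#' proportion mapped to a unit (cluster or reference read):
#' `E = (c / C) / (i / I)`.
#'
#' Zero-input handling (`i = 0` with `c > 0`) follows `zero_policy`:
#' `"infinite"` (default) returns `Inf`, which is always selected at any
#' finite threshold and is reported distinctly; `"pseudocount"` adds
#' `pseudocount` to both counts.  `c = 0, i = 0` yields `NA`.
#'
#' @param chip_count,input_count Unit-level counts (vectors allowed).
#' @param chip_total,input_total Post-QC totals of the two read sets
#'   (must be positive).
#' @param zero_policy `"infinite"` or `"pseudocount"`.
#' @param pseudocount Pseudocount added under the `"pseudocount"` policy.
#' @return Numeric vector of enrichment values.
#' @examples
#' compute_enrichment(5, 100, 50, 1000)        # proportions equal -> 1
#' compute_enrichment(0, 100, 5, 1000)         # no ChIP reads -> 0
#' compute_enrichment(3, 100, 0, 1000)         # zero input -> Inf
#' @export
compute_enrichment <- function(chip_count, chip_total, input_count,
                               input_total,
                               zero_policy = c("infinite", "pseudocount"),
                               pseudocount = 1) {
  zero_policy <- match.arg(zero_policy)
  if (chip_total <= 0 || input_total <= 0) {
    stop("chip_total and input_total must be positive", call. = FALSE)
  }
  if (zero_policy == "pseudocount") {
    zero <- input_count == 0
    chip_count <- ifelse(zero, chip_count + pseudocount, chip_count)
    input_count <- ifelse(zero, input_count + pseudocount, input_count)
  }
  e <- (chip_count / chip_total) / (input_count / input_total)
  # 0/0 under the infinite policy: no information at all
  e[chip_count == 0 & input_count == 0] <- NA_real_
  e
}

#' Select units with at-least-threshold enrichment
#'
#' The threshold is inclusive ("at least 10-fold"); `Inf` enrichment is
#' always selected.
#'
#' @param records Tibble with an `enrichment` column (e.g. per reference
#'   read).
#' @param threshold Minimum enrichment (default 10).
#' @return The selected rows, with attribute `"selection_summary"`: tibble
#'   `n_selected`, `n_total`, `percent` (rounded to 2 decimals).
#' @examples
#' rec <- tibble::tibble(unit_id = c("a", "b", "c"),
#'                       enrichment = c(10, 9.99, Inf))
#' sel <- select_enriched_reads(rec)
#' attr(sel, "selection_summary")
#' @export
select_enriched_reads <- function(records, threshold = 10) {
  stopifnot(is.data.frame(records), "enrichment" %in% names(records))
  keep <- !is.na(records$enrichment) & records$enrichment >= threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "selection_summary") <- tibble::tibble(
    n_selected = sum(keep),
    n_total = nrow(records),
    percent = round_half_up(100 * sum(keep) / nrow(records), 2)
  )
  out
}

#' Summarize an enrichment distribution
#'
#' Tabulates a histogram of enrichment values over log-spaced bins with exact
#' edges at `E = 1` and `E = 10` (zero and infinite values get their own
#' bins) plus the (chip, input) count scatter, and reports the fraction of
#' ChIP-depleted units (`E < 1`).
#'
#' @param records Tibble with `enrichment` and (optionally) `chip_count`,
#'   `input_count` columns.
#' @return A `censat_enrichment_summary`: list with `histogram` (tibble
#'   `bin_low`, `bin_high`, `n`), `scatter` (tibble of counts, if present),
#'   `frac_depleted`, `n_units`.  Has an [ggplot2::autoplot()] method.
#' @examples
#' rec <- tibble::tibble(enrichment = c(0, 0.5, 1, 2, 12, Inf))
#' enrichment_summary(rec)$frac_depleted
#' @export
enrichment_summary <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0,
            "enrichment" %in% names(records))
  e <- records$enrichment[!is.na(records$enrichment)]
  breaks <- c(0, 10^seq(-3, 4, by = 0.25), Inf)
  nbin <- length(breaks) - 1
  idx <- pmin(findInterval(e, breaks), nbin)  # zeros -> bin 1, Inf -> last
  hist_tbl <- tibble::tibble(bin_low = breaks[-length(breaks)],
                             bin_high = breaks[-1],
                             n = tabulate(idx, nbins = nbin))
  scatter <- if (all(c("chip_count", "input_count") %in% names(records))) {
    dplyr::select(records, dplyr::any_of(c("unit_id", "reference_id",
                                           "cluster_id")),
                  "chip_count", "input_count", "enrichment")
  }
  structure(list(histogram = hist_tbl,
                 scatter = scatter,
                 frac_depleted = mean(e < 1),
                 n_units = length(e)),
            class = "censat_enrichment_summary")
}

#' @export
print.censat_enrichment_summary <- function(x, ...) {
  cat(sprintf(
    "<censat_enrichment_summary> %d units; %.1f%% ChIP-depleted (E < 1)\n",
    x$n_units, 100 * x$frac_depleted))
  occupied <- x$histogram[x$histogram$n > 0, ]
  print(occupied, n = 20)
  invisible(x)
}
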