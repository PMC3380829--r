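#' Matching parameters for the bounded-difference model
#'
#' A query matches a window of a reference read when a full-query alignment
#' exists with at most `max_differences` difference events, where one
#' mismatch is one event and one indel run of L bases is one event
#' contributing L bases to the total, and the total indel bases do not exceed
#' `max_total_indel_bases`.  Matching is global in the query and local in the
#' reference.
#'
#' @param max_differences Maximum difference events (0, 1 or 2; the exact
#'   case-analysis verifier is complete only up to 2, which is the model this
#'   package implements).
#' @param max_total_indel_bases Cap on the summed indel lengths (0--8).
#' @param search_both_strands Also match the reverse complement of each
#'   query.
#' @return A `match_params` list.
#' @examples
#' match_params()
#' @export
match_params <- function(max_differences = 2, max_total_indel_bases = 4,
                         search_both_strands = TRUE) {
  if (max_differences < 0 || max_differences > 2) {
    stop("max_differences must be 0, 1 or 2 (the verifier's exact case ",
         "analysis is complete only in that range)", call. = FALSE)
  }
  stopifnot(max_total_indel_bases >= 0, max_total_indel_bases <= 8)
  structure(list(max_differences = as.integer(max_differences),
                 max_total_indel_bases = as.integer(max_total_indel_bases),
                 search_both_strands = isTRUE(search_both_strands)),
            class = "match_params")
}

#' @export
print.match_params <- function(x, ...) {
  cat(sprintf(
    "<match_params> <= %d differences, <= %d indel bases, %s\n",
    x$max_differences, x$max_total_indel_bases,
    if (x$search_both_strands) "both strands" else "forward strand only"))
  invisible(x)
}

#' Index reference reads for seeded matching
#'
#' Builds an exact k-mer index over the reference reads.  Completeness of the
#' seeded search for queries of length `L` under ([match_params()] `d`
#' difference events, `B` indel bases) requires
#' `L >= (seed_length - 1) * (d + 1) + B + d`: any qualifying alignment then
#' contains an intact run of at least `seed_length` query bases.  The default
#' `seed_length = 9` is complete for 31-nt queries at (2, 4); [match_reads()]
#' warns when a query is too short for the guarantee.
#'
#' @param references Tibble with `read_id`/`sequence`, named character
#'   vector, or FASTA/FASTQ path.
#' @param seed_length Exact seed k-mer length (4--14).
#' @return A `censat_index` object.
#' @examples
#' idx <- reference_index(c(r1 = "ACGTACGTACGTACGTACGTACGTACGTACGT"))
#' idx
#' @export
reference_index <- function(references, seed_length = 9) {
  references <- resolve_reads(references, arg = "references")
  ptr <- cpp_build_index(references$sequence, as.integer(seed_length))
  structure(list(ptr = ptr, read_id = references$read_id,
                 n = nrow(references), seed_length = as.integer(seed_length)),
            class = "censat_index")
}

#' @export
print.censat_index <- function(x, ...) {
  cat(sprintf("<censat_index> %d reference reads, seed length %d\n",
              x$n, x$seed_length))
  invisible(x)
}

check_query_lengths <- function(lens, index, params) {
  need <- (index$seed_length - 1) * (params$max_differences + 1) +
    params$max_total_indel_bases + params$max_differences
  if (any(lens < 12)) {
    stop("queries shorter than 12 nt are not supported", call. = FALSE)
  }
  if (any(lens < need)) {
    warning(sprintf(paste0(
      "some queries are shorter than %d nt; seeded search is not guaranteed ",
      "complete for them at this seed length"), need), call. = FALSE)
  }
}

#' Match reads against an indexed reference set
#'
#' Returns every (query, reference, strand) combination for which a
#' qualifying alignment exists, with the best alignment's difference counts.
#' The search is complete within the difference bounds: no true hit is
#' missed (see [reference_index()] for the seed-length condition).
#'
#' @param queries Tibble with `read_id`/`sequence`, character vector, or
#'   file path.  All-N queries produce no hits.
#' @param index A [reference_index()].
#' @param params A [match_params()].
#' @return Tibble `query_id`, `reference_id`, `strand`, `n_differences`,
#'   `indel_bases`, `reference_offset` (0-based start of the aligned window's
#'   first segment).  One row per (query, reference, strand) with the
#'   best (fewest differences, then fewest indel bases) alignment.
#' @examples
#' ref <- c(r1 = "TTTTTACGTACGTACGTACGTACGTACGTACGTACGTTTTT")
#' idx <- reference_index(ref)
#' match_reads(c(q1 = "ACGTACGTACGTACGTACGTACGTACGTACGT"), idx)
#' @export
match_reads <- function(queries, index, params = match_params()) {
  stopifnot(inherits(index, "censat_index"))
  queries <- resolve_reads(queries, arg = "queries")
  if (nrow(queries) == 0 || index$n == 0) {
    return(tibble::tibble(query_id = character(), reference_id = character(),
                          strand = character(), n_differences = integer(),
                          indel_bases = integer(),
                          reference_offset = integer()))
  }
  check_query_lengths(nchar(queries$sequence), index, params)
  res <- cpp_match_query(index$ptr, queries$sequence,
                         params$max_differences,
                         params$max_total_indel_bases,
                         params$search_both_strands, "hits",
                         integer(), numeric(), "count_all")
  tibble::tibble(
    query_id = queries$read_id[res$query],
    reference_id = index$read_id[res$reference],
    strand = res$strand,
    n_differences = res$n_differences,
    indel_bases = res$indel_bases,
    reference_offset = res$ref_offset
  )
}

#' Count ChIP and input reads matching each reference read
#'
#' Runs the seeded matcher in counting mode for a ChIP and an input read set
#' and tabulates per-reference counts under the chosen multi-hit policy:
#' `"count_all"` (default) increments every reference a query matches;
#' `"fractional"` splits each query evenly across its matched references.  A
#' query matching a reference on both strands counts it once.
#'
#' @param chip,input Tibbles of QC'd reads (or character vectors / paths).
#' @param index A [reference_index()].
#' @param params A [match_params()].
#' @param policy `"count_all"` or `"fractional"`.
#' @return Tibble `reference_id`, `chip_count`, `input_count` (one row per
#'   reference read, zeros included), with attribute `"mapping_summary"`:
#'   a tibble of totals and mapped-read counts for both sets.
#' @examples
#' ref <- c(r1 = "TTTTTACGTACGTACGTACGTACGTACGTACGTACGTTTTT")
#' idx <- reference_index(ref)
#' q <- "ACGTACGTACGTACGTACGTACGTACGTACGT"
#' count_reference_hits(q, q, idx)
#' @export
count_reference_hits <- function(chip, input, index,
                                 params = match_params(),
                                 policy = c("count_all", "fractional")) {
  stopifnot(inherits(index, "censat_index"))
  policy <- match.arg(policy)
  chip <- resolve_reads(chip, arg = "chip")
  input <- resolve_reads(input, arg = "input")
  run <- function(reads) {
    if (nrow(reads) == 0) {
      return(list(counts = numeric(index$n), mapped = logical(0)))
    }
    check_query_lengths(nchar(reads$sequence), index, params)
    cpp_match_query(index$ptr, reads$sequence, params$max_differences,
                    params$max_total_indel_bases,
                    params$search_both_strands, "counts",
                    integer(), numeric(), policy)
  }
  rc <- run(chip)
  ri <- run(input)
  out <- tibble::tibble(reference_id = index$read_id,
                        chip_count = rc$counts,
                        input_count = ri$counts)
  attr(out, "mapping_summary") <- tibble::tibble(
    set = c("chip", "input"),
    n_reads = c(nrow(chip), nrow(input)),
    n_mapped = c(sum(rc$mapped), sum(ri$mapped))
  )
  out
}
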