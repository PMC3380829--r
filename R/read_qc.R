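#' QC parameters for read trimming and quality filtering
#'
#' Defaults implement the protocol: trim each read to 31 bp and remove reads
#' with more than one base below Phred 20.  When `trim_5p`/`trim_3p` are
#' `NULL`, the trim split is derived per read as
#' `trim_5p = ceiling(excess / 2)`, `trim_3p = floor(excess / 2)` where
#' `excess = read_length - target_length` (36-nt reads: 3 + 2; 35-nt: 2 + 2).
#'
#' @param target_length Length of trimmed reads (bp).
#' @param quality_threshold Phred threshold; bases with quality strictly
#'   below it count as low-quality.
#' @param max_low_quality_bases Maximum number of low-quality bases a kept
#'   read may contain.
#' @param trim_5p,trim_3p Explicit trim amounts; if set, reads whose length
#'   is not `trim_5p + trim_3p + target_length` are dropped as too short.
#' @return A `qc_params` list.
#' @examples
#' qc_params()
#' @export
qc_params <- function(target_length = 31, quality_threshold = 20,
                      max_low_quality_bases = 1,
                      trim_5p = NULL, trim_3p = NULL) {
  stopifnot(target_length >= 1, quality_threshold >= 0,
            max_low_quality_bases >= 0)
  if (xor(is.null(trim_5p), is.null(trim_3p))) {
    stop("supply both `trim_5p` and `trim_3p`, or neither", call. = FALSE)
  }
  structure(list(target_length = as.integer(target_length),
                 quality_threshold = as.integer(quality_threshold),
                 max_low_quality_bases = as.integer(max_low_quality_bases),
                 trim_5p = trim_5p, trim_3p = trim_3p),
            class = "qc_params")
}

#' @export
print.qc_params <- function(x, ...) {
  cat(sprintf(
    "<qc_params> target %d bp; drop reads with > %d bases below Q%d\n",
    x$target_length, x$max_low_quality_bases, x$quality_threshold))
  invisible(x)
}

#' Trim reads to the target length
#'
#' Trims bases from both ends (see [qc_params()] for the split rule); reads
#' shorter than the target are dropped and counted, not raised as errors.
#'
#' @param reads Tibble with `sequence` (and optionally `quality`, trimmed in
#'   lockstep), or a FASTA/FASTQ path.
#' @param params A [qc_params()] object.
#' @return Tibble of trimmed reads with attribute `n_dropped_short`.
#' @examples
#' r <- tibble::tibble(read_id = "r1",
#'                     sequence = strrep("ACGTAC", 6),
#'                     quality  = strrep("I", 36))
#' nchar(trim_reads(r, qc_params())$sequence)
#' @export
trim_reads <- function(reads, params = qc_params()) {
  reads <- resolve_reads(reads)
  len <- nchar(reads$sequence)
  tgt <- params$target_length
  if (is.null(params$trim_5p)) {
    t5 <- as.integer(ceiling((len - tgt) / 2))
  } else {
    t5 <- rep(as.integer(params$trim_5p), length(len))
    bad_len <- len != params$trim_5p + params$trim_3p + tgt
  }
  short <- len < tgt
  if (!is.null(params$trim_5p)) short <- short | bad_len
  out <- reads[!short, , drop = FALSE]
  t5 <- t5[!short]
  out$sequence <- substring(out$sequence, t5 + 1, t5 + tgt)
  if ("quality" %in% names(out)) {
    out$quality <- substring(out$quality, t5 + 1, t5 + tgt)
  }
  attr(out, "n_dropped_short") <- sum(short)
  out
}

#' Quality-filter reads
#'
#' Keeps a read iff it has at most `max_low_quality_bases` bases with quality
#' below `quality_threshold`.
#'
#' @inheritParams trim_reads
#' @return Logical keep vector, one element per read.
#' @examples
#' r <- tibble::tibble(sequence = c("ACGT", "ACGT"),
#'                     quality  = c("IIII", "I##I"))
#' quality_filter(r, qc_params())
#' @export
quality_filter <- function(reads, params = qc_params()) {
  reads <- resolve_reads(reads)
  if (!"quality" %in% names(reads)) {
    stop("quality filtering requires a `quality` column (FASTQ input)",
         call. = FALSE)
  }
  count_low_quality(reads$quality, params$quality_threshold) <=
    params$max_low_quality_bases
}

#' Run the full QC stage: trim, then quality-filter
#'
#' @inheritParams trim_reads
#' @return Tibble of surviving reads; the attribute `"qc_summary"` (see
#'   [qc_summary()]) accounts for every input read:
#'   `n_input = n_kept + dropped_short + dropped_quality`.
#' @examples
#' fam <- satellite_family("SAT-1", 50, 0.7, 1, 50)
#' g <- build_genome(fam, background_length = 20000, seed = 1)
#' rs <- simulate_chip_and_input(g, 200, 200, seed = 2)
#' qc <- qc_reads(rs$chip)
#' qc_summary(qc)
#' @export
qc_reads <- function(reads, params = qc_params()) {
  reads <- resolve_reads(reads, need_quality = TRUE)
  n_input <- nrow(reads)
  trimmed <- trim_reads(reads, params)
  dropped_short <- attr(trimmed, "n_dropped_short")
  keep <- quality_filter(trimmed, params)
  out <- trimmed[keep, , drop = FALSE]
  attr(out, "n_dropped_short") <- NULL
  attr(out, "qc_summary") <- tibble::tibble(
    n_input = n_input,
    n_kept = nrow(out),
    dropped_short = dropped_short,
    dropped_quality = sum(!keep)
  )
  out
}

#' @rdname qc_reads
#' @param x A tibble returned by [qc_reads()].
#' @export
qc_summary <- function(x) {
  s <- attr(x, "qc_summary")
  if (is.null(s)) stop("no qc_summary attribute; was this made by qc_reads()?",
                       call. = FALSE)
  s
}
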