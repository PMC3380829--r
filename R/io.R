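#' Read and write read sets as FASTA/FASTQ
#'
#' Thin wrappers around Biostrings I/O that move read sets between tibbles
#' (`read_id`, `sequence`, and for FASTQ `quality` as a Phred+33 string) and
#' files.
#'
#' @param reads Tibble with columns `read_id`, `sequence` (and `quality` for
#'   FASTQ).
#' @param path File path.
#' @return `read_sequences()` and `read_fastq()` return tibbles;
#'   the writers return `path` invisibly.
#' @examples
#' tmp <- tempfile(fileext = ".fasta")
#' write_fasta(tibble::tibble(read_id = "r1", sequence = "ACGTACGT"), tmp)
#' read_sequences(tmp)
#' @name censat_io
NULL

#' @rdname censat_io
#' @export
write_fasta <- function(reads, path) {
  reads <- resolve_reads(reads)
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname censat_io
#' @export
write_fastq <- function(reads, path) {
  reads <- resolve_reads(reads, need_quality = TRUE)
  x <- Biostrings::DNAStringSet(stats::setNames(reads$sequence, reads$read_id))
  q <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname censat_io
#' @export
read_sequences <- function(path) {
  fmt <- detect_format(path)
  if (fmt == "fastq") return(read_fastq(path))
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 sequence = as.character(unname(x)))
}

#' @rdname censat_io
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) {
      line <- locate_fastq_error(path)
      stop(sprintf("malformed FASTQ in '%s' near line %d: %s",
                   path, line, conditionMessage(e)), call. = FALSE)
    })
  tibble::tibble(read_id = sub("\\s.*$", "", names(x)),
                 sequence = as.character(unname(x)),
                 quality = as.character(S4Vectors::mcols(x)$qualities))
}

detect_format <- function(path) {
  first <- readLines(path, n = 1)
  if (length(first) && startsWith(first, "@")) "fastq" else "fasta"
}

# Best-effort diagnostic: first line at which the 4-line FASTQ structure
# breaks.
locate_fastq_error <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  i <- 1L
  while (i <= n) {
    if (!startsWith(lines[i], "@")) return(i)
    if (i + 3 > n) return(n)
    if (!startsWith(lines[i + 2], "+")) return(i + 2L)
    if (nchar(lines[i + 1]) != nchar(lines[i + 3])) return(i + 3L)
    i <- i + 4L
  }
  n
}
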