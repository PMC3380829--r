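#' Assemble a representative contig from a cluster's reads
#'
#' Greedy overlap extension: reads are deduplicated and canonically sorted
#' (longest first, then lexicographic); the first read seeds the contig,
#' which is repeatedly extended on the right by the unused read (either
#' strand) whose prefix overlaps the contig tail by at least `min_overlap`
#' bases at `min_identity` ungapped identity with the largest extension, then
#' symmetrically on the left.  Deterministic for a given read multiset.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `sequence` column.
#' @param min_overlap Minimum overlap length in bp.
#' @param min_identity Minimum ungapped identity of the overlap.
#' @param max_length Stop extending once the contig reaches this length
#'   (default 6000, at least two periods of the longest expected monomer).
#' @param max_steps Cap on extension steps.
#' @param max_reads Use at most this many reads (after canonical sorting).
#' @return List with `contig` (character scalar), `n_reads_used`, and
#'   `low_confidence` (`TRUE` when no overlaps were found and the contig is
#'   just the longest read).
#' @examples
#' arr <- strrep("GATTACAGGG", 12)
#' reads <- substring(arr, seq(1, 80, by = 7), seq(1, 80, by = 7) + 39)
#' res <- assemble_representative(reads)
#' nchar(res$contig)
#' @export
assemble_representative <- function(reads, min_overlap = 15,
                                    min_identity = 0.85, max_length = 6000,
                                    max_steps = 400, max_reads = 500) {
  if (is.data.frame(reads)) reads <- reads$sequence
  reads <- unique(reads)
  reads <- reads[order(-nchar(reads), reads)]
  if (length(reads) > max_reads) reads <- reads[seq_len(max_reads)]
  if (length(reads) == 0) stop("no reads to assemble", call. = FALSE)

  contig <- reads[1]
  used <- c(TRUE, rep(FALSE, length(reads) - 1))
  n_used <- 1L
  steps <- 0L
  extended <- FALSE

  extend_right <- function(contig) {
    repeat {
      if (nchar(contig) >= max_length || steps >= max_steps || all(used)) {
        return(contig)
      }
      avail <- which(!used)
      variants <- c(reads[avail], str_revcomp(reads[avail]))
      tail_seq <- substr(contig, max(1, nchar(contig) - 149), nchar(contig))
      hit <- cpp_best_extension(tail_seq, variants, as.integer(min_overlap),
                                min_identity)
      if (hit$index == 0 || nchar(hit$extension) == 0) return(contig)
      ridx <- avail[(hit$index - 1) %% length(avail) + 1]
      used[ridx] <<- TRUE
      n_used <<- n_used + 1L
      steps <<- steps + 1L
      extended <<- TRUE
      contig <- paste0(contig, hit$extension)
      if (nchar(contig) >= max_length) return(contig)
    }
  }

  contig <- extend_right(contig)
  contig <- str_revcomp(extend_right(str_revcomp(contig)))

  list(contig = contig, n_reads_used = n_used,
       low_confidence = !extended)
}

#' Estimate the monomer length of a (putative) tandem array
#'
#' The fundamental period is found by self-comparison: for each shift `s`,
#' the identity between `seq[1..L-s]` and `seq[s+1..L]` is computed; among
#' shifts whose identity reaches at least `min_identity`, the smallest shift
#' within `tolerance` of the maximum identity is reported (so an exact dimer
#' array reports the monomer, and point divergence does not inflate the
#' period).
#'
#' @param sequence Contig or array sequence (ideally >= 2 periods long).
#' @param min_identity Identity floor below which no period is called.
#' @param tolerance Identity slack for preferring smaller shifts.
#' @return List `monomer_length` (NA when aperiodic), `identity` (identity at
#'   the reported shift), `periodic` (logical).
#' @examples
#' estimate_monomer_length(strrep("GATTACAGGG", 10))$monomer_length
#' estimate_monomer_length(strrep("A", 50))$monomer_length  # homopolymer
#' @export
estimate_monomer_length <- function(sequence, min_identity = 0.8,
                                    tolerance = 0.02) {
  L <- nchar(sequence)
  smax <- L %/% 2
  if (smax < 1) {
    return(list(monomer_length = NA_integer_, identity = NA_real_,
                periodic = FALSE))
  }
  ids <- cpp_shift_identity(sequence, as.integer(smax))
  ok <- which(!is.na(ids) & ids >= min_identity)
  if (length(ok) == 0) {
    return(list(monomer_length = NA_integer_, identity = NA_real_,
                periodic = FALSE))
  }
  best <- max(ids[ok])
  m <- ok[ids[ok] >= best - tolerance][1]
  list(monomer_length = as.integer(m), identity = ids[m], periodic = TRUE)
}

#' Verify head-to-tail tandem organization
#'
#' In-silico analog of the outward-primer test: locate copies of the
#' consensus in the target (both strands, allowing
#' `floor(max_mismatch_fraction * m)` mismatches) and report `TRUE` iff two
#' adjacent same-strand copies occur with an inter-copy gap of at most
#' `max_gap_fraction * m` bases.
#'
#' @param target Sequence to scan (assembled contig, genome, or long read).
#' @param consensus Family consensus (one monomer).
#' @param max_mismatch_fraction Mismatch tolerance when locating copies.
#' @param max_gap_fraction Maximum junction gap, as a fraction of the monomer
#'   length.
#' @return Logical scalar with attribute `n_copies` (copies found; 0 means
#'   the consensus was not found at all).
#' @examples
#' verify_tandem_organization(strrep("GATTACAGGG", 6), "GATTACAGGG")
#' @export
verify_tandem_organization <- function(target, consensus,
                                       max_mismatch_fraction = 0.15,
                                       max_gap_fraction = 0.1) {
  m <- nchar(consensus)
  if (m < 1 || m > nchar(target)) {
    return(structure(FALSE, n_copies = 0L))
  }
  max_mm <- floor(max_mismatch_fraction * m)
  subject <- Biostrings::DNAString(target)
  find <- function(pat) {
    hits <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                     max.mismatch = max_mm)
    IRanges::ranges(hits)
  }
  plus <- find(consensus)
  minus <- find(str_revcomp(consensus))
  n_copies <- length(plus) + length(minus)
  adjacent <- function(r) {
    if (length(r) < 2) return(FALSE)
    st <- sort(IRanges::start(r))
    any(diff(st) <= m + max_gap_fraction * m)
  }
  structure(adjacent(plus) || adjacent(minus), n_copies = n_copies)
}

#' AT content of sequences
#'
#' Fraction `(A + T) / (A + C + G + T)`; ambiguous bases (N) are excluded
#' from both numerator and denominator.  All-ambiguous input yields `NA`.
#'
#' @param sequence Character vector of sequences.
#' @return Numeric vector of AT fractions.
#' @examples
#' at_content(c("ATAT", "ACGT", "NNNN"))
#' @export
at_content <- function(sequence) {
  at <- stringr::str_count(sequence, "[ATat]")
  gc <- stringr::str_count(sequence, "[CGcg]")
  ifelse(at + gc == 0, NA_real_, at / (at + gc))
}

#' Classify a profiled cluster
#'
#' A cluster is `ltr_retroelement` when its contig aligns to any element of
#' the reference library at `min_retro_identity` identity over at least
#' `min_retro_coverage` of the shorter of contig and library element --
#' a long contig chaining several dispersed copies still counts as covered
#' when one full element aligns (this takes precedence over a periodic
#' signal, which identical LTRs can mimic; the conflict is flagged);
#' `satellite` when the contig is periodic AND tandem-organized; otherwise
#' `unclassified`.
#'
#' @param contig Representative contig sequence.
#' @param monomer Result of [estimate_monomer_length()].
#' @param tandem Result of [verify_tandem_organization()].
#' @param retro_library Optional named character vector (or tibble) of known
#'   retroelement sequences.
#' @param min_retro_identity,min_retro_coverage Retroelement-similarity
#'   thresholds.
#' @return List `classification` (`"satellite"`, `"ltr_retroelement"` or
#'   `"unclassified"`), `retro_identity` (best library identity or NA), and
#'   `conflict` (`TRUE` when retro-similar AND periodic+tandem).
#' @examples
#' arr <- strrep("GATTACAGGG", 20)
#' mono <- estimate_monomer_length(arr)
#' tand <- verify_tandem_organization(arr, "GATTACAGGG")
#' classify_cluster(arr, mono, tand)$classification
#' @export
classify_cluster <- function(contig, monomer, tandem, retro_library = NULL,
                             min_retro_identity = 0.8,
                             min_retro_coverage = 0.5) {
  if (is.data.frame(retro_library)) retro_library <- retro_library$sequence
  retro_identity <- NA_real_
  is_retro <- FALSE
  for (elem in retro_library %||% character()) {
    for (s in c(elem, str_revcomp(elem))) {
      al <- cpp_local_align(contig, s)
      cov <- (al$a_end - al$a_start) / min(nchar(contig), nchar(s))
      if (al$columns > 0 && cov >= min_retro_coverage) {
        if (is.na(retro_identity) || al$identity > retro_identity) {
          retro_identity <- al$identity
        }
        if (al$identity >= min_retro_identity) is_retro <- TRUE
      }
    }
  }
  is_sat <- isTRUE(monomer$periodic) && isTRUE(as.logical(tandem))
  classification <- if (is_retro) "ltr_retroelement" else
    if (is_sat) "satellite" else "unclassified"
  list(classification = classification,
       retro_identity = retro_identity,
       conflict = is_retro && is_sat)
}

#' All-vs-all windowed dotplot
#'
#' For every ordered pair of sequences (including self-pairs), reports each
#' position pair whose `window`-length ungapped comparison reaches
#' `min_identity`, on both strands.  The match set is symmetric under pair
#' swap.
#'
#' @param sequences Named character vector or tibble
#'   (`read_id`/`family_id` + `sequence`).
#' @param window Window length (must not exceed the shortest sequence).
#' @param min_identity Minimum window identity.
#' @param step Report every `step`-th matching position (thins dense
#'   diagonals).
#' @return A tibble of class `censat_dotplot`: `seq_a`, `seq_b`, `pos_a`,
#'   `pos_b` (0-based window starts; minus-strand `pos_b` is in reverse
#'   complement coordinates), `strand`.  Has an [ggplot2::autoplot()] method.
#' @examples
#' dp <- dotplot(c(x = strrep("GATTACAGGG", 10)), window = 20)
#' nrow(dp) > 0  # self-similarity off-diagonals
#' @export
dotplot <- function(sequences, window = 50, min_identity = 0.9, step = 1) {
  if (is.data.frame(sequences)) {
    ids <- sequences[[intersect(c("family_id", "read_id", "id"),
                                names(sequences))[1]]]
    sequences <- stats::setNames(sequences$sequence, ids)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq_%03d", seq_along(sequences))
  }
  stopifnot(length(sequences) >= 1, window >= 4,
            window <= min(nchar(sequences)))
  rows <- list()
  nm <- names(sequences)
  for (a in seq_along(sequences)) {
    for (b in a:length(sequences)) {
      hits <- cpp_dotplot(sequences[[a]], sequences[[b]],
                          as.integer(window), min_identity,
                          as.integer(step))
      if (length(hits$pos_a) == 0) next
      tb <- tibble::tibble(seq_a = nm[a], seq_b = nm[b],
                           pos_a = hits$pos_a, pos_b = hits$pos_b,
                           strand = hits$strand)
      rows[[length(rows) + 1]] <- tb
      if (a != b) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          seq_a = nm[b], seq_b = nm[a], pos_a = hits$pos_b,
          pos_b = hits$pos_a, strand = hits$strand)
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(seq_a = character(), seq_b = character(),
                   pos_a = integer(), pos_b = integer(),
                   strand = character())
  class(out) <- c("censat_dotplot", class(out))
  attr(out, "window") <- window
  attr(out, "min_identity") <- min_identity
  out
}

#' Percent identity of two sequences
#'
#' Global-in-the-shorter / local-in-the-longer ("glocal") alignment: the
#' shorter sequence must align end to end, end gaps on the longer sequence
#' are free.  Scoring: match +1, mismatch -1, gap opening 2, gap extension
#' 0.5 (nucleotide) or BLOSUM62 with the same gap costs (protein).  Identity
#' is matches over alignment columns.
#'
#' @param seq_a,seq_b Sequences (character scalars).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return Percent identity in `[0, 100]`, with attribute `"parameters"`
#'   recording the alignment settings.
#' @examples
#' pairwise_identity("ACGT", "ACGA")  # 75
#' @export
pairwise_identity <- function(seq_a, seq_b,
                              alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  if (nchar(seq_a) > nchar(seq_b)) { tmp <- seq_a; seq_a <- seq_b; seq_b <- tmp }
  if (alphabet == "nucleotide") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = FALSE)
    pat <- Biostrings::DNAString(seq_a)
    sub <- Biostrings::DNAString(seq_b)
  } else {
    mat <- "BLOSUM62"
    pat <- Biostrings::AAString(seq_a)
    sub <- Biostrings::AAString(seq_b)
  }
  aln <- Biostrings::pairwiseAlignment(pat, sub, type = "global-local",
                                       substitutionMatrix = mat,
                                       gapOpening = 2, gapExtension = 0.5)
  structure(Biostrings::pid(aln, type = "PID1"),
            parameters = sprintf(paste0(
              "glocal (shorter sequence global); %s; match +1/mismatch -1 ",
              "or BLOSUM62; gap open 2, extend 0.5; PID1"), alphabet))
}
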