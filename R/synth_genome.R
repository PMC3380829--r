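#' Declare a tandem satellite family for the synthetic genome
#'
#' A satellite family is realized as `n_loci` tandem arrays, each containing a
#' (possibly ranged) number of head-to-tail copies of a family consensus
#' monomer, with independent per-base substitutions at rate `divergence`.
#'
#' @param family_id Family label.
#' @param monomer_length Monomer length in bp (>= 1).
#' @param at_content Target AT fraction of the consensus monomer; the realized
#'   consensus carries exactly `round(monomer_length * at_content)` A/T bases.
#' @param n_loci Number of tandem arrays placed in the genome.
#' @param copies_per_locus Integer count, or length-2 range from which the
#'   copy number of each locus is drawn uniformly.
#' @param divergence Per-base substitution probability in `[0, 0.3]` applied
#'   independently to every realized base.
#' @param fold_enrichment ChIP sampling weight relative to background (1 =
#'   no enrichment); this is the ground truth that the pipeline's enrichment
#'   estimates recover.
#' @return One-row tibble describing the family, ready to be row-bound with
#'   other family specs and passed to [build_genome()].
#' @examples
#' satellite_family("SAT-1", monomer_length = 50, at_content = 0.72,
#'                  n_loci = 2, copies_per_locus = 40)
#' @export
satellite_family <- function(family_id, monomer_length, at_content,
                             n_loci = 1, copies_per_locus = 10,
                             divergence = 0, fold_enrichment = 1) {
  stopifnot(monomer_length >= 1, at_content >= 0, at_content <= 1,
            n_loci >= 1, divergence >= 0, divergence <= 0.3,
            fold_enrichment >= 0,
            length(copies_per_locus) %in% c(1, 2), all(copies_per_locus >= 1))
  tibble::tibble(
    family_id = as.character(family_id), type = "satellite",
    monomer_length = as.integer(monomer_length), at_content = at_content,
    n_loci = as.integer(n_loci),
    copies_min = as.integer(min(copies_per_locus)),
    copies_max = as.integer(max(copies_per_locus)),
    divergence = divergence, fold_enrichment = fold_enrichment,
    element_length = NA_integer_, ltr_length = NA_integer_,
    n_insertions = NA_integer_
  )
}

#' Declare a dispersed LTR retroelement family for the synthetic genome
#'
#' The element is a single consensus of `element_length` bp whose first and
#' last `ltr_length` bp are identical (the long terminal repeats).  Its
#' `n_insertions` copies are dispersed -- placed at non-adjacent genomic
#' positions separated by background sequence -- never tandemly arranged.
#'
#' @inheritParams satellite_family
#' @param element_length Full element length in bp (>= 2 * `ltr_length`).
#' @param ltr_length Length of each identical terminal repeat.
#' @param n_insertions Number of dispersed insertions.
#' @return One-row tibble compatible with [satellite_family()] rows.
#' @examples
#' retroelement_family("CRM-like", element_length = 3000, ltr_length = 300,
#'                     n_insertions = 25, at_content = 0.62)
#' @export
retroelement_family <- function(family_id, element_length = 3000,
                                ltr_length = 300, n_insertions = 10,
                                at_content = 0.5, divergence = 0,
                                fold_enrichment = 1) {
  stopifnot(element_length >= 2 * ltr_length, ltr_length >= 0,
            n_insertions >= 1, divergence >= 0, divergence <= 0.3,
            fold_enrichment >= 0)
  tibble::tibble(
    family_id = as.character(family_id), type = "retroelement",
    monomer_length = NA_integer_, at_content = at_content,
    n_loci = as.integer(n_insertions),
    copies_min = 1L, copies_max = 1L,
    divergence = divergence, fold_enrichment = fold_enrichment,
    element_length = as.integer(element_length),
    ltr_length = as.integer(ltr_length),
    n_insertions = as.integer(n_insertions)
  )
}

#' Build a truth-annotated synthetic genome
#'
#' Places every family's repeat blocks (tandem arrays for satellites,
#' dispersed single copies for retroelements) in random order along a
#' background sequence, separated by background gaps of at least `min_gap`
#' bp.  Total background length is exactly `background_length`, so annotated
#' repeat bp + background bp = genome length.
#'
#' @param families Tibble of family specs from [satellite_family()] /
#'   [retroelement_family()] (row-bind them).
#' @param background_length Total background bp (must leave room for at least
#'   `min_gap` between consecutive repeat blocks and at both ends).
#' @param seed Integer seed; the genome is deterministic given
#'   (families, background_length, seed).
#' @param background_at AT fraction of the background sequence.
#' @param min_gap Minimum background gap (bp) between repeat blocks.
#' @return An object of class `censat_genome`: a list with `sequence`
#'   (character scalar), `annotations` (tibble `family_id`, `start`, `end`,
#'   `strand`; 0-based half-open), `genome_length`, `families` (the input
#'   spec plus realized totals), and `consensus` (named character vector of
#'   family consensus sequences).
#' @examples
#' fam <- satellite_family("SAT-1", 50, 0.72, n_loci = 1,
#'                         copies_per_locus = 100)
#' g <- build_genome(fam, background_length = 20000, seed = 1)
#' g
#' @export
build_genome <- function(families, background_length, seed,
                         background_at = 0.5, min_gap = 100) {
  stopifnot(is.data.frame(families), nrow(families) >= 1,
            background_length > 0)
  if (anyDuplicated(families$family_id)) {
    stop("duplicated family_id in `families`", call. = FALSE)
  }
  with_seed(seed, {
    # consensus per family
    consensus <- vapply(seq_len(nrow(families)), function(i) {
      f <- families[i, ]
      if (f$type == "satellite") {
        consensus_dna(f$monomer_length, f$at_content)
      } else {
        ltr <- consensus_dna(f$ltr_length, f$at_content)
        internal <- consensus_dna(f$element_length - 2 * f$ltr_length,
                                  f$at_content)
        paste0(ltr, internal, ltr)
      }
    }, character(1))
    names(consensus) <- families$family_id

    # realized repeat blocks
    blocks <- purrr::map(seq_len(nrow(families)), function(i) {
      f <- families[i, ]
      purrr::map(seq_len(f$n_loci), function(j) {
        n_copies <- if (f$copies_min == f$copies_max) f$copies_min else
          sample(seq(f$copies_min, f$copies_max), 1)
        raw <- if (f$type == "satellite") {
          strrep(consensus[[f$family_id]], n_copies)
        } else {
          consensus[[f$family_id]]
        }
        list(family_id = f$family_id,
             sequence = mutate_dna(raw, f$divergence),
             strand = sample(c("+", "-"), 1))
      })
    })
    blocks <- purrr::flatten(blocks)
    blocks <- blocks[sample(length(blocks))]

    n_blocks <- length(blocks)
    n_seg <- n_blocks + 1
    extra <- background_length - n_seg * min_gap
    if (extra < 0) {
      stop(sprintf(paste0(
        "cannot place %d repeat blocks with min_gap = %d in %d bp of ",
        "background; need at least %d bp"),
        n_blocks, min_gap, background_length, n_seg * min_gap),
        call. = FALSE)
    }
    breaks <- sort(sample(0:extra, n_seg - 1, replace = TRUE))
    seg_len <- diff(c(0, breaks, extra)) + min_gap

    pieces <- character(2 * n_blocks + 1)
    ann <- vector("list", n_blocks)
    pos <- 0L
    for (b in seq_len(n_blocks)) {
      bg <- random_dna(seg_len[b], background_at)
      pieces[2 * b - 1] <- bg
      pos <- pos + seg_len[b]
      blk <- blocks[[b]]
      s <- blk$sequence
      if (blk$strand == "-") s <- str_revcomp(s)
      pieces[2 * b] <- s
      ann[[b]] <- tibble::tibble(family_id = blk$family_id, start = pos,
                                 end = pos + nchar(s), strand = blk$strand)
      pos <- pos + nchar(s)
    }
    pieces[2 * n_blocks + 1] <- random_dna(seg_len[n_seg], background_at)
    sequence <- paste(pieces, collapse = "")
    annotations <- dplyr::bind_rows(ann)

    fam_out <- families
    fam_out$annotated_bp <- vapply(families$family_id, function(id) {
      sum(annotations$end[annotations$family_id == id] -
            annotations$start[annotations$family_id == id])
    }, numeric(1))
    fam_out$consensus <- unname(consensus)

    structure(
      list(sequence = sequence, annotations = annotations,
           genome_length = nchar(sequence), families = fam_out,
           consensus = consensus, seed = seed),
      class = "censat_genome"
    )
  })
}

#' @export
print.censat_genome <- function(x, ...) {
  cat(sprintf("<censat_genome> %s bp, %d repeat blocks, %d families\n",
              format(x$genome_length, big.mark = ","),
              nrow(x$annotations), nrow(x$families)))
  print(genome_proportions(x))
  invisible(x)
}

#' Realized genome proportions and expected enrichment of a synthetic genome
#'
#' `genome_proportions()` reports each family's annotated bp and fraction of
#' the genome.  `expected_enrichment()` adds the analytic expectation of the
#' ChIP/input enrichment ratio under the generator's sampling model: ChIP
#' read positions are drawn with weight equal to the covering family's
#' `fold_enrichment` (background weight 1), so
#' `E(f) = w_f / sum_g p_g * w_g`, the sum running over all families plus
#' background.
#'
#' @param genome A `censat_genome`.
#' @return Tibble with one row per family.
#' @examples
#' fam <- satellite_family("SAT-1", 50, 0.7, 1, 100, fold_enrichment = 50)
#' g <- build_genome(fam, background_length = 50000, seed = 1)
#' expected_enrichment(g)
#' @export
genome_proportions <- function(genome) {
  stopifnot(inherits(genome, "censat_genome"))
  tibble::tibble(
    family_id = genome$families$family_id,
    type = genome$families$type,
    annotated_bp = genome$families$annotated_bp,
    proportion = genome$families$annotated_bp / genome$genome_length
  )
}

#' @rdname genome_proportions
#' @export
expected_enrichment <- function(genome) {
  p <- genome_proportions(genome)
  w <- genome$families$fold_enrichment
  p_bg <- 1 - sum(p$proportion)
  denom <- sum(p$proportion * w) + p_bg * 1
  dplyr::mutate(p, fold_enrichment = w,
                expected_enrichment = w / denom)
}

#' Simulate low-coverage reference reads from a synthetic genome
#'
#' Read start positions are uniform over the genome, strands uniform (minus
#' strand reads are reverse-complemented), and each read is truth-labelled by
#' the family covering the majority (> half) of its bases, otherwise
#' `"background"`.
#'
#' @param genome A `censat_genome`.
#' @param coverage Fold coverage in `(0, 2]`; read count =
#'   `round(coverage * genome_length / read_length)`.
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return Tibble `read_id`, `sequence`, `start` (0-based), `strand`,
#'   `truth_family`.
#' @examples
#' fam <- satellite_family("SAT-1", 50, 0.7, 1, 100)
#' g <- build_genome(fam, background_length = 100000, seed = 1)
#' refs <- simulate_reference_reads(g, coverage = 0.48, read_length = 100,
#'                                  seed = 2)
#' nrow(refs)  # round(0.48 * genome_length / 100)
#' @export
simulate_reference_reads <- function(genome, coverage = 0.48,
                                     read_length = 100, seed = 1) {
  stopifnot(inherits(genome, "censat_genome"),
            coverage > 0, coverage <= 2,
            read_length <= genome$genome_length)
  n <- round(coverage * genome$genome_length / read_length)
  with_seed(seed, {
    starts <- sample.int(genome$genome_length - read_length + 1, n,
                         replace = TRUE)           # 1-based
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- substring(genome$sequence, starts, starts + read_length - 1)
    minus <- strands == "-"
    if (any(minus)) seqs[minus] <- str_revcomp(seqs[minus])
    tibble::tibble(
      read_id = sprintf("ref_%07d", seq_len(n)),
      sequence = seqs,
      start = starts - 1L,
      strand = strands,
      truth_family = truth_label(genome, starts - 1L, read_length)
    )
  })
}

# Majority-bp truth labelling: the family overlapping more than half of the
# read wins; anything else (including exact half) is background.
truth_label <- function(genome, starts0, read_length) {
  ann <- genome$annotations
  reads_ir <- IRanges::IRanges(start = starts0 + 1L, width = read_length)
  ann_ir <- IRanges::IRanges(start = ann$start + 1L,
                             width = ann$end - ann$start)
  ov <- IRanges::findOverlaps(reads_ir, ann_ir)
  w <- IRanges::width(IRanges::pintersect(
    reads_ir[S4Vectors::queryHits(ov)], ann_ir[S4Vectors::subjectHits(ov)]))
  lab <- rep("background", length(starts0))
  if (length(ov)) {
    df <- data.frame(read = S4Vectors::queryHits(ov),
                     fam = ann$family_id[S4Vectors::subjectHits(ov)],
                     w = w)
    df <- df[order(df$read, -df$w), ]
    df <- df[!duplicated(df$read), ]
    win <- df$w > read_length / 2
    lab[df$read[win]] <- df$fam[win]
  }
  lab
}

#' Simulate ChIP and input read sets with locus-specific enrichment
#'
#' Input reads are sampled uniformly over the genome.  ChIP reads are sampled
#' with per-start-position weight equal to the `fold_enrichment` of the
#' family covering the read midpoint (background weight 1).  Under this
#' normalization the expected realized enrichment of family `f` is
#' `fold_enrichment(f) / sum_g p_g * fold_enrichment(g)` with the sum over
#' all families plus background at weight 1 (see [expected_enrichment()]).
#' Phred qualities are `round(rnorm(mean, sd))` clamped to `[2, 60]`, with a
#' fraction `low_quality_rate` of bases replaced by qualities drawn uniformly
#' from 2..19.
#'
#' @param genome A `censat_genome`.
#' @param n_chip,n_input Read counts (> 0).
#' @param read_length Read length in bp (default 36).
#' @param quality_model List with `mean`, `sd`, `low_quality_rate`.
#' @param seed Integer seed.
#' @return List with tibbles `chip` and `input`, each with `read_id`,
#'   `sequence`, `quality` (Phred+33 string), `start`, `strand`,
#'   `truth_family`.
#' @examples
#' fam <- satellite_family("SAT-1", 50, 0.7, 1, 100, fold_enrichment = 50)
#' g <- build_genome(fam, background_length = 50000, seed = 1)
#' rs <- simulate_chip_and_input(g, n_chip = 1000, n_input = 1000, seed = 3)
#' head(rs$chip)
#' @export
simulate_chip_and_input <- function(genome, n_chip, n_input,
                                    read_length = 36,
                                    quality_model = list(
                                      mean = 36, sd = 3,
                                      low_quality_rate = 0.01),
                                    seed = 1) {
  stopifnot(inherits(genome, "censat_genome"), n_chip > 0, n_input > 0,
            read_length <= genome$genome_length)
  npos <- genome$genome_length - read_length + 1L
  midoff <- read_length %/% 2L

  # per-start weight from the family covering the read midpoint
  w <- rep(1, npos)
  ann <- genome$annotations
  fold <- genome$families$fold_enrichment[
    match(ann$family_id, genome$families$family_id)]
  for (i in seq_len(nrow(ann))) {
    lo <- max(1L, ann$start[i] - midoff + 1L)
    hi <- min(npos, ann$end[i] - midoff)
    if (lo <= hi) w[lo:hi] <- fold[i]
  }
  if (all(w == 0)) stop("all sampling weights are zero", call. = FALSE)

  with_seed(seed, {
    sample_set <- function(n, prob, prefix) {
      starts <- sample.int(npos, n, replace = TRUE, prob = prob)
      strands <- sample(c("+", "-"), n, replace = TRUE)
      seqs <- substring(genome$sequence, starts, starts + read_length - 1)
      minus <- strands == "-"
      if (any(minus)) seqs[minus] <- str_revcomp(seqs[minus])
      q <- matrix(as.integer(pmin(pmax(round(stats::rnorm(
        n * read_length, quality_model$mean, quality_model$sd)), 2L), 60L)),
        nrow = n)
      low <- matrix(stats::runif(n * read_length) <
                      quality_model$low_quality_rate, nrow = n)
      if (any(low)) q[low] <- sample(2:19, sum(low), replace = TRUE)
      qual <- vapply(seq_len(n), function(i) phred_to_string(q[i, ]),
                     character(1))
      tibble::tibble(
        read_id = sprintf("%s_%07d", prefix, seq_len(n)),
        sequence = seqs, quality = qual,
        start = starts - 1L, strand = strands,
        truth_family = truth_label(genome, starts - 1L, read_length)
      )
    }
    list(chip = sample_set(n_chip, w, "chip"),
         input = sample_set(n_input, NULL, "input"))
  })
}
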