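#' Pipeline configuration
#'
#' Bundles all stage parameters; serializable to a plain-text file with
#' [write_censat_config()] / [read_censat_config()].
#'
#' @param qc [qc_params()].
#' @param match [match_params()].
#' @param similarity [similarity_params()].
#' @param enrichment_threshold Inclusive enrichment cutoff (default 10).
#' @param top_n_clusters Cluster count kept in approach A (default 1000).
#' @param reference_sample_size Reference reads sampled for approach A
#'   clustering (default 2e6).
#' @param min_cluster_reads Minimum members for a cluster to be profiled
#'   (contig assembly needs >= 5 reads).
#' @param genome_size_mbp Genome size used for Mbp conversions.
#' @param zero_policy Zero-input policy of [compute_enrichment()].
#' @param seed Seed for the pipeline's sampling steps.
#' @return A `censat_config` list.
#' @examples
#' censat_config(seed = 42)
#' @export
censat_config <- function(qc = qc_params(), match = match_params(),
                          similarity = similarity_params(),
                          enrichment_threshold = 10,
                          top_n_clusters = 1000,
                          reference_sample_size = 2e6,
                          min_cluster_reads = 5,
                          genome_size_mbp = 4300,
                          zero_policy = c("infinite", "pseudocount"),
                          seed = 1) {
  stopifnot(inherits(qc, "qc_params"), inherits(match, "match_params"),
            inherits(similarity, "similarity_params"),
            enrichment_threshold >= 0, top_n_clusters >= 1,
            reference_sample_size >= 1, min_cluster_reads >= 1,
            genome_size_mbp > 0)
  structure(list(qc = qc, match = match, similarity = similarity,
                 enrichment_threshold = enrichment_threshold,
                 top_n_clusters = as.integer(top_n_clusters),
                 reference_sample_size = reference_sample_size,
                 min_cluster_reads = as.integer(min_cluster_reads),
                 genome_size_mbp = genome_size_mbp,
                 zero_policy = match.arg(zero_policy),
                 seed = seed),
            class = "censat_config")
}

#' @export
print.censat_config <- function(x, ...) {
  cat("<censat_config>\n")
  cat(sprintf("  QC: target %d bp, <= %d bases below Q%d\n",
              x$qc$target_length, x$qc$max_low_quality_bases,
              x$qc$quality_threshold))
  cat(sprintf("  match: <= %d differences, <= %d indel bases\n",
              x$match$max_differences, x$match$max_total_indel_bases))
  cat(sprintf("  similarity: %.2f identity over %.2f of shorter read\n",
              x$similarity$min_identity, x$similarity$min_overlap_fraction))
  cat(sprintf(paste0("  enrichment threshold %s; top %d clusters; ",
                     "genome %s Mbp; seed %s\n"),
              format(x$enrichment_threshold), x$top_n_clusters,
              format(x$genome_size_mbp), format(x$seed)))
  invisible(x)
}

#' @rdname censat_config
#' @param config A `censat_config`.
#' @param path File path for the plain-text serialization.
#' @export
write_censat_config <- function(config, path) {
  flat <- c(
    qc.target_length = config$qc$target_length,
    qc.quality_threshold = config$qc$quality_threshold,
    qc.max_low_quality_bases = config$qc$max_low_quality_bases,
    qc.trim_5p = config$qc$trim_5p %||% NA,
    qc.trim_3p = config$qc$trim_3p %||% NA,
    match.max_differences = config$match$max_differences,
    match.max_total_indel_bases = config$match$max_total_indel_bases,
    match.search_both_strands = config$match$search_both_strands,
    similarity.min_identity = config$similarity$min_identity,
    similarity.min_overlap_fraction = config$similarity$min_overlap_fraction,
    similarity.seed_length = config$similarity$seed_length,
    enrichment_threshold = config$enrichment_threshold,
    top_n_clusters = config$top_n_clusters,
    reference_sample_size = config$reference_sample_size,
    min_cluster_reads = config$min_cluster_reads,
    genome_size_mbp = config$genome_size_mbp,
    zero_policy = config$zero_policy,
    seed = config$seed
  )
  writeLines(sprintf("%s: %s", names(flat), as.character(flat)), path)
  invisible(path)
}

#' @rdname censat_config
#' @export
read_censat_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ": ", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  num <- function(k) as.numeric(vals[[k]])
  maybe <- function(k) if (vals[[k]] == "NA") NULL else as.integer(vals[[k]])
  censat_config(
    qc = qc_params(target_length = num("qc.target_length"),
                   quality_threshold = num("qc.quality_threshold"),
                   max_low_quality_bases = num("qc.max_low_quality_bases"),
                   trim_5p = maybe("qc.trim_5p"),
                   trim_3p = maybe("qc.trim_3p")),
    match = match_params(
      max_differences = num("match.max_differences"),
      max_total_indel_bases = num("match.max_total_indel_bases"),
      search_both_strands = as.logical(vals[["match.search_both_strands"]])),
    similarity = similarity_params(
      min_identity = num("similarity.min_identity"),
      min_overlap_fraction = num("similarity.min_overlap_fraction"),
      seed_length = num("similarity.seed_length")),
    enrichment_threshold = num("enrichment_threshold"),
    top_n_clusters = num("top_n_clusters"),
    reference_sample_size = num("reference_sample_size"),
    min_cluster_reads = num("min_cluster_reads"),
    genome_size_mbp = num("genome_size_mbp"),
    zero_policy = vals[["zero_policy"]],
    seed = num("seed")
  )
}

# Profile clusters: contig, monomer, tandem organization, AT content,
# classification.  `get_seq` maps read ids to sequences.
profile_clusters <- function(clusters, get_seq, retro_library,
                             min_cluster_reads) {
  if (nrow(clusters) == 0) {
    return(tibble::tibble(cluster_id = integer(),
                          classification = character(),
                          monomer_length = integer(),
                          monomer_identity = numeric(), tandem = logical(),
                          at_content = numeric(), contig = character(),
                          low_confidence = logical(),
                          retro_identity = numeric(),
                          retro_conflict = logical(), profiled = logical()))
  }
  rows <- purrr::map(seq_len(nrow(clusters)), function(i) {
    cl <- clusters[i, ]
    base <- tibble::tibble(cluster_id = cl$cluster_id)
    if (cl$n_members < min_cluster_reads) {
      return(dplyr::mutate(base, classification = "unclassified",
                           monomer_length = NA_integer_,
                           monomer_identity = NA_real_, tandem = NA,
                           at_content = NA_real_, contig = NA_character_,
                           low_confidence = TRUE, retro_identity = NA_real_,
                           retro_conflict = NA, profiled = FALSE))
    }
    seqs <- get_seq(cl$member_ids[[1]])
    asm <- assemble_representative(seqs)
    mono <- estimate_monomer_length(asm$contig)
    tand <- if (mono$periodic) {
      # take the monomer representative from the middle of the contig:
      # greedy assembly ends can carry short misassembled anchors
      mid <- max(0L, (nchar(asm$contig) - mono$monomer_length) %/% 2L)
      verify_tandem_organization(
        asm$contig, substr(asm$contig, mid + 1L, mid + mono$monomer_length))
    } else {
      structure(FALSE, n_copies = 0L)
    }
    cls <- classify_cluster(asm$contig, mono, tand, retro_library)
    tibble::tibble(
      cluster_id = cl$cluster_id,
      classification = cls$classification,
      monomer_length = if (cls$classification == "ltr_retroelement")
        NA_integer_ else mono$monomer_length,
      monomer_identity = mono$identity,
      tandem = as.logical(tand),
      at_content = at_content(asm$contig),
      contig = asm$contig,
      low_confidence = asm$low_confidence,
      retro_identity = cls$retro_identity,
      retro_conflict = cls$conflict,
      profiled = TRUE
    )
  })
  dplyr::bind_rows(rows)
}

build_report <- function(clusters, enr, prof, config) {
  clusters |>
    dplyr::select("cluster_id", "n_members", "genome_proportion") |>
    dplyr::left_join(enr, by = "cluster_id") |>
    dplyr::left_join(prof, by = "cluster_id") |>
    dplyr::mutate(
      family_id = sprintf("CL%04d", .data$cluster_id),
      genome_proportion_pct = 100 * .data$genome_proportion,
      total_mbp = genome_proportion_to_mbp(.data$genome_proportion_pct,
                                           config$genome_size_mbp)
    ) |>
    dplyr::arrange(dplyr::desc(.data$profiled),
                   dplyr::desc(.data$enrichment)) |>
    dplyr::select("family_id", "cluster_id", "classification", "enrichment",
                  "genome_proportion_pct", "total_mbp", "monomer_length",
                  "at_content", "n_members", "chip_count", "input_count",
                  "tandem", "low_confidence", dplyr::everything())
}

qc_or_die <- function(reads, params, label) {
  out <- qc_reads(reads, params)
  if (nrow(out) == 0) {
    s <- qc_summary(out)
    stop(sprintf(paste0(
      "no %s reads survive QC (input %d, dropped short %d, ",
      "dropped quality %d)"),
      label, s$n_input, s$dropped_short, s$dropped_quality), call. = FALSE)
  }
  out
}

#' Approach A: enrichment of top-abundance reference clusters
#'
#' Clusters a random sample of reference reads by mutual similarity, keeps
#' the `top_n_clusters` with the highest genome representation, assigns each
#' QC'd ChIP/input read to a single cluster (best hit; ties to the cluster
#' with higher genome representation), computes per-cluster enrichment and
#' profiles every cluster with at least `min_cluster_reads` members.
#'
#' @param chip,input ChIP / input read sets: tibbles with `sequence` and
#'   `quality`, or FASTQ paths.
#' @param reference Reference read set: tibble, named character vector, or
#'   FASTA/FASTQ path.
#' @param config A [censat_config()].
#' @param retro_library Optional known-retroelement sequences for
#'   classification.
#' @return A `censat_run` object; see [tidy.censat_run()] for the family
#'   report.
#' @examples
#' \donttest{
#' fam <- dplyr::bind_rows(
#'   satellite_family("SAT-1", 50, 0.72, 2, 60, divergence = 0.02,
#'                    fold_enrichment = 40),
#'   satellite_family("SAT-2", 120, 0.68, 2, 25, divergence = 0.02))
#' g <- build_genome(fam, background_length = 150000, seed = 1)
#' refs <- simulate_reference_reads(g, 0.48, 100, seed = 2)
#' rs <- simulate_chip_and_input(g, 20000, 20000, seed = 3)
#' run <- run_approach_a(rs$chip, rs$input, refs, censat_config(seed = 4))
#' tidy(run)
#' }
#' @export
run_approach_a <- function(chip, input, reference,
                           config = censat_config(), retro_library = NULL) {
  chip_qc <- qc_or_die(chip, config$qc, "ChIP")
  input_qc <- qc_or_die(input, config$qc, "input")
  reference <- resolve_reads(reference, arg = "reference")

  n_sample <- min(config$reference_sample_size, nrow(reference))
  sample_refs <- with_seed(config$seed,
                           reference[sample.int(nrow(reference), n_sample), ])

  graph <- build_similarity_graph(sample_refs, config$similarity)
  clusters <- select_top_clusters(cluster_components(graph),
                                  config$top_n_clusters)

  index <- reference_index(sample_refs)
  asg_chip <- assign_with_index(chip_qc$sequence, index, clusters,
                                config$match)
  asg_input <- assign_with_index(input_qc$sequence, index, clusters,
                                 config$match)
  nc <- max(clusters$cluster_id)
  enr <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    chip_count = tabulate(asg_chip$cluster, nbins = nc)[clusters$cluster_id],
    input_count = tabulate(asg_input$cluster, nbins = nc)[clusters$cluster_id]
  )
  enr$enrichment <- compute_enrichment(
    enr$chip_count, nrow(chip_qc), enr$input_count, nrow(input_qc),
    zero_policy = config$zero_policy)

  seq_lookup <- stats::setNames(sample_refs$sequence, sample_refs$read_id)
  prof <- profile_clusters(clusters, function(ids) unname(seq_lookup[ids]),
                           retro_library, config$min_cluster_reads)
  report <- build_report(clusters, enr, prof, config)

  new_censat_run(
    approach = "A", report = report, clusters = clusters, enrichment = enr,
    config = config,
    qc = list(chip = qc_summary(chip_qc), input = qc_summary(input_qc)),
    mapping = tibble::tibble(
      set = c("chip", "input"),
      n_reads = c(nrow(chip_qc), nrow(input_qc)),
      n_mapped = c(sum(asg_chip$mapped), sum(asg_input$mapped)),
      n_assigned = c(sum(asg_chip$cluster > 0), sum(asg_input$cluster > 0))),
    selection = NULL, n_reference = nrow(reference))
}

#' Approach B: per-reference-read enrichment, then clustering
#'
#' Computes enrichment for every reference read (counts under the
#' `"count_all"` policy), selects reads at
#' `enrichment >= enrichment_threshold`, clusters only those by mutual
#' similarity, computes cluster-level enrichment from the aggregated member
#' counts, and profiles clusters with at least `min_cluster_reads` members.
#' Genome proportions stay relative to the full reference set.  This approach
#' recovers low-abundance enriched families that fall below approach A's
#' top-cluster cut.
#'
#' @inheritParams run_approach_a
#' @return A `censat_run` object; `$selection` holds the enriched-read count
#'   and percentage.
#' @examples
#' \donttest{
#' fam <- satellite_family("SAT-1", 50, 0.72, 2, 60, divergence = 0.02,
#'                         fold_enrichment = 40)
#' g <- build_genome(fam, background_length = 100000, seed = 1)
#' refs <- simulate_reference_reads(g, 0.48, 100, seed = 2)
#' rs <- simulate_chip_and_input(g, 20000, 20000, seed = 3)
#' run <- run_approach_b(rs$chip, rs$input, refs, censat_config(seed = 4))
#' glance(run)
#' }
#' @export
run_approach_b <- function(chip, input, reference,
                           config = censat_config(), retro_library = NULL) {
  chip_qc <- qc_or_die(chip, config$qc, "ChIP")
  input_qc <- qc_or_die(input, config$qc, "input")
  reference <- resolve_reads(reference, arg = "reference")

  index <- reference_index(reference)
  counts <- count_reference_hits(chip_qc, input_qc, index, config$match)
  counts$enrichment <- compute_enrichment(
    counts$chip_count, nrow(chip_qc), counts$input_count, nrow(input_qc),
    zero_policy = config$zero_policy)

  enriched <- select_enriched_reads(counts, config$enrichment_threshold)
  selection <- attr(enriched, "selection_summary")
  if (nrow(enriched) < 2) {
    clusters <- tibble::tibble(cluster_id = integer(), n_members = integer(),
                               genome_proportion = numeric(),
                               member_ids = list(), member_index = list())
  } else {
    enriched_reads <- reference[match(enriched$reference_id,
                                      reference$read_id), ]
    graph <- build_similarity_graph(enriched_reads, config$similarity)
    clusters <- cluster_components(graph, total_reads = nrow(reference))
  }

  count_lookup <- counts[match(unlist(clusters$member_ids),
                               counts$reference_id), ]
  grp <- rep(clusters$cluster_id, clusters$n_members)
  enr <- tibble::tibble(
    cluster_id = clusters$cluster_id,
    chip_count = as.numeric(tapply(count_lookup$chip_count, grp, sum)[
      as.character(clusters$cluster_id)]),
    input_count = as.numeric(tapply(count_lookup$input_count, grp, sum)[
      as.character(clusters$cluster_id)])
  )
  if (nrow(enr)) {
    enr$enrichment <- compute_enrichment(
      enr$chip_count, nrow(chip_qc), enr$input_count, nrow(input_qc),
      zero_policy = config$zero_policy)
  } else {
    enr$enrichment <- numeric()
  }

  seq_lookup <- stats::setNames(reference$sequence, reference$read_id)
  prof <- profile_clusters(clusters, function(ids) unname(seq_lookup[ids]),
                           retro_library, config$min_cluster_reads)
  report <- build_report(clusters, enr, prof, config)

  map_sum <- attr(counts, "mapping_summary")
  new_censat_run(
    approach = "B", report = report, clusters = clusters, enrichment = enr,
    config = config,
    qc = list(chip = qc_summary(chip_qc), input = qc_summary(input_qc)),
    mapping = dplyr::mutate(map_sum, n_assigned = NA_integer_),
    selection = selection, n_reference = nrow(reference),
    read_enrichment = counts)
}

new_censat_run <- function(...) {
  structure(list(...), class = "censat_run")
}

#' @export
print.censat_run <- function(x, ...) {
  cat(sprintf("<censat_run> approach %s: %d clusters\n",
              x$approach, nrow(x$report)))
  if (!is.null(x$selection)) {
    cat(sprintf("  enriched reference reads: %d of %d (%.2f%%)\n",
                x$selection$n_selected, x$selection$n_total,
                x$selection$percent))
  }
  shown <- dplyr::select(x$report, "family_id", "classification",
                         "enrichment", "genome_proportion_pct",
                         "monomer_length", "at_content", "n_members")
  print(shown, n = 15)
  invisible(x)
}

#' Tidy and glance methods for pipeline runs
#'
#' `tidy()` returns the per-family report (one row per cluster, mirroring the
#' published table structure: classification, enrichment, genome proportion
#' and Mbp, monomer size, AT content).  `glance()` returns a one-row summary
#' of the run.
#'
#' @param x A `censat_run`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.censat_run <- function(x, ...) x$report

#' @rdname tidy.censat_run
#' @export
glance.censat_run <- function(x, ...) {
  tibble::tibble(
    approach = x$approach,
    n_chip = x$qc$chip$n_kept,
    n_input = x$qc$input$n_kept,
    n_reference = x$n_reference,
    n_clusters = nrow(x$report),
    n_satellite = sum(x$report$classification == "satellite", na.rm = TRUE),
    n_ltr_retroelement = sum(x$report$classification == "ltr_retroelement",
                             na.rm = TRUE),
    n_enriched_reads = if (is.null(x$selection)) NA_integer_ else
      x$selection$n_selected,
    percent_enriched = if (is.null(x$selection)) NA_real_ else
      x$selection$percent
  )
}

#' Write pipeline outputs
#'
#' `write_family_report()` writes the per-family TSV;
#' `write_cluster_members()` the cluster membership TSV; `write_contigs()`
#' the representative contigs as FASTA; `write_run_log()` a plain-text
#' account of read bookkeeping.
#'
#' @param run A `censat_run`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_family_report <- function(run, path) {
  out <- dplyr::select(run$report, "family_id", "classification",
                       "enrichment", "genome_proportion_pct", "total_mbp",
                       "monomer_length", "at_content", "n_members",
                       "chip_count", "input_count")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_family_report
#' @export
write_cluster_members <- function(run, path) {
  members <- tidyr::unnest(
    dplyr::select(run$clusters, "cluster_id", "member_ids"), "member_ids")
  utils::write.table(members, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_family_report
#' @export
write_contigs <- function(run, path) {
  with_contig <- run$report[!is.na(run$report$contig), ]
  write_fasta(tibble::tibble(read_id = with_contig$family_id,
                             sequence = with_contig$contig), path)
  invisible(path)
}

#' @rdname write_family_report
#' @export
write_enrichment_histogram <- function(run, path) {
  records <- run$read_enrichment %||% run$enrichment
  h <- enrichment_summary(records)$histogram
  utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_family_report
#' @export
write_run_log <- function(run, path) {
  lines <- c(
    sprintf("approach: %s", run$approach),
    sprintf("chip: input=%d kept=%d dropped_short=%d dropped_quality=%d",
            run$qc$chip$n_input, run$qc$chip$n_kept,
            run$qc$chip$dropped_short, run$qc$chip$dropped_quality),
    sprintf("input: input=%d kept=%d dropped_short=%d dropped_quality=%d",
            run$qc$input$n_input, run$qc$input$n_kept,
            run$qc$input$dropped_short, run$qc$input$dropped_quality),
    sprintf("reference reads: %d", run$n_reference),
    sprintf("mapped: chip=%d input=%d",
            run$mapping$n_mapped[1], run$mapping$n_mapped[2]),
    if (!is.null(run$selection)) {
      sprintf("enriched reference reads: %d of %d (%.2f%%)",
              run$selection$n_selected, run$selection$n_total,
              run$selection$percent)
    },
    sprintf("clusters: %d", nrow(run$report))
  )
  writeLines(lines, path)
  invisible(path)
}
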