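#' Similarity parameters for read clustering
#'
#' Two reads are connected when a local alignment of one against the other
#' (either strand) reaches at least `min_identity` over a region covering at
#' least `min_overlap_fraction` of the shorter read.
#'
#' @param min_identity Minimum alignment identity, in `(0, 1]`.
#' @param min_overlap_fraction Minimum aligned fraction of the shorter read,
#'   in `(0, 1]`.
#' @param seed_length Exact k-mer length of the candidate-pair prefilter:
#'   only pairs sharing at least one canonical k-mer are aligned.
#' @return A `similarity_params` list.
#' @examples
#' similarity_params()
#' @export
similarity_params <- function(min_identity = 0.90,
                              min_overlap_fraction = 0.55,
                              seed_length = 13) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_overlap_fraction > 0, min_overlap_fraction <= 1,
            seed_length >= 6, seed_length <= 31)
  structure(list(min_identity = min_identity,
                 min_overlap_fraction = min_overlap_fraction,
                 seed_length = as.integer(seed_length)),
            class = "similarity_params")
}

#' @export
print.similarity_params <- function(x, ...) {
  cat(sprintf(
    "<similarity_params> >= %.0f%% identity over >= %.0f%% of shorter read\n",
    100 * x$min_identity, 100 * x$min_overlap_fraction))
  invisible(x)
}

#' Build the mutual-similarity graph over a read set
#'
#' Vertices are reads; an undirected edge joins two reads that satisfy the
#' [similarity_params()] criterion (checked by Smith-Waterman local alignment
#' on candidate pairs sharing a canonical k-mer).
#'
#' @param reads Tibble with `read_id`/`sequence`, character vector, or path.
#' @param params A [similarity_params()].
#' @return An igraph graph whose vertices carry `name` (read id).
#' @examples
#' g <- build_similarity_graph(c(a = strrep("ACGGT", 20),
#'                               b = strrep("ACGGT", 20),
#'                               c = strrep("TTACG", 20)))
#' igraph::ecount(g)
#' @export
build_similarity_graph <- function(reads, params = similarity_params()) {
  reads <- resolve_reads(reads)
  if (nrow(reads) < 2) {
    stop("need at least 2 reads to build a similarity graph", call. = FALSE)
  }
  edges <- cpp_similarity_edges(reads$sequence, params$min_identity,
                                params$min_overlap_fraction,
                                params$seed_length)
  g <- igraph::make_empty_graph(n = nrow(reads), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = reads$read_id)
  if (length(edges$from)) {
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  }
  g
}

#' Cluster reads into repeat families by connected components
#'
#' Connected components of the similarity graph, including singletons, sorted
#' by descending genome proportion (`n_members / total_reads`); ties are
#' broken by the smallest member vertex index, and `cluster_id` is assigned
#' in that order.
#'
#' @param graph Graph from [build_similarity_graph()].
#' @param total_reads Denominator of `genome_proportion`; defaults to the
#'   vertex count.  Pass the full reference-read count when clustering a
#'   subset (e.g. only enriched reads) so proportions stay genome-wide.
#' @return Tibble `cluster_id`, `n_members`, `genome_proportion`,
#'   `member_ids` (list of read ids), `member_index` (list of vertex
#'   indices).
#' @examples
#' g <- build_similarity_graph(c(a = strrep("ACGGT", 20),
#'                               b = strrep("ACGGT", 20),
#'                               c = strrep("TTACG", 20)))
#' cluster_components(g)
#' @export
cluster_components <- function(graph, total_reads = NULL) {
  comp <- igraph::components(graph)
  total <- total_reads %||% igraph::vcount(graph)
  ids <- igraph::V(graph)$name
  members <- split(seq_along(comp$membership), comp$membership)
  tbl <- tibble::tibble(
    n_members = unname(lengths(members)),
    member_index = unname(purrr::map(members, as.integer)),
    member_ids = unname(purrr::map(members, ~ ids[.x])),
    min_member = vapply(members, min, numeric(1))
  )
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$n_members), .data$min_member)
  tibble::tibble(
    cluster_id = seq_len(nrow(tbl)),
    n_members = tbl$n_members,
    genome_proportion = tbl$n_members / total,
    member_ids = tbl$member_ids,
    member_index = tbl$member_index
  )
}

#' Keep the clusters with the highest genome representation
#'
#' @param clusters Tibble from [cluster_components()] (already sorted).
#' @param n Number of clusters to keep (default 1000).
#' @return The first `min(n, nrow(clusters))` rows.
#' @examples
#' g <- build_similarity_graph(c(a = strrep("ACGGT", 20),
#'                               b = strrep("ACGGT", 20),
#'                               c = strrep("TTACG", 20)))
#' select_top_clusters(cluster_components(g), n = 1)
#' @export
select_top_clusters <- function(clusters, n = 1000) {
  dplyr::slice_head(clusters, n = n)
}

#' Assign queries to a single cluster from their match hits
#'
#' Each query is assigned to exactly one cluster: the cluster of its best hit
#' (fewest differences, then fewest indel bases).  When equally good hits
#' fall in more than one cluster, the cluster with the higher genome
#' proportion wins; remaining ties go to the lower `cluster_id`.  Queries
#' whose best hits all fall outside the given clusters, or with no hits, are
#' unassigned (`NA`).
#'
#' @param hits Tibble from [match_reads()] (any number of queries).
#' @param clusters Tibble from [cluster_components()] /
#'   [select_top_clusters()].
#' @return Tibble `query_id`, `cluster_id` (NA when unassigned), one row per
#'   distinct query in `hits`.
#' @examples
#' hits <- tibble::tibble(query_id = "q", reference_id = c("a", "c"),
#'                        strand = "+", n_differences = c(0L, 0L),
#'                        indel_bases = 0L)
#' cl <- tibble::tibble(cluster_id = 1:2, n_members = c(2L, 1L),
#'                      genome_proportion = c(2, 1) / 3,
#'                      member_ids = list(c("a", "b"), "c"))
#' assign_read_to_cluster(hits, cl)
#' @export
assign_read_to_cluster <- function(hits, clusters) {
  membership <- tidyr::unnest(
    dplyr::select(clusters, "cluster_id", "genome_proportion", "member_ids"),
    "member_ids")
  ranked <- hits |>
    dplyr::left_join(membership,
                     by = c(reference_id = "member_ids")) |>
    dplyr::group_by(.data$query_id) |>
    dplyr::filter(.data$n_differences == min(.data$n_differences)) |>
    dplyr::filter(.data$indel_bases == min(.data$indel_bases)) |>
    dplyr::arrange(dplyr::desc(.data$genome_proportion), .data$cluster_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = 1) |>
    dplyr::ungroup()
  tibble::tibble(query_id = ranked$query_id, cluster_id = ranked$cluster_id)
}

# Fast path used by the pipeline: assign every query via the compiled
# matcher.  Returns an integer cluster id per query (0 = unassigned).
assign_with_index <- function(queries, index, clusters, params) {
  ref_cluster <- integer(index$n)
  for (i in seq_len(nrow(clusters))) {
    ref_cluster[match(clusters$member_ids[[i]], index$read_id)] <-
      clusters$cluster_id[i]
  }
  prop <- numeric(max(clusters$cluster_id, 1))
  prop[clusters$cluster_id] <- clusters$genome_proportion
  res <- cpp_match_query(index$ptr, queries, params$max_differences,
                         params$max_total_indel_bases,
                         params$search_both_strands, "assign",
                         ref_cluster, prop, "count_all")
  list(cluster = res$cluster, mapped = res$mapped)
}
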