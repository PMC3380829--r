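test_that("clusters partition the reads", {
  set.seed(51)
  mono_a <- random_dna_str(50)
  mono_b <- random_dna_str(50)
  reads <- c(tandem_reads(mono_a, 20, seed = 52),
             stats::setNames(tandem_reads(mono_b, 20, seed = 53),
                             sprintf("u%03d", 1:20)),
             stats::setNames(vapply(1:10, function(i) random_dna_str(100),
                                    ""), sprintf("bg%02d", 1:10)))
  g <- build_similarity_graph(reads)
  cl <- cluster_components(g)
  expect_equal(sum(cl$n_members), length(reads))
  all_members <- unlist(cl$member_ids)
  expect_setequal(all_members, names(reads))
  expect_equal(anyDuplicated(all_members), 0L)
  # proportions sum to 1 when total defaults to the vertex count
  expect_equal(sum(cl$genome_proportion), 1)
})

test_that("same-family reads cluster together, families stay apart", {
  set.seed(54)
  mono_a <- random_dna_str(50)
  mono_b <- random_dna_str(50)
  reads <- c(tandem_reads(mono_a, 25, seed = 55),
             stats::setNames(tandem_reads(mono_b, 15, seed = 56),
                             sprintf("u%03d", 1:15)))
  cl <- cluster_components(build_similarity_graph(reads))
  expect_equal(cl$n_members[1:2], c(25L, 15L))
  expect_true(all(startsWith(cl$member_ids[[1]], "t")))
  expect_true(all(startsWith(cl$member_ids[[2]], "u")))
})

test_that("clustering is invariant to read order", {
  set.seed(57)
  mono <- random_dna_str(60)
  reads <- c(tandem_reads(mono, 12, seed = 58),
             stats::setNames(vapply(1:8, function(i) random_dna_str(100),
                                    ""), sprintf("bg%02d", 1:8)))
  cl1 <- cluster_components(build_similarity_graph(reads))
  perm <- censat:::with_seed(59, sample(length(reads)))
  cl2 <- cluster_components(build_similarity_graph(reads[perm]))
  sets1 <- lapply(cl1$member_ids, sort)
  sets2 <- lapply(cl2$member_ids, sort)
  expect_setequal(sets1, sets2)
  expect_equal(cl1$n_members, cl2$n_members)
})

test_that("genome proportion uses the supplied total", {
  reads <- c(a = strrep("ACGGT", 20), b = strrep("ACGGT", 20),
             c = strrep("TGCAA", 20))
  cl <- cluster_components(build_similarity_graph(reads), total_reads = 100)
  expect_equal(cl$genome_proportion, cl$n_members / 100)
})

test_that("the similarity criterion respects identity and overlap floors", {
  base <- random_dna_str(100)
  # identical reads connect
  g <- build_similarity_graph(c(a = base, b = base))
  expect_equal(igraph::ecount(g), 1)
  # a read pair overlapping by less than 55% of the shorter must not connect
  short <- substr(base, 1, 60)                   # 60-nt read
  far <- paste0(substr(base, 41, 100), random_dna_str(40))
  # overlap region 41..60 = 20 nt = 33% of the 60-nt read
  g2 <- build_similarity_graph(c(a = short, b = far))
  expect_equal(igraph::ecount(g2), 0)
  # reverse-complement similarity counts
  g3 <- build_similarity_graph(c(a = base, b = censat:::str_revcomp(base)))
  expect_equal(igraph::ecount(g3), 1)
})

test_that("select_top_clusters keeps the highest-proportion clusters", {
  cl <- tibble::tibble(cluster_id = 1:5, n_members = c(9L, 7L, 3L, 2L, 1L),
                       genome_proportion = c(9, 7, 3, 2, 1) / 22,
                       member_ids = as.list(letters[1:5]),
                       member_index = as.list(1:5))
  top <- select_top_clusters(cl, n = 3)
  expect_equal(top$cluster_id, 1:3)
  expect_equal(nrow(select_top_clusters(cl, n = 10)), 5)
})

test_that("reads are assigned to their best cluster with proportion ties", {
  hits <- tibble::tibble(
    query_id = c("q1", "q1", "q2", "q2", "q3"),
    reference_id = c("a", "c", "b", "c", "zz"),
    strand = "+",
    n_differences = c(1L, 0L, 1L, 1L, 0L),
    indel_bases = 0L)
  cl <- tibble::tibble(cluster_id = 1:2, n_members = c(2L, 1L),
                       genome_proportion = c(2, 1) / 3,
                       member_ids = list(c("a", "b"), "c"))
  asg <- assign_read_to_cluster(hits, cl)
  # q1: best hit (0 diffs) is in cluster 2
  expect_equal(asg$cluster_id[asg$query_id == "q1"], 2L)
  # q2: tie across clusters 1 and 2 -> higher proportion wins
  expect_equal(asg$cluster_id[asg$query_id == "q2"], 1L)
  # q3: hits only an unclustered reference -> unassigned
  expect_true(is.na(asg$cluster_id[asg$query_id == "q3"]))
})

test_that("the fast pipeline assignment matches the tibble version", {
  fx <- medium_fixture()
  refs <- fx$reference[1:800, ]
  idx <- reference_index(refs)
  clusters <- cluster_components(build_similarity_graph(refs))
  queries <- qc_reads(fx$chip[1:400, ])
  fast <- censat:::assign_with_index(queries$sequence, idx, clusters,
                                     match_params())
  hits <- match_reads(stats::setNames(queries$sequence, queries$read_id),
                      idx)
  slow <- assign_read_to_cluster(hits, clusters)
  slow_vec <- rep(0L, nrow(queries))
  slow_vec[match(slow$query_id, queries$read_id)] <-
    dplyr::coalesce(slow$cluster_id, 0L)
  expect_equal(fast$cluster, slow_vec)
})

test_that("a two-read minimum is enforced", {
  expect_error(build_similarity_graph(c(a = strrep("ACGT", 25))), "2")
})
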