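test_that("network construction dedupes, infers roles and logs self-loops", {
  edges <- data.frame(tf_id = c("a", "a", "a", "b", "c"),
                      target_id = c("b", "b", "c", "c", "c"))
  net <- build_network(edges)
  expect_equal(igraph::ecount(net), 3)  # a->b deduped, c->c dropped
  roles <- setNames(igraph::V(net)$role, igraph::V(net)$name)
  expect_identical(roles[["a"]], "TF")
  expect_identical(roles[["b"]], "both")
  expect_identical(roles[["c"]], "target")
  expect_equal(nrow(attr(net, "dropped")), 1)
})

test_that("degree profile matches the generator ledger", {
  sim <- simulate_trn(sim_config(seed = 8, n_tf = 60, n_target = 400))
  net <- build_network(sim$edges)
  expect_equal(igraph::ecount(net), nrow(sim$edges))
  prof <- degree_profile(net)
  tf <- prof[prof$role == "TF", ]
  expect_equal(setNames(tf$k, tf$node_id),
               sim$truth$tf_degree[tf$node_id])
  expect_equal(sum(tf$k), nrow(sim$edges))
  tg <- prof[prof$role == "target", ]
  expect_equal(setNames(tg$k, tg$node_id),
               sim$truth$target_in_degree[tg$node_id])
})

test_that("hub classification is strict at the 80th percentile", {
  expect_identical(which(classify_hubs(1:10)), c(9L, 10L))
  expect_warning(h <- classify_hubs(c(5, 5, 5, 5, 1)), "threshold")
  expect_false(any(h))
  # a class whose 80th percentile is exactly 44: k=45 is a hub, k=44 is not
  k <- c(rep(5, 15), 44, 44, 45, 50, 60)
  expect_equal(unname(quantile(k, 0.8)), 44)
  h <- classify_hubs(k)
  expect_identical(sort(k[h]), c(45, 50, 60))
  expect_error(classify_hubs(1:3), "at least 5")
})

test_that("hub sets never exceed the nominal fraction", {
  withr::with_seed(42, {
    for (i in 1:50) {
      k <- sample(1:30, sample(5:60, 1), replace = TRUE)
      h <- suppressWarnings(classify_hubs(k))
      expect_lte(sum(h), ceiling(0.2 * length(k)))
    }
  })
})

test_that("betweenness matches simple geometries after rescaling", {
  path3 <- build_network(data.frame(tf = c("a", "b"), tg = c("b", "c")))
  b <- betweenness_centrality(path3)
  expect_equal(b[["b"]], 1)
  expect_equal(b[["a"]], 0)
  expect_equal(b[["c"]], 0)
  expect_equal(betweenness_centrality(path3, rescale = FALSE)[["b"]], 1)
  star <- build_network(data.frame(tf = "hub", tg = paste0("t", 1:6)))
  expect_true(all(betweenness_centrality(star) == 0))
})

test_that("betweenness equals the exhaustive path-enumeration oracle", {
  withr::with_seed(7, {
    for (i in 1:30) {
      n <- sample(3:6, 1)
      rd <- random_digraph(n)
      raw <- betweenness_centrality(rd$g, rescale = FALSE)
      expect_equal(unname(raw), brute_betweenness(rd$adj), tolerance = 1e-12)
    }
  })
})

test_that("eigenvector centrality matches a dense eigendecomposition", {
  # complete graph: perfect symmetry
  cg <- igraph::make_full_graph(5, directed = TRUE)
  igraph::V(cg)$name <- letters[1:5]
  expect_equal(unname(eigenvector_centrality(cg)), rep(1, 5))
  # path: center dominates
  path3 <- build_network(data.frame(tf = c("a", "b"), tg = c("b", "c")))
  e <- eigenvector_centrality(path3)
  expect_equal(names(which.max(e)), "b")
  # 4-node toy vs dense oracle
  adj <- matrix(c(0, 1, 1, 0,
                  0, 0, 1, 0,
                  0, 0, 0, 1,
                  1, 0, 0, 0), 4, 4, byrow = TRUE)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::V(g)$name <- as.character(1:4)
  expect_equal(unname(eigenvector_centrality(g)), eigen_centrality_oracle(adj),
               tolerance = 1e-8)
})

test_that("probe mapping enforces the perfect-unique-match rule", {
  transcripts <- Biostrings::DNAStringSet(c(
    geneA = "ATGCATGCATGCATGCAAATTTCCC",
    geneB = "TTTTGGGGCCCCAAAATTTTGGGG",
    geneC = "ATGCATGCATGCATGCAAATTTCCC"))  # duplicate of geneA
  probes <- Biostrings::DNAStringSet(c(
    p_unique = "GGGGCCCCAAAA",
    p_revcomp = as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("TTTTGGGGCCCC"))),
    p_mismatch = "GGGGCCCCTAAA",
    p_ambig = "ATGCATGCATGC"))
  res <- map_probes(probes, transcripts)
  expect_identical(res$status[res$probe_id == "p_unique"], "assigned")
  expect_identical(res$gene_id[res$probe_id == "p_unique"], "geneB")
  expect_identical(res$status[res$probe_id == "p_revcomp"], "assigned")
  expect_identical(res$status[res$probe_id == "p_mismatch"], "unmatched")
  expect_identical(res$status[res$probe_id == "p_ambig"], "ambiguous")
  # order independence and idempotence
  res2 <- map_probes(rev(probes), transcripts)
  m <- merge(res, res2, by = "probe_id")
  expect_identical(m$status.x, m$status.y)
  expect_error(map_probes(c(p = "ACGX"), transcripts), "non-nucleotide")
})

test_that("node metrics combine degrees, hubs and centralities", {
  sim <- simulate_trn(sim_config(seed = 9, n_tf = 40, n_target = 200))
  net <- build_network(sim$edges)
  m <- node_metrics(net)
  expect_true(all(m$betweenness >= 0 & m$betweenness <= 1))
  expect_true(all(m$eigenvector >= 0 & m$eigenvector <= 1))
  tf <- m[m$role == "TF", ]
  expect_lte(sum(tf$hub), ceiling(0.2 * nrow(tf)))
})
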