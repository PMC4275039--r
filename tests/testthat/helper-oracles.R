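# Independent oracles used across the suite. These deliberately use naive
# exhaustive algorithms so they share no code path with the package.

# Exhaustive betweenness: enumerate every simple path between every ordered
# pair of an adjacency matrix, keep the shortest ones, and accumulate the
# fraction passing through each intermediate vertex.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  score <- numeric(n)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        return()
      }
      for (w in which(adj[v, ] == 1)) {
        if (!(w %in% path)) walk(c(path, w))
      }
    }
    walk(s)
    paths
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      score[inner] <- score[inner] + 1 / length(shortest)
    }
  }
  score
}

# Exact Wilcoxon rank-sum p by full enumeration of the choose(nx+ny, nx)
# group assignments (untied data only). Mirrors the usual exact two-sided
# doubling convention.
wilcox_enum_p <- function(x, y, alternative = "less") {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  idx <- utils::combn(nx + ny, nx)
  u_all <- apply(idx, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  switch(alternative,
         less = mean(u_all <= u_obs),
         greater = mean(u_all >= u_obs),
         two_sided = {
           p <- if (u_obs > nx * ny / 2) 2 * mean(u_all >= u_obs)
                else 2 * mean(u_all <= u_obs)
           min(p, 1)
         })
}

# Dense-eigendecomposition oracle for eigenvector centrality of the
# symmetrized adjacency, normalized to max 1.
eigen_centrality_oracle <- function(adj) {
  sym <- pmax(adj, t(adj))
  ev <- eigen(sym, symmetric = TRUE)
  v <- abs(ev$vectors[, which.max(ev$values)])
  v / max(v)
}

# random small digraph as an igraph + adjacency pair
random_digraph <- function(n, p = 0.4) {
  adj <- matrix(rbinom(n * n, 1, p), n, n)
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  igraph::V(g)$name <- as.character(seq_len(n))
  list(g = g, adj = adj)
}

# Mirror a genome fixture: reverse-complement the chromosome, flip strands
# and coordinates, complement alleles. Counts must be invariant under this.
mirror_fixture <- function(fx) {
  L <- Biostrings::width(fx$genome)[1]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  genome <- Biostrings::reverseComplement(fx$genome)
  models <- fx$models
  models$genes$strand <- ifelse(models$genes$strand == "+", "-", "+")
  new_start <- L + 1 - models$cds$end
  new_end <- L + 1 - models$cds$start
  models$cds$start <- new_start
  models$cds$end <- new_end
  models <- gene_models(models$genes, models$cds)
  variants <- fx$variants
  variants$pos <- L + 1 - variants$pos
  variants$ref <- unname(comp[variants$ref])
  variants$alt <- unname(comp[variants$alt])
  list(models = models, genome = genome, variants = variants)
}
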