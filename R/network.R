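# Directed TRN construction and node-level topology metrics. The graph
# container and the centrality algorithms are igraph's; this layer fixes the
# conventions used throughout the analysis (roles, strict hub thresholds,
# min-max rescaled betweenness, symmetrized eigenvector centrality).

#' Build a directed TF-to-target network from an edge list
#'
#' Duplicate edge rows are collapsed and self-loops are rejected (logged in
#' the `dropped` attribute). Node roles are inferred from the edge list:
#' source-only nodes are `TF`, sink-only nodes are `target`, nodes appearing
#' on both sides are `both`.
#'
#' @param edges two-column data.frame (`tf_id`, `target_id`) or a path to a
#'   two-column TSV.
#' @param allow_self_loops keep self-regulation edges instead of dropping
#'   them.
#' @return an `igraph` directed graph with a vertex attribute `role`.
#' @examples
#' net <- build_network(data.frame(tf_id = c("a", "a"), target_id = c("b", "c")))
#' igraph::V(net)$role
#' @export
build_network <- function(edges, allow_self_loops = FALSE) {
  if (is.character(edges)) {
    edges <- read.delim(edges, stringsAsFactors = FALSE)
  }
  if (ncol(edges) < 2) stop_input("edge list needs two columns")
  el <- data.frame(from = as.character(edges[[1]]),
                   to = as.character(edges[[2]]), stringsAsFactors = FALSE)
  if (anyNA(el)) stop_input("missing node identifiers in edge list")
  loops <- el$from == el$to
  dropped <- el[loops & !allow_self_loops, , drop = FALSE]
  if (!allow_self_loops) el <- el[!loops, , drop = FALSE]
  el <- unique(el)
  g <- igraph::graph_from_data_frame(el, directed = TRUE)
  out_deg <- igraph::degree(g, mode = "out")
  in_deg <- igraph::degree(g, mode = "in")
  role <- ifelse(out_deg > 0 & in_deg > 0, "both",
                 ifelse(out_deg > 0, "TF", "target"))
  igraph::V(g)$role <- role
  attr(g, "dropped") <- dropped
  g
}

#' Connectedness (k) per node
#'
#' Connectedness follows the role convention: out-degree for TFs, in-degree
#' for targets; nodes acting as both report both.
#'
#' @param net a directed graph from [build_network()].
#' @return data.frame with `node_id`, `role`, `k_out`, `k_in` and the
#'   role-appropriate `k` (for `both` nodes, `k` is the out-degree, the
#'   regulatory fan-out).
#' @export
degree_profile <- function(net) {
  stopifnot(inherits(net, "igraph"))
  role <- igraph::V(net)$role
  k_out <- igraph::degree(net, mode = "out")
  k_in <- igraph::degree(net, mode = "in")
  data.frame(node_id = igraph::V(net)$name, role = role,
             k_out = as.integer(k_out), k_in = as.integer(k_in),
             k = as.integer(ifelse(role == "target", k_in, k_out)),
             stringsAsFactors = FALSE)
}

#' Flag hub nodes by connectedness
#'
#' A node is a hub when its connectedness strictly exceeds the empirical
#' `1 - fraction` quantile of its class, so ties at the threshold are never
#' hubs and the hub set never exceeds the nominal fraction. With the default
#' 0.20, this is the "top 20% most connected" rule.
#'
#' @param k_values named or unnamed numeric vector of connectedness values
#'   for one role class.
#' @param fraction nominal hub fraction (default 0.20).
#' @return logical vector parallel to `k_values`.
#' @examples
#' classify_hubs(1:10)  # the top two
#' @export
classify_hubs <- function(k_values, fraction = 0.20) {
  if (length(k_values) < 5) stop_input("need at least 5 nodes in the class")
  stopifnot(fraction > 0, fraction < 1)
  thr <- as.numeric(quantile(k_values, 1 - fraction))
  hubs <- k_values > thr
  if (!any(hubs)) warning("no node exceeds the hub threshold (ties or constant k)")
  hubs
}

#' Betweenness centrality, min-max rescaled to [0, 1]
#'
#' Brandes' algorithm over directed unweighted shortest paths (via igraph),
#' followed by a min-max rescaling so the most central node scores 1 and the
#' least central 0. If all raw scores are equal (e.g. a star graph, which has
#' no through-paths), all rescaled scores are 0.
#'
#' @param net a directed graph from [build_network()].
#' @param directed use directed shortest paths (default) or the undirected
#'   view.
#' @param rescale apply the min-max rescaling; `FALSE` returns raw path
#'   counts.
#' @return named numeric vector of scores.
#' @export
betweenness_centrality <- function(net, directed = TRUE, rescale = TRUE) {
  stopifnot(inherits(net, "igraph"))
  raw <- igraph::betweenness(net, directed = directed, weights = NA)
  if (!rescale) return(raw)
  rng <- range(raw)
  if (diff(rng) == 0) return(setNames(rep(0, length(raw)), names(raw)))
  (raw - rng[1]) / diff(rng)
}

#' Eigenvector centrality on the symmetrized network
#'
#' Computed on the undirected view of the graph (edge directions collapsed)
#' and normalized so the maximum score is 1. On a near-bipartite directed
#' TRN the strictly directed variant degenerates (sources receive no
#' support), so the symmetrized view is the meaningful one.
#'
#' @param net a directed graph from [build_network()].
#' @return named numeric vector of scores in [0, 1].
#' @export
eigenvector_centrality <- function(net) {
  stopifnot(inherits(net, "igraph"))
  und <- igraph::as_undirected(net, mode = "collapse")
  res <- igraph::eigen_centrality(und)  # scores scaled to max 1
  setNames(res$vector, igraph::V(net)$name)
}

#' Per-node topology metrics table
#'
#' Combines connectedness, hub flags (per role class), rescaled betweenness
#' and eigenvector centrality into one table.
#'
#' @param net a directed graph from [build_network()].
#' @param hub_fraction nominal hub fraction passed to [classify_hubs()].
#' @return data.frame with node_id, role, k_out, k_in, k, hub, betweenness,
#'   eigenvector.
#' @export
node_metrics <- function(net, hub_fraction = 0.20) {
  prof <- degree_profile(net)
  prof$hub <- NA
  for (r in unique(prof$role)) {
    idx <- prof$role == r
    if (sum(idx) >= 5) prof$hub[idx] <- classify_hubs(prof$k[idx], hub_fraction)
  }
  btw <- betweenness_centrality(net)
  eig <- eigenvector_centrality(net)
  prof$betweenness <- as.numeric(btw[prof$node_id])
  prof$eigenvector <- as.numeric(eig[prof$node_id])
  prof
}

#' Map microarray probes to genes by perfect sequence match
#'
#' Each probe (and its reverse complement) is searched as an exact substring
#' of every transcript; probes matching transcripts of exactly one gene are
#' assigned, probes with zero or several matching genes are dropped with a
#' logged reason. This reproduces a strict perfect-match remapping of array
#' probes onto a reference gene set.
#'
#' @param probes named `Biostrings::DNAStringSet` (or named character vector)
#'   of probe sequences.
#' @param transcripts named `DNAStringSet` of transcript sequences; names are
#'   gene identifiers (several transcripts may share a gene).
#' @return data.frame with `probe_id`, `gene_id` (NA when unassigned),
#'   `n_genes` matched and `status` in assigned/unmatched/ambiguous.
#' @export
map_probes <- function(probes, transcripts) {
  probes <- as_dna_set(probes, "probes")
  transcripts <- as_dna_set(transcripts, "transcripts")
  if (length(probes) == 0 || length(transcripts) == 0) {
    stop_input("need non-empty probe and transcript sets")
  }
  genes <- names(transcripts)
  res <- lapply(seq_along(probes), function(i) {
    p <- probes[[i]]
    fwd <- Biostrings::vcountPattern(p, transcripts) > 0
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(p),
                                     transcripts) > 0
    hit_genes <- unique(genes[fwd | rev])
    n <- length(hit_genes)
    data.frame(probe_id = names(probes)[i],
               gene_id = if (n == 1) hit_genes else NA_character_,
               n_genes = n,
               status = if (n == 1) "assigned" else if (n == 0) "unmatched" else "ambiguous",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

as_dna_set <- function(x, what) {
  if (is.character(x)) {
    if (grepl("[^ACGTNacgtn]", paste(x, collapse = ""))) {
      stop_input("non-nucleotide characters in ", what)
    }
    x <- Biostrings::DNAStringSet(x)
  }
  if (!methods::is(x, "DNAStringSet")) {
    stop_input(what, " must be a DNAStringSet or character vector")
  }
  if (is.null(names(x))) names(x) <- paste0(what, seq_along(x))
  x
}

#' Write node metrics as TSV
#' @param metrics data.frame from [node_metrics()].
#' @param path file path.
#' @export
write_node_metrics <- function(metrics, path) {
  write.table(metrics, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
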