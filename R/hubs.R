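#' Extract a module's weighted subnetwork
#'
#' Nodes are the module's genes; edges are adjacency entries strictly above
#' `weight_cutoff`. Isolated nodes are retained so centralities and ranks
#' cover the whole module.
#'
#' @param adj Adjacency matrix (as from [soft_adjacency()]).
#' @param labels Named gene -> module labels.
#' @param module Module id to extract.
#' @param weight_cutoff Minimum retained edge weight (default 0.4).
#' @return An undirected weighted `igraph` graph.
#' @export
extract_subnetwork <- function(adj, labels, module, weight_cutoff = 0.4) {
  genes <- names(labels)[labels == module]
  if (length(genes) == 0) stop("module is empty: ", module, call. = FALSE)
  a <- adj[genes, genes, drop = FALSE]
  a[a <= weight_cutoff] <- 0
  diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  g
}

#' Five node centralities of a weighted graph
#'
#' Degree is the weighted degree (strength); betweenness and closeness use
#' edge distances `1/weight`; closeness is the harmonic variant so
#' disconnected graphs are handled; eigenvector centrality is the principal
#' eigenvector of the weight matrix; PageRank uses damping 0.85 on the
#' weights.
#'
#' @param g An undirected weighted `igraph` graph.
#' @return Data frame, one row per node: `gene`, `degree`, `betweenness`,
#'   `closeness`, `eigenvector`, `pagerank`.
#' @export
centralities <- function(g) {
  nv <- igraph::vcount(g)
  if (nv < 2) {
    warning("graph has fewer than 2 nodes; returning zeros")
    return(data.frame(gene = igraph::V(g)$name, degree = 0, betweenness = 0,
                      closeness = 0, eigenvector = 0, pagerank = 0,
                      stringsAsFactors = FALSE))
  }
  w <- igraph::E(g)$weight
  dist_w <- if (length(w)) 1 / w else numeric(0)
  data.frame(
    gene = igraph::V(g)$name,
    degree = igraph::strength(g),
    betweenness = igraph::betweenness(g, weights = dist_w, directed = FALSE),
    closeness = igraph::harmonic_centrality(g, weights = dist_w,
                                            normalized = TRUE),
    eigenvector = igraph::eigen_centrality(g, weights = w)$vector,
    pagerank = igraph::page_rank(g, weights = w, damping = 0.85)$vector,
    stringsAsFactors = FALSE, row.names = NULL)
}

# descending ranks with average ties; stable on gene order
.desc_rank <- function(x) rank(-x, ties.method = "average")

#' Robust rank aggregation of centrality ranks
#'
#' For each gene the K normalized ranks `r = rank / n` are sorted and the
#' order-statistic p-values `p_k = P(Beta(k, K - k + 1) <= r_(k))`
#' (equivalently the binomial tail `P(Bin(K, r_(k)) >= k)`) computed; the
#' rho score is their minimum, corrected to `score = min(K * rho, 1)` for the
#' minimum over K order statistics, and a gene is a hub when the
#' Bonferroni-adjusted score across the n genes falls below `alpha`.
#'
#' @param rank_lists Either a list of K numeric rank vectors over the same
#'   genes (1 = most central) or a centrality data frame from
#'   [centralities()] (ranks are derived per measure, ties averaged).
#' @param alpha Hub-calling cutoff on the Bonferroni-adjusted score
#'   (default 0.05).
#' @return Data frame of class `HubReport`: `gene`, per-list ranks, `rho`,
#'   `score`, `padj`, `hub`; sorted by `rho`.
#' @export
rra_aggregate <- function(rank_lists, alpha = 0.05) {
  if (is.data.frame(rank_lists)) {
    genes <- rank_lists$gene
    measures <- setdiff(names(rank_lists), "gene")
    rank_lists <- lapply(rank_lists[measures], .desc_rank)
    for (m in measures) names(rank_lists[[m]]) <- genes
  }
  genes <- names(rank_lists[[1]])
  if (is.null(genes)) genes <- as.character(seq_along(rank_lists[[1]]))
  for (l in rank_lists) {
    if (length(l) != length(genes) ||
        (!is.null(names(l)) && !setequal(names(l), genes)))
      stop("all rank lists must cover the same gene set", call. = FALSE)
  }
  K <- length(rank_lists)
  n <- length(genes)
  R <- vapply(rank_lists, function(l)
    as.numeric(if (is.null(names(l))) l else l[genes]) / n, numeric(n))
  if (is.null(dim(R))) R <- matrix(R, nrow = n)
  rho <- numeric(n)
  for (i in seq_len(n)) {
    r <- sort(R[i, ])
    pk <- stats::pbeta(r, seq_len(K), K - seq_len(K) + 1)
    rho[i] <- min(pk)
  }
  score <- pmin(K * rho, 1)
  padj <- pmin(n * score, 1)
  out <- data.frame(gene = genes, R * n, rho = rho, score = score,
                    padj = padj, hub = padj < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[2:(K + 1)] <- if (!is.null(names(rank_lists)) &&
                                all(nzchar(names(rank_lists))))
    paste0("rank_", names(rank_lists)) else paste0("rank_", seq_len(K))
  out[order(out$rho, out$gene), , drop = FALSE]
}

#' Call hub genes of a module
#'
#' Convenience wrapper: extract the module subnetwork, compute the five
#' centralities, and aggregate their ranks by robust rank aggregation.
#'
#' @inheritParams extract_subnetwork
#' @inheritParams rra_aggregate
#' @return A `HubReport` data frame (see [rra_aggregate()]).
#' @export
module_hubs <- function(adj, labels, module, weight_cutoff = 0.4,
                        alpha = 0.05) {
  g <- extract_subnetwork(adj, labels, module, weight_cutoff)
  rra_aggregate(centralities(g), alpha = alpha)
}
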