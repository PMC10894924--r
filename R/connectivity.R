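# ES of `hit` (logical over the already-sorted reference) given the sorted
# scores; weighted: hit increments proportional to |score|^p.
.ks_es <- function(sorted_scores, hit, weighted, weight_power) {
  n <- length(hit); t <- sum(hit)
  inc_hit <- if (weighted) {
    w <- abs(sorted_scores[hit])^weight_power
    s <- sum(w)
    if (s == 0) rep(1 / t, t) else w / s
  } else rep(1 / t, t)
  running <- numeric(n)
  running[hit] <- inc_hit
  running[!hit] <- -1 / (n - t)
  running <- cumsum(running)
  running[which.max(abs(running))]
}

#' Weighted bidirectional K-S enrichment score
#'
#' Walks the reference ranking in decreasing score order; positions in
#' `gene_set` increment the running sum by `|score|^weight_power`
#' (normalized over the set) in weighted mode or by `1/t` otherwise, all
#' other positions decrement by `1/(n - t)`. The enrichment score is the
#' signed maximal deviation of the running sum, in `[-1, 1]`.
#'
#' @param reference Named numeric vector of per-gene scores (any order).
#' @param gene_set Character vector; must intersect the reference.
#' @param weighted Use score-weighted hit increments (default `TRUE`).
#' @param weight_power Exponent on `|score|` (default 1).
#' @return Enrichment score in `[-1, 1]`.
#' @export
ks_enrichment <- function(reference, gene_set, weighted = TRUE,
                          weight_power = 1) {
  gene_set <- intersect(gene_set, names(reference))
  if (length(gene_set) == 0)
    stop("gene_set does not intersect the reference", call. = FALSE)
  if (length(gene_set) == length(reference))
    stop("gene_set covers the whole reference", call. = FALSE)
  ord <- order(reference, decreasing = TRUE)
  sorted <- reference[ord]
  hit <- names(sorted) %in% gene_set
  .ks_es(sorted, hit, weighted, weight_power)
}

#' Bidirectional connectivity score
#'
#' Combines the enrichment of an up- and a down-query set in a drug-induced
#' ranking: when the two enrichment scores have the same sign the query is
#' not coherently mimicked or reversed and the score is 0, otherwise
#' `score = (ES_up - ES_down) / 2`. A positive score means the drug signature
#' mimics the query response; a negative one that it opposes it. With a
#' one-directional query the score keeps that convention:
#' `ES_up` for an up-only query, `-ES_down` for a down-only query.
#'
#' @param query_up,query_down Disjoint character vectors (one may be empty).
#' @param drug_signature Named numeric vector of the drug's per-gene scores.
#' @param weighted,weight_power Passed to [ks_enrichment()].
#' @return Connectivity score in `[-1, 1]`.
#' @export
connectivity_score <- function(query_up, query_down, drug_signature,
                               weighted = TRUE, weight_power = 1) {
  if (length(intersect(query_up, query_down)))
    stop("query_up and query_down must be disjoint", call. = FALSE)
  has_up <- length(intersect(query_up, names(drug_signature))) > 0
  has_down <- length(intersect(query_down, names(drug_signature))) > 0
  if (!has_up && !has_down) stop("both query sets are empty", call. = FALSE)
  if (has_up && !has_down)
    return(ks_enrichment(drug_signature, query_up, weighted, weight_power))
  if (!has_up && has_down)
    return(-ks_enrichment(drug_signature, query_down, weighted, weight_power))
  es_up <- ks_enrichment(drug_signature, query_up, weighted, weight_power)
  es_down <- ks_enrichment(drug_signature, query_down, weighted, weight_power)
  if (sign(es_up) == sign(es_down)) 0 else (es_up - es_down) / 2
}

#' Screen a drug-signature library against a hub-gene response query
#'
#' The query is the hub genes' signed mean log2FC: genes with negative
#' response form the down set, positive ones the up set. Per drug the
#' bidirectional connectivity score is computed against its signature; a
#' one-sided permutation p-value comes from rescoring `n_perm` random query
#' sets of matched sizes, BH-adjusted across drugs. Drugs with
#' `padj < padj_cutoff` and `score > score_cutoff` are flagged effective.
#'
#' The permutation test is computed on the raw bidirectional statistic
#' `(ES_up - ES_down)/2` without the same-sign zeroing (the zero rule is a
#' reporting convention; zeroing would put an atom at 0 in the null and make
#' the p-values non-uniform).
#'
#' @param hub_response Named numeric vector: hub genes' mean log2FC.
#' @param library A `DrugSignatureLibrary`.
#' @param cell_line_filter Optional character vector of cell lines to keep.
#' @param n_perm Permutations (default 1000).
#' @param score_cutoff,padj_cutoff Effectiveness thresholds (defaults 0.7,
#'   0.05).
#' @param weighted,weight_power Passed to [ks_enrichment()].
#' @param seed Optional RNG seed for the permutations.
#' @return Data frame of class `ConnectivityReport`, sorted by decreasing
#'   score: `drug`, `cell_line`, `score`, `p`, `padj`, `effective`; the query
#'   coverage is stored in attribute `coverage`.
#' @export
drug_screen <- function(hub_response, library, cell_line_filter = NULL,
                        n_perm = 1000, score_cutoff = 0.7, padj_cutoff = 0.05,
                        weighted = TRUE, weight_power = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scores <- library$scores
  if (!is.null(cell_line_filter)) {
    keep <- rownames(scores)[library$cell_line[rownames(scores)] %in%
                               cell_line_filter]
    if (length(keep) == 0) stop("no drug matches the cell-line filter", call. = FALSE)
    scores <- scores[keep, , drop = FALSE]
  }
  lib_genes <- colnames(scores)
  covered <- intersect(names(hub_response), lib_genes)
  coverage <- length(covered) / length(hub_response)
  if (length(covered) == 0) stop("no query gene is in the library", call. = FALSE)
  if (coverage < 0.5)
    warning(sprintf("query coverage is only %.0f%% of the hub genes",
                    100 * coverage))
  q <- hub_response[covered]
  query_up <- names(q)[q > 0]
  query_down <- names(q)[q < 0]

  raw_one <- function(sig, up, down) {
    # raw bidirectional statistic, no same-sign zeroing
    has_up <- length(intersect(up, names(sig))) > 0
    has_down <- length(intersect(down, names(sig))) > 0
    eu <- if (has_up) ks_enrichment(sig, up, weighted, weight_power) else 0
    ed <- if (has_down) ks_enrichment(sig, down, weighted, weight_power) else 0
    if (has_up && has_down) (eu - ed) / 2 else if (has_up) eu else -ed
  }

  # shared permutation query sets of matched sizes
  perm_sets <- lapply(seq_len(n_perm), function(i) {
    g <- sample(lib_genes, length(query_up) + length(query_down))
    list(up = g[seq_len(length(query_up))],
         down = g[setdiff(seq_along(g), seq_len(length(query_up)))])
  })

  res <- lapply(rownames(scores), function(d) {
    sig <- scores[d, ]
    obs <- connectivity_score(query_up, query_down, sig, weighted, weight_power)
    obs_raw <- raw_one(sig, query_up, query_down)
    null <- vapply(perm_sets, function(ps)
      raw_one(sig, ps$up, ps$down), numeric(1))
    p <- (1 + sum(null >= obs_raw)) / (n_perm + 1)
    data.frame(drug = d, cell_line = unname(library$cell_line[d]),
               score = obs, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- adjust_fdr(out$p)
  out$effective <- out$padj < padj_cutoff & out$score > score_cutoff
  out <- out[order(-out$score, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "coverage") <- coverage
  attr(out, "null_scores") <- NULL
  class(out) <- c("ConnectivityReport", "data.frame")
  out
}
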