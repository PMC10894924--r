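# Gaussian log-likelihood BIC of one node given its parents.
# d = #parents + 2 free parameters (intercept, coefficients, variance).
.node_score <- function(y, X, n) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, 1e-300)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  ll - (ncol(X) + 2) / 2 * log(n)
}

# is there a directed path from `from` to `to` in adjacency matrix `amat`?
.has_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  visited <- rep(FALSE, nrow(amat))
  stack <- from
  while (length(stack)) {
    v <- stack[[length(stack)]]; stack <- stack[-length(stack)]
    if (v == to) return(TRUE)
    if (visited[v]) next
    visited[v] <- TRUE
    stack <- c(stack, which(amat[v, ] & !visited))
  }
  FALSE
}

#' Hill-climbing Bayesian network structure learning
#'
#' Greedy search over single-edge additions, deletions and reversals
#' maximizing the linear-Gaussian BIC (log-likelihood minus
#' `(parameters/2) * log(n)`), with acyclicity enforced at every move.
#' The search is deterministic: candidate moves are scanned in lexicographic
#' order and the first best strict improvement is taken.
#'
#' @param data Numeric matrix or data frame, observations x variables
#'   (continuous; column names are node names).
#' @return List of class `bn_dag`: `amat` (logical adjacency, `amat[i, j]`
#'   means an edge i -> j), `nodes`, `score` (total BIC), `edges` data frame.
#' @export
hill_climb <- function(data) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n < 10) stop("need at least 10 observations", call. = FALSE)
  sds <- apply(data, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(data)[sds == 0], collapse = ", "), call. = FALSE)
  nodes <- colnames(data)
  amat <- matrix(FALSE, p, p, dimnames = list(nodes, nodes))
  node_sc <- vapply(seq_len(p), function(j)
    .node_score(data[, j], data[, integer(0), drop = FALSE], n), numeric(1))

  score_with <- function(j, parents)
    .node_score(data[, j], data[, parents, drop = FALSE], n)

  repeat {
    best <- list(delta = 1e-10, move = NULL)
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      if (!amat[i, j]) {
        # addition (skip if creates a cycle)
        if (.has_path(amat, j, i)) next
        new_j <- score_with(j, which(amat[, j] | seq_len(p) == i))
        delta <- new_j - node_sc[j]
        if (delta > best$delta)
          best <- list(delta = delta, move = c("add", i, j), new = new_j)
      } else {
        # deletion
        new_j <- score_with(j, setdiff(which(amat[, j]), i))
        delta <- new_j - node_sc[j]
        if (delta > best$delta)
          best <- list(delta = delta, move = c("del", i, j), new = new_j)
        # reversal i->j  =>  j->i
        amat[i, j] <- FALSE
        cyc <- .has_path(amat, i, j)
        amat[i, j] <- TRUE
        if (!cyc) {
          new_j2 <- score_with(j, setdiff(which(amat[, j]), i))
          new_i <- score_with(i, which(amat[, i] | seq_len(p) == j))
          delta <- (new_j2 - node_sc[j]) + (new_i - node_sc[i])
          if (delta > best$delta)
            best <- list(delta = delta, move = c("rev", i, j),
                         new = c(new_j2, new_i))
        }
      }
    }
    if (is.null(best$move)) break
    i <- as.integer(best$move[2]); j <- as.integer(best$move[3])
    switch(best$move[1],
      add = { amat[i, j] <- TRUE; node_sc[j] <- best$new },
      del = { amat[i, j] <- FALSE; node_sc[j] <- best$new },
      rev = { amat[i, j] <- FALSE; amat[j, i] <- TRUE
              node_sc[j] <- best$new[1]; node_sc[i] <- best$new[2] })
  }
  idx <- which(amat, arr.ind = TRUE)
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  structure(list(amat = amat, nodes = nodes, score = sum(node_sc),
                 edges = edges[order(edges$from, edges$to), , drop = FALSE]),
            class = "bn_dag")
}

# Elbow of the empirical CDF of edge strengths: the strength at the maximum
# vertical distance between the CDF and the chord joining its endpoints.
# Unobserved node pairs enter as strength 0 so the CDF starts at the true
# proportion of absent edges.
.strength_elbow <- function(strengths, n_pairs) {
  s <- c(rep(0, max(n_pairs - length(strengths), 0)), strengths)
  xs <- sort(unique(s))
  if (length(xs) < 2) return(max(0, xs[1] - .Machine$double.eps))
  F <- stats::ecdf(s)(xs)
  x0 <- xs[1]; x1 <- xs[length(xs)]
  F0 <- F[1]; F1 <- F[length(F)]
  chord <- F0 + (F1 - F0) * (xs - x0) / (x1 - x0)
  xs[which.max(F - chord)]
}

#' Bootstrapped Bayesian consensus network over modules and a trait
#'
#' Each iteration samples `genes_per_module` genes per module (without
#' replacement when the module is large enough), averages their responses per
#' patient, appends the clinical trait column, and learns a DAG by
#' [hill_climb()]. Edge strength is the fraction of iterations containing the
#' edge in either direction; direction confidence is the frequency of the
#' majority orientation given presence. The consensus keeps edges whose
#' strength exceeds a threshold (by default the elbow of the strength CDF),
#' oriented by majority direction; edges are admitted in decreasing strength
#' order, skipping any that would close a cycle.
#'
#' @param resp Response matrix (genes x patients).
#' @param labels Named gene -> module labels (`"unassigned"` ignored).
#' @param clin A `ClinicalTable`.
#' @param trait Trait column name (default `"dbp"`).
#' @param n_iter Bootstrap iterations (default 1000).
#' @param genes_per_module Genes sampled per module per iteration (default 20).
#' @param direction_rule Minimum direction confidence (default 0.5).
#' @param strength_threshold Optional fixed threshold overriding the elbow.
#' @param resample_patients Also resample patients with replacement per
#'   iteration (default `FALSE`: only genes are resampled).
#' @param seed Optional RNG seed.
#' @return List of class `ConsensusBN`: `nodes`, `edges` (all observed, with
#'   `strength`, `direction_confidence`, `retained`), `consensus` (retained
#'   edges only), `strength_threshold`, `n_bootstrap`.
#' @export
bootstrap_consensus <- function(resp, labels, clin, trait = "dbp",
                                n_iter = 1000, genes_per_module = 20,
                                direction_rule = 0.5,
                                strength_threshold = NULL,
                                resample_patients = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods) < 1) stop("no modules", call. = FALSE)
  tv <- clin[[trait]][match(colnames(resp), clin$patient_id)]
  if (mean(is.na(tv)) > 0.2)
    stop(sprintf("trait '%s' missing for more than 20%% of patients", trait),
         call. = FALSE)
  keep <- !is.na(tv)
  resp <- resp[, keep, drop = FALSE]; tv <- tv[keep]
  np <- ncol(resp)
  mod_genes <- lapply(mods, function(m) names(labels)[labels == m])
  names(mod_genes) <- mods
  short <- mods[vapply(mod_genes, length, integer(1)) < genes_per_module]
  if (length(short))
    message("module(s) smaller than genes_per_module, sampling with replacement: ",
            paste(short, collapse = ", "))

  nodes <- c(mods, trait)
  pair_counts <- new.env(parent = emptyenv())
  for (it in seq_len(n_iter)) {
    X <- vapply(mods, function(m) {
      g <- mod_genes[[m]]
      gi <- sample(g, genes_per_module, replace = length(g) < genes_per_module)
      colMeans(resp[gi, , drop = FALSE])
    }, numeric(np))
    X <- cbind(X, tv)
    colnames(X) <- nodes
    if (resample_patients) X <- X[sample.int(np, np, replace = TRUE), , drop = FALSE]
    dag <- hill_climb(X)
    if (nrow(dag$edges)) for (r in seq_len(nrow(dag$edges))) {
      key <- paste(dag$edges$from[r], dag$edges$to[r], sep = "\r")
      pair_counts[[key]] <- get0(key, envir = pair_counts, ifnotfound = 0L) + 1L
    }
  }

  dir_keys <- ls(pair_counts)
  if (length(dir_keys) == 0) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0), to = character(0),
                                             strength = numeric(0),
                                             direction_confidence = numeric(0),
                                             retained = logical(0)),
                          consensus = data.frame(from = character(0),
                                                 to = character(0),
                                                 strength = numeric(0)),
                          strength_threshold = strength_threshold %||% 0,
                          n_bootstrap = n_iter), class = "ConsensusBN"))
  }
  parts <- strsplit(dir_keys, "\r", fixed = TRUE)
  dd <- data.frame(from = vapply(parts, `[`, "", 1),
                   to = vapply(parts, `[`, "", 2),
                   count = vapply(dir_keys, function(k) pair_counts[[k]], 0L),
                   stringsAsFactors = FALSE, row.names = NULL)
  pair_id <- ifelse(dd$from < dd$to, paste(dd$from, dd$to),
                    paste(dd$to, dd$from))
  agg <- tapply(dd$count, pair_id, sum)
  edges <- do.call(rbind, lapply(names(agg), function(pid) {
    sel <- dd[pair_id == pid, , drop = FALSE]
    maj <- sel[which.max(sel$count), ]
    data.frame(from = maj$from, to = maj$to,
               strength = agg[[pid]] / n_iter,
               direction_confidence = maj$count / agg[[pid]],
               stringsAsFactors = FALSE)
  }))
  n_pairs <- length(nodes) * (length(nodes) - 1) / 2
  thr <- strength_threshold %||% .strength_elbow(edges$strength, n_pairs)
  edges$retained <- edges$strength > thr &
    edges$direction_confidence >= direction_rule

  # admit retained edges by decreasing strength, skipping cycle-closers
  ord <- order(-edges$strength, edges$from, edges$to)
  amat <- matrix(FALSE, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  for (r in ord) {
    if (!edges$retained[r]) next
    i <- match(edges$from[r], nodes); j <- match(edges$to[r], nodes)
    if (.has_path(amat, j, i)) { edges$retained[r] <- FALSE; next }
    amat[i, j] <- TRUE
  }
  consensus <- edges[edges$retained,
                     c("from", "to", "strength", "direction_confidence")]
  structure(list(nodes = nodes,
                 edges = edges[order(-edges$strength), , drop = FALSE],
                 consensus = consensus[order(-consensus$strength), , drop = FALSE],
                 strength_threshold = thr, n_bootstrap = n_iter),
            class = "ConsensusBN")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
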