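# equal-frequency bin assignment from ranks (ties mid-ranked)
.mi_bins <- function(x, B) {
  n <- length(x)
  b <- ceiling(B * rank(x, ties.method = "average") / n)
  pmin(pmax(b, 1L), B)
}

# plug-in MI from binned vectors with Miller-Madow bias correction, in nats
.mi_from_bins <- function(bx, by, B, n) {
  counts <- tabulate(bx + B * (by - 1L), B * B)
  p <- counts / n
  px <- tabulate(bx, B) / n
  py <- tabulate(by, B) / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz])) - sum(px[px > 0] * log(px[px > 0])) -
    sum(py[py > 0] * log(py[py > 0]))
  mi <- mi + (sum(px > 0) + sum(py > 0) - sum(nz) - 1) / (2 * n)
  max(mi, 0)
}

#' Rank-binned mutual information
#'
#' Both vectors are rank-transformed and partitioned into
#' `B = max(2, floor(sqrt(n/5)))` equal-frequency bins; the plug-in MI of the
#' joint histogram is corrected for small-sample bias (Miller-Madow) and
#' clipped at zero. Rank transformation makes the estimate invariant under
#' monotone transforms of either input.
#'
#' @param x,y Numeric vectors of equal length (>= 20).
#' @param estimator Currently only `"rank_binned"`.
#' @return MI estimate in nats (non-negative scalar), with attribute `bins`.
#' @export
estimate_mi <- function(x, y, estimator = c("rank_binned")) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 20) stop("need at least 20 observations", call. = FALSE)
  B <- max(2L, floor(sqrt(n / 5)))
  mi <- .mi_from_bins(.mi_bins(x, B), .mi_bins(y, B), B, n)
  attr(mi, "bins") <- B
  mi
}

#' Data-processing-inequality pruning
#'
#' For every fully connected triangle in a weighted (MI) graph the weakest
#' edge is removed as a putative indirect interaction, when its weight falls
#' below `(1 - tolerance)` times the smaller of the other two. Pruning is
#' simultaneous: all triangles are evaluated against the original graph.
#'
#' @param edges Data frame with columns `a`, `b`, `w` (undirected weighted
#'   edges, no duplicates).
#' @param tolerance Non-negative slack; `0` is the strict rule, values >= 1
#'   disable pruning.
#' @return The edge data frame with the pruned rows removed.
#' @export
apply_dpi <- function(edges, tolerance = 0) {
  if (tolerance < 0) stop("tolerance must be >= 0", call. = FALSE)
  if (nrow(edges) == 0) return(edges)
  nodes <- unique(c(edges$a, edges$b))
  ia <- match(edges$a, nodes); ib <- match(edges$b, nodes)
  W <- matrix(0, length(nodes), length(nodes))
  W[cbind(ia, ib)] <- edges$w
  W[cbind(ib, ia)] <- edges$w
  drop <- logical(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- ia[e]; j <- ib[e]
    common <- which(W[i, ] > 0 & W[j, ] > 0)
    common <- setdiff(common, c(i, j))
    if (length(common) == 0) next
    m <- pmin(W[i, common], W[j, common])
    drop[e] <- any(edges$w[e] < (1 - tolerance) * m)
  }
  edges[!drop, , drop = FALSE]
}

#' ARACNe-style regulatory-network inference
#'
#' Per bootstrap (patients resampled with replacement), rank-binned MI is
#' computed for every TF-gene pair; pairs below
#' `max(mi_floor, permutation-null (1 - alpha) quantile)` are dropped and the
#' data-processing inequality is applied within the bootstrap network. Edge
#' occurrences are counted across bootstraps and the consensus keeps edges
#' whose occurrence is significantly higher than a Poisson background
#' (`lambda` = total retained edge slots / distinct edges observed) after
#' Bonferroni correction (`Padj < 0.05`). Edge confidence is the bootstrap
#' support fraction.
#'
#' @param resp Response matrix (genes x patients).
#' @param tfs Character vector of regulator (TF) gene ids.
#' @param n_boot Number of bootstraps (default 100).
#' @param mi_floor Absolute MI floor in nats (default 0.5).
#' @param dpi_tolerance DPI tolerance (default 0, strict).
#' @param alpha Permutation-null tail for the MI threshold (default 0.05).
#' @param n_null Number of permuted gene pairs for the null MI distribution.
#' @param consensus_alpha Bonferroni-corrected Poisson cutoff (default 0.05).
#' @param seed Optional RNG seed.
#' @return A named list of regulons of class `RegulonSet`: per TF a data
#'   frame `target`, `weight` (bootstrap support in (0, 1]), `mor` (`NA`
#'   until [mode_of_regulation()] is applied). Attributes record the MI
#'   threshold, `n_boot`, and the TF list size.
#' @export
aracne_network <- function(resp, tfs, n_boot = 100, mi_floor = 0.5,
                           dpi_tolerance = 0, alpha = 0.05, n_null = 1000,
                           consensus_alpha = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- rownames(resp)
  tfs <- intersect(tfs, genes)
  if (length(tfs) == 0) stop("no TF is present in the response matrix", call. = FALSE)
  n <- ncol(resp)
  B <- max(2L, floor(sqrt(n / 5)))
  tf_idx <- match(tfs, genes)

  # permutation null for the MI significance threshold
  null_mi <- numeric(n_null)
  for (r in seq_len(n_null)) {
    gi <- sample.int(nrow(resp), 2L)
    null_mi[r] <- .mi_from_bins(.mi_bins(resp[gi[1], ], B),
                                .mi_bins(sample(resp[gi[2], ]), B), B, n)
  }
  thr <- max(mi_floor, stats::quantile(null_mi, 1 - alpha, names = FALSE))

  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bins <- t(apply(resp[, idx, drop = FALSE], 1L, .mi_bins, B = B))
    elist <- vector("list", length(tfs))
    for (t in seq_along(tfs)) {
      ti <- tf_idx[t]
      mi <- vapply(seq_len(nrow(resp)), function(g) {
        if (g == ti) return(0)
        .mi_from_bins(bins[ti, ], bins[g, ], B, n)
      }, numeric(1))
      hits <- which(mi >= thr)
      if (length(hits))
        elist[[t]] <- data.frame(a = genes[ti], b = genes[hits], w = mi[hits],
                                 stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, elist)
    if (is.null(edges) || nrow(edges) == 0) next
    # deduplicate TF-TF pairs recorded twice (keep first occurrence)
    key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b, sep = "\r"),
                  paste(edges$b, edges$a, sep = "\r"))
    edges <- edges[!duplicated(key), , drop = FALSE]
    edges <- apply_dpi(edges, tolerance = dpi_tolerance)
    if (nrow(edges) == 0) next
    key <- ifelse(edges$a < edges$b, paste(edges$a, edges$b, sep = "\r"),
                  paste(edges$b, edges$a, sep = "\r"))
    for (k in key)
      counts[[k]] <- get0(k, envir = counts, ifnotfound = 0L) + 1L
  }

  keys <- ls(counts)
  empty <- structure(stats::setNames(list(), character(0)),
                     class = "RegulonSet", mi_threshold = thr,
                     n_boot = n_boot, n_tfs = length(tfs))
  if (length(keys) == 0) {
    warning("no edge survived the MI threshold / DPI filters")
    return(empty)
  }
  k_e <- vapply(keys, function(k) counts[[k]], 0L)
  # Poisson background: expected support of a pair under uniform edge
  # placement, i.e. total retained edge slots over all possible TF-gene pairs
  n_possible <- length(tfs) * (nrow(resp) - 1) -
    length(tfs) * (length(tfs) - 1) / 2
  lambda <- sum(k_e) / n_possible
  p <- stats::ppois(k_e - 1, lambda, lower.tail = FALSE)
  padj <- pmin(p * length(k_e), 1)
  sig <- padj < consensus_alpha
  if (!any(sig)) {
    warning("no edge passed the Poisson consensus filter")
    return(empty)
  }
  parts <- strsplit(keys[sig], "\r", fixed = TRUE)
  a <- vapply(parts, `[`, "", 1); bnode <- vapply(parts, `[`, "", 2)
  wts <- k_e[sig] / n_boot
  is_tf_a <- a %in% tfs; is_tf_b <- bnode %in% tfs
  reg <- rep(list(NULL), length(tfs)); names(reg) <- tfs
  add <- function(tf, target, w) {
    reg[[tf]][[length(reg[[tf]]) + 1L]] <<- data.frame(
      target = target, weight = w, mor = NA_real_, stringsAsFactors = FALSE)
  }
  for (e in seq_along(a)) {
    if (is_tf_a[e]) add(a[e], bnode[e], wts[e])
    if (is_tf_b[e]) add(bnode[e], a[e], wts[e])
  }
  reg <- lapply(reg, function(x) if (is.null(x)) NULL else do.call(rbind, x))
  reg <- reg[!vapply(reg, is.null, logical(1))]
  structure(reg, class = "RegulonSet", mi_threshold = thr, n_boot = n_boot,
            n_tfs = length(tfs))
}

#' Annotate regulons with signed modes of regulation
#'
#' The mode of regulation (MoR) of each TF-target pair is the Spearman
#' correlation of their response profiles across patients: positive for
#' activation, negative for repression. Constant profiles yield `NA`.
#'
#' @param regulons A `RegulonSet`.
#' @param resp Response matrix containing TF and target rows.
#' @return The regulon set with the `mor` column filled in.
#' @export
mode_of_regulation <- function(regulons, resp) {
  for (tf in names(regulons)) {
    if (!tf %in% rownames(resp)) next
    x <- resp[tf, ]
    if (stats::sd(x) == 0) next
    tg <- regulons[[tf]]$target
    ok <- tg %in% rownames(resp)
    mor <- rep(NA_real_, length(tg))
    if (any(ok)) {
      ymat <- resp[tg[ok], , drop = FALSE]
      sds <- apply(ymat, 1L, stats::sd)
      mor[ok][sds > 0] <- suppressWarnings(
        stats::cor(x, t(ymat[sds > 0, , drop = FALSE]), method = "spearman"))[1, ]
    }
    regulons[[tf]]$mor <- mor
  }
  regulons
}

#' Write a regulon set as TSV
#'
#' Columns `tf`, `target`, `weight`, `mor`, in lexicographic order.
#'
#' @param regulons A `RegulonSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regulons <- function(regulons, path) {
  df <- do.call(rbind, lapply(names(regulons), function(tf)
    data.frame(tf = tf, regulons[[tf]], stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(tf = character(0), target = character(0),
                     weight = numeric(0), mor = numeric(0))
  df <- df[order(df$tf, df$target), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a regulon TSV written by [write_regulons()]
#'
#' @param path Path to the TSV.
#' @return A `RegulonSet`.
#' @export
read_regulons <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  reg <- lapply(split(df[, c("target", "weight", "mor")], df$tf),
                function(x) { rownames(x) <- NULL; x })
  structure(reg, class = "RegulonSet")
}
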