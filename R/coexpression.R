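#' Soft-thresholding adjacency from response correlations
#'
#' Pearson correlation between gene response profiles raised to a soft power.
#' Unsigned networks use `|cor|^power`; signed ones `((1 + cor)/2)^power`.
#' The diagonal is set to 1.
#'
#' @param resp Response matrix (genes x patients).
#' @param power Soft-thresholding exponent (default 5).
#' @param signed Use the signed transform (default `FALSE`, the usual
#'   unsigned network).
#' @return Symmetric adjacency matrix in `[0, 1]` with attribute `power`.
#' @export
soft_adjacency <- function(resp, power = 5, signed = FALSE) {
  if (ncol(resp) < 4) stop("need at least 4 patients", call. = FALSE)
  sds <- apply(resp, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant gene(s) have undefined correlations: ",
         paste(utils::head(rownames(resp)[sds == 0], 10), collapse = ", "),
         call. = FALSE)
  cc <- stats::cor(t(resp))
  adj <- if (signed) ((1 + cc) / 2)^power else abs(cc)^power
  diag(adj) <- 1
  attr(adj, "power") <- power
  attr(adj, "signed") <- signed
  adj
}

#' Topological overlap dissimilarity
#'
#' For adjacency `a`, `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with `l_ij = sum_u a_iu a_uj` over `u` distinct from `i` and `j` and
#' `k_i` the connectivity `sum_{u != i} a_iu`. Returns the dissimilarity
#' `1 - TOM` with a zero diagonal.
#'
#' @param adj Symmetric adjacency matrix in `[0, 1]`.
#' @return Dissimilarity matrix, entries in `[0, 1]`, diagonal 0.
#' @export
topological_overlap <- function(adj) {
  if (!isSymmetric(unname(as.matrix(adj)), tol = 1e-10))
    stop("adjacency must be symmetric", call. = FALSE)
  a <- as.matrix(adj)
  attr(a, "power") <- NULL; attr(a, "signed") <- NULL
  diag(a) <- 0
  l <- a %*% a           # u = i, j terms vanish because diag(a) = 0
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  d <- 1 - tom
  diag(d) <- 0
  d
}

#' Module eigengenes
#'
#' Per module, gene profiles are standardized (mean 0, sd 1 across patients)
#' and the first right singular vector over patients is taken as the
#' eigengene, its sign fixed so it correlates positively with the module's
#' mean standardized profile.
#'
#' @param resp Response matrix (genes x patients).
#' @param labels Named character vector gene -> module id
#'   (`"unassigned"` genes are ignored).
#' @return List with `eigengenes` (modules x patients matrix) and
#'   `variance_explained` (named vector in `(0, 1]`).
#' @export
module_eigengenes <- function(resp, labels) {
  mods <- setdiff(unique(labels), "unassigned")
  if (length(mods) == 0)
    return(list(eigengenes = matrix(0, 0, ncol(resp),
                                    dimnames = list(NULL, colnames(resp))),
                variance_explained = numeric(0)))
  eig <- matrix(NA_real_, length(mods), ncol(resp),
                dimnames = list(mods, colnames(resp)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    gi <- names(labels)[labels == m]
    x <- resp[gi, , drop = FALSE]
    xs <- t(scale(t(x)))
    if (length(gi) == 1) {
      warning(sprintf("module %s has a single gene; returning its profile", m))
      eig[m, ] <- xs[1, ] / sqrt(sum(xs[1, ]^2))
      ve[m] <- 1
      next
    }
    sv <- svd(xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (stats::cor(v, colMeans(xs)) < 0) v <- -v
    eig[m, ] <- v
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eig, variance_explained = ve)
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering on the dissimilarity, a static cut
#' at `cut_height` (on the raw dissimilarity scale, which is already in
#' `[0, 1]`; the cut is capped just below the tallest merge), removal of
#' clusters below `min_size`, pruning of weak members (genes whose
#' correlation with their module eigengene falls below `min_kme` become
#' `"unassigned"`, re-checking `min_size` until stable), and iterative
#' merging of modules whose eigengene dissimilarity `1 - cor` falls below
#' `merge_height`. Modules are relabeled `M1, M2, ...` by decreasing size.
#'
#' @param tom_diss Square dissimilarity matrix in `[0, 1]`.
#' @param resp Response matrix used for eigengenes.
#' @param cut_height Static tree-cut height (default 0.995).
#' @param min_size Minimum module size (default 50).
#' @param merge_height Eigengene-dissimilarity threshold below which modules
#'   merge (default 0.2).
#' @param min_kme Minimum absolute gene-eigengene correlation for module
#'   membership (default 0.5).
#' @return List with `labels` (named gene -> module or `"unassigned"`),
#'   `eigengenes`, `variance_explained`, `hclust`, `n_merged`.
#' @export
detect_modules <- function(tom_diss, resp, cut_height = 0.995, min_size = 50,
                           merge_height = 0.2, min_kme = 0.5) {
  genes <- rownames(tom_diss)
  if (is.null(genes)) genes <- rownames(resp)
  dimnames(tom_diss) <- list(genes, genes)
  hc <- stats::hclust(stats::as.dist(tom_diss), method = "average")
  h <- min(cut_height, max(hc$height) * (1 - 1e-8))
  raw <- stats::cutree(hc, h = h)
  labels <- stats::setNames(rep("unassigned", length(genes)), genes)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  for (i in seq_along(keep)) labels[raw == as.integer(keep[i])] <- paste0("C", i)

  prune <- function(labels) {
    repeat {
      mods <- setdiff(unique(labels), "unassigned")
      if (length(mods) == 0) break
      em <- module_eigengenes(resp, labels)
      changed <- FALSE
      for (m in mods) {
        gi <- names(labels)[labels == m]
        kme <- suppressWarnings(
          stats::cor(t(resp[gi, , drop = FALSE]), em$eigengenes[m, ]))[, 1]
        weak <- gi[is.na(kme) | abs(kme) < min_kme]
        if (length(weak)) { labels[weak] <- "unassigned"; changed <- TRUE }
        if (sum(labels == m) < min_size) {
          labels[labels == m] <- "unassigned"; changed <- TRUE
        }
      }
      if (!changed) break
    }
    labels
  }
  labels <- prune(labels)
  if (all(labels == "unassigned")) {
    warning("no cluster survives min_size/min_kme; all genes unassigned")
    return(list(labels = labels,
                eigengenes = matrix(0, 0, ncol(resp),
                                    dimnames = list(NULL, colnames(resp))),
                variance_explained = numeric(0), hclust = hc, n_merged = 0L))
  }

  n_merged <- 0L
  repeat {
    em <- module_eigengenes(resp, labels)
    mods <- rownames(em$eigengenes)
    if (length(mods) < 2) break
    dd <- 1 - stats::cor(t(em$eigengenes))
    diag(dd) <- Inf
    if (min(dd) >= merge_height) break
    pair <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    a <- mods[pair[1]]; b <- mods[pair[2]]
    labels[labels == b] <- a
    n_merged <- n_merged + 1L
  }
  if (n_merged > 0) labels <- prune(labels)

  # stable relabel by decreasing size (gene order breaks size ties)
  mods <- setdiff(unique(labels), "unassigned")
  sizes <- vapply(mods, function(m) sum(labels == m), integer(1))
  mods <- mods[order(-sizes)]
  new <- stats::setNames(paste0("M", seq_along(mods)), mods)
  labels[labels != "unassigned"] <- new[labels[labels != "unassigned"]]
  em <- module_eigengenes(resp, labels)
  list(labels = labels, eigengenes = em$eigengenes,
       variance_explained = em$variance_explained, hclust = hc,
       n_merged = n_merged)
}

#' Module-trait correlation matrix
#'
#' Correlates each module eigengene with each clinical covariate via
#' [trait_correlation()] (BH across modules per trait) and annotates the
#' usual significance stars.
#'
#' @param eigengenes Modules x patients matrix.
#' @param clin A `ClinicalTable`.
#' @param covariates Covariates to test (default all 14).
#' @return Data frame as [trait_correlation()] plus a `stars` column
#'   (`*` Padj < 0.05, `**` < 0.01, `***` < 0.001).
#' @export
module_trait_matrix <- function(eigengenes, clin,
                                covariates = c(.BINARY_COVARIATES,
                                               .CONTINUOUS_COVARIATES)) {
  out <- trait_correlation(eigengenes, clin, covariates = covariates)
  out$stars <- ifelse(is.na(out$padj), "",
               ifelse(out$padj < 0.001, "***",
               ifelse(out$padj < 0.01, "**",
               ifelse(out$padj < 0.05, "*", ""))))
  out
}
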