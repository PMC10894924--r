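#' Drop samples with too few detectable genes
#'
#' A gene counts as detectable in a sample when its intensity exceeds the
#' `(1 - alpha)` quantile of the negative-control intensity distribution.
#' Samples with fewer than `min_detected` detectable genes are removed.
#'
#' @param expr An `ExpressionMatrix`.
#' @param neg_control Numeric vector (or matrix) of negative-control
#'   intensities on the same log2 scale.
#' @param min_detected Minimum number of detectable genes a sample must reach
#'   (default 9000; samples strictly below are dropped).
#' @param alpha Detection tail probability (default 0.05).
#' @return List with the filtered `expr` and a `qc` report
#'   (`dropped_samples`, `detection_threshold`, `detected_counts`).
#' @export
filter_samples_by_detection <- function(expr, neg_control, min_detected = 9000,
                                        alpha = 0.05) {
  thr <- stats::quantile(as.numeric(neg_control), probs = 1 - alpha,
                         names = FALSE, type = 7)
  counts <- colSums(expr$values > thr)
  drop <- counts < min_detected
  if (all(drop))
    stop("all samples dropped by the detection filter; review min_detected/controls",
         call. = FALSE)
  keep <- !drop
  out <- expression_matrix(expr$values[, keep, drop = FALSE],
                           expr$condition[keep], expr$patient_id[keep])
  qc <- list(dropped_samples = data.frame(
               sample_id = colnames(expr$values)[drop],
               reason = rep("low_detection", sum(drop)),
               detected = unname(counts[drop]), stringsAsFactors = FALSE),
             detection_threshold = thr,
             min_detected = min_detected,
             detected_counts = counts)
  list(expr = out, qc = qc)
}

#' Remove borderline-expressed and low-variance genes
#'
#' Two sequential filters: (1) genes whose intensity stays below `min_log2`
#' in every sample are removed; (2) genes whose response variability falls
#' below `min_sd` are removed. When the matrix contains paired
#' baseline/stimulated samples the SD is computed on the per-patient log2
#' fold-change (the response scale); otherwise on the intensities.
#'
#' @param expr An `ExpressionMatrix`.
#' @param min_log2 Borderline-intensity threshold (default 7.5).
#' @param min_sd Minimum response SD (default 0.5; strictly below is removed).
#' @return List with filtered `expr` and `qc` (counts per filter).
#' @export
filter_genes <- function(expr, min_log2 = 7.5, min_sd = 0.5) {
  vals <- expr$values
  borderline <- apply(vals, 1L, max) < min_log2
  vals2 <- vals[!borderline, , drop = FALSE]

  paired <- .paired_patients(expr)
  if (length(paired) >= 2) {
    b <- vals2[, .sample_of(expr, paired, "baseline"), drop = FALSE]
    s <- vals2[, .sample_of(expr, paired, "stimulated"), drop = FALSE]
    spread <- apply(s - b, 1L, stats::sd)
  } else {
    spread <- apply(vals2, 1L, stats::sd)
  }
  lowvar <- spread < min_sd
  keep_genes <- rownames(vals2)[!lowvar]
  if (length(keep_genes) == 0)
    stop("no genes remain after filtering; review min_log2/min_sd", call. = FALSE)
  out <- expression_matrix(vals[keep_genes, , drop = FALSE],
                           expr$condition, expr$patient_id)
  qc <- list(dropped_genes = c(borderline_intensity = sum(borderline),
                               low_variance = sum(lowvar)),
             thresholds = c(min_log2 = min_log2, min_sd = min_sd),
             sd_scale = if (length(paired) >= 2) "log2fc" else "intensity")
  list(expr = out, qc = qc)
}

.paired_patients <- function(...) {
  pats <- lapply(list(...), function(e)
    intersect(e$patient_id[e$condition == "baseline"],
              e$patient_id[e$condition == "stimulated"]))
  Reduce(intersect, pats)
}

# sample ids of `patients` under `cond`, in patient order
.sample_of <- function(expr, patients, cond) {
  sel <- expr$condition == cond & expr$patient_id %in% patients
  sid <- colnames(expr$values)[sel]
  sid[match(patients, expr$patient_id[sid])]
}

#' Build the per-patient log2 fold-change response matrix
#'
#' Pairs baseline and stimulated samples by patient id and returns
#' `stimulated - baseline` per gene and patient. The two inputs may be one
#' and the same `ExpressionMatrix` holding both conditions, or separate
#' matrices sharing the gene set.
#'
#' @param baseline,stimulated `ExpressionMatrix` objects (may be identical).
#' @return List with `response` (genes x patients matrix of class
#'   `ResponseMatrix`) and `qc` (unpaired patients per side).
#' @export
build_response_matrix <- function(baseline, stimulated = baseline) {
  gs <- setdiff(union(rownames(baseline$values), rownames(stimulated$values)),
                intersect(rownames(baseline$values), rownames(stimulated$values)))
  if (length(gs))
    stop("gene sets differ between conditions; symmetric difference: ",
         paste(utils::head(gs, 10), collapse = ", "),
         if (length(gs) > 10) ", ..." else "", call. = FALSE)
  b_pat <- unique(baseline$patient_id[baseline$condition == "baseline"])
  s_pat <- unique(stimulated$patient_id[stimulated$condition == "stimulated"])
  shared <- intersect(b_pat, s_pat)
  if (length(shared) == 0) stop("no patient has both conditions", call. = FALSE)
  genes <- rownames(baseline$values)
  b <- baseline$values[, .sample_of(baseline, shared, "baseline"), drop = FALSE]
  s <- stimulated$values[genes, .sample_of(stimulated, shared, "stimulated"),
                         drop = FALSE]
  resp <- s - b
  dimnames(resp) <- list(genes, shared)
  class(resp) <- c("ResponseMatrix", class(resp))
  qc <- list(unpaired = list(baseline_only = setdiff(b_pat, shared),
                             stimulated_only = setdiff(s_pat, shared)),
             n_patients = length(shared))
  list(response = resp, qc = qc)
}

#' Flag and remove outlier patients from a response matrix
#'
#' Patients are clustered by average-linkage hierarchical clustering on their
#' Euclidean response distances (the dendrogram is returned for inspection);
#' a patient is flagged when its mean distance to all other patients exceeds
#' the Tukey upper fence `Q3 + k * IQR` of the per-patient mean distances.
#' (A median + k*MAD fence is too noisy at cohort sizes of a few dozen: the
#' MAD's sampling error alone pushes the null flag rate above 10%.)
#'
#' @param resp Response matrix (genes x patients).
#' @param k Fence multiplier on the IQR (default 3).
#' @param force Remove flagged patients even when more than 20% of the cohort
#'   is flagged (default `FALSE`: in that case a warning is issued and nothing
#'   is removed).
#' @return List with `response` (possibly reduced), `qc`
#'   (`outlier_patients`, per-patient mean distances, threshold) and `hclust`.
#' @export
detect_outliers <- function(resp, k = 3, force = FALSE) {
  if (ncol(resp) < 4) stop("need at least 4 patients", call. = FALSE)
  d <- stats::dist(t(resp))
  hc <- stats::hclust(d, method = "average")
  dm <- as.matrix(d)
  mean_dist <- rowSums(dm) / (ncol(resp) - 1)
  thr <- stats::quantile(mean_dist, 0.75, names = FALSE) +
    k * stats::IQR(mean_dist)
  flagged <- names(mean_dist)[mean_dist > thr]
  removed <- flagged
  if (length(flagged) > 0.2 * ncol(resp) && !force) {
    warning(sprintf("%d of %d patients flagged (>20%%); none removed (use force = TRUE)",
                    length(flagged), ncol(resp)))
    removed <- character(0)
  }
  out <- resp[, setdiff(colnames(resp), removed), drop = FALSE]
  class(out) <- class(resp)
  list(response = out,
       qc = list(outlier_patients = flagged, removed = removed,
                 mean_distance = mean_dist, threshold = thr, k = k),
       hclust = hc)
}

#' PCA on the top-expressed genes, with trait correlations
#'
#' Ranks genes by mean expression across samples, runs a centered PCA on the
#' top fraction (samples as observations), and correlates PC1/PC2 scores with
#' each clinical covariate (Pearson; BH-adjusted per PC across covariates).
#' The per-sample `condition` is also tested, coded baseline = 0,
#' stimulated = 1, to ask whether the leading PCs separate conditions.
#'
#' @param expr An `ExpressionMatrix` (both conditions allowed).
#' @param top_fraction Fraction of highest-expressed genes used (default 0.25).
#' @param clin Optional `ClinicalTable` for trait correlations.
#' @return List with `scores` (samples x PCs), `variance_fraction`,
#'   `trait_correlation` (data frame, or `NULL` without `clin`), and
#'   `condition_correlation`.
#' @export
pca_top_expressed <- function(expr, top_fraction = 0.25, clin = NULL) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]", call. = FALSE)
  if (ncol(expr$values) < 3) stop("need at least 3 samples", call. = FALSE)
  mean_expr <- rowMeans(expr$values)
  n_top <- max(2L, ceiling(top_fraction * nrow(expr$values)))
  top <- names(sort(mean_expr, decreasing = TRUE))[seq_len(n_top)]
  x <- t(expr$values[top, , drop = FALSE])     # samples x genes
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  varfrac <- pc$sdev^2 / sum(pc$sdev^2)

  cond_num <- as.numeric(expr$condition == "stimulated")
  cond_cor <- if (stats::sd(cond_num) > 0) {
    do.call(rbind, lapply(1:2, function(i) {
      ct <- stats::cor.test(pc$x[, i], cond_num)
      data.frame(pc = paste0("PC", i), r = unname(ct$estimate),
                 p = ct$p.value, stringsAsFactors = FALSE)
    }))
  } else NULL
  if (!is.null(cond_cor)) cond_cor$padj <- stats::p.adjust(cond_cor$p, "BH")

  trait_cor <- NULL
  if (!is.null(clin)) {
    covs <- c(.BINARY_COVARIATES, .CONTINUOUS_COVARIATES)
    pat <- expr$patient_id[rownames(pc$x)]
    rows <- list()
    for (i in 1:2) {
      sc <- pc$x[, i]
      for (cv in covs) {
        v <- clin[[cv]][match(pat, clin$patient_id)]
        ok <- !is.na(v) & !is.na(sc)
        if (sum(ok) >= 4 && stats::sd(v[ok]) > 0) {
          ct <- stats::cor.test(sc[ok], v[ok])
          rows[[length(rows) + 1L]] <-
            data.frame(pc = paste0("PC", i), covariate = cv,
                       r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                       stringsAsFactors = FALSE)
        }
      }
    }
    trait_cor <- do.call(rbind, rows)
    if (!is.null(trait_cor)) {
      trait_cor$padj <- NA_real_
      for (p in unique(trait_cor$pc)) {
        sel <- trait_cor$pc == p
        trait_cor$padj[sel] <- stats::p.adjust(trait_cor$p[sel], "BH")
      }
    }
  }
  list(scores = pc$x, variance_fraction = varfrac,
       trait_correlation = trait_cor, condition_correlation = cond_cor,
       top_genes = top)
}
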