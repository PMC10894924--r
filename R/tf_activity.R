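#' Normal-quantile rank signature
#'
#' Per patient, gene log2 fold-changes are replaced by standard-normal
#' quantiles of their mid-ranks, `qnorm((rank - 0.5) / n)`; ties get average
#' ranks. The transform is monotone in log2FC within each patient.
#'
#' @param resp Response matrix (genes x patients), >= 10 genes.
#' @return Matrix of the same shape with standard-normal quantile scores.
#' @export
rank_signature <- function(resp) {
  if (nrow(resp) < 10) stop("need at least 10 genes", call. = FALSE)
  n <- nrow(resp)
  out <- apply(resp, 2L, function(x) {
    if (stats::sd(x) == 0) stop("a patient column is constant", call. = FALSE)
    stats::qnorm((rank(x, ties.method = "average") - 0.5) / n)
  })
  rownames(out) <- rownames(resp)
  out
}

#' Regulon enrichment: per-patient TF activity (NES)
#'
#' Analytic rank-based enrichment: for each TF and patient the enrichment
#' score is the MoR- and confidence-weighted sum of its targets'
#' normal-quantile scores, `ES = sum_i mor_i w_i q_i`, normalized by
#' `sqrt(sum_i (mor_i w_i)^2)` so that the NES is standard normal when the
#' targets are an exchangeable draw from a null signature. Two-sided normal
#' p-values, BH-adjusted across TFs per patient. Targets missing from the
#' signature are dropped; regulons smaller than `min_regulon` after
#' intersection are skipped.
#'
#' @param sig Signature matrix from [rank_signature()].
#' @param regulons A `RegulonSet` with `mor` filled in (`NA` modes are
#'   treated as activation, +1).
#' @param min_regulon Minimum regulon size after intersection (default 10).
#' @return List of class `TfActivityMatrix`: `nes` (TFs x patients), `p`,
#'   `padj` (same shape), `regulon_sizes`, `skipped`.
#' @export
regulon_enrichment <- function(sig, regulons, min_regulon = 10) {
  tfs <- names(regulons)
  used <- character(0); skipped <- character(0)
  rows <- list()
  for (tf in tfs) {
    r <- regulons[[tf]]
    ok <- r$target %in% rownames(sig)
    r <- r[ok, , drop = FALSE]
    if (nrow(r) < min_regulon) { skipped <- c(skipped, tf); next }
    mor <- ifelse(is.na(r$mor), 1, r$mor)
    wt <- mor * r$weight
    q <- sig[r$target, , drop = FALSE]
    es <- as.numeric(crossprod(wt, q))
    rows[[tf]] <- es / sqrt(sum(wt^2))
    used <- c(used, tf)
  }
  if (length(rows) == 0)
    stop("no regulon reaches min_regulon after intersection", call. = FALSE)
  nes <- do.call(rbind, rows)
  dimnames(nes) <- list(used, colnames(sig))
  p <- 2 * stats::pnorm(-abs(nes))
  padj <- apply(p, 2L, adjust_fdr)
  dimnames(padj) <- dimnames(p)
  sizes <- vapply(used, function(tf)
    sum(regulons[[tf]]$target %in% rownames(sig)), integer(1))
  structure(list(nes = nes, p = p, padj = padj, regulon_sizes = sizes,
                 skipped = skipped), class = "TfActivityMatrix")
}

#' Correlate TF activities with a clinical trait
#'
#' Delegates to [trait_correlation()] with the NES matrix as features.
#'
#' @param act A `TfActivityMatrix`.
#' @param clin A `ClinicalTable`.
#' @param covariates Covariates to test (default `"dbp"`).
#' @param method Correlation method (default Pearson).
#' @return Data frame as [trait_correlation()].
#' @export
tf_trait_correlation <- function(act, clin, covariates = "dbp",
                                 method = "pearson") {
  trait_correlation(act$nes, clin, method = method, covariates = covariates)
}
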