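#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjustment: order-preserving, capped at 1. Thin, validated
#' wrapper around `stats::p.adjust(method = "BH")` so every stage shares one
#' entry point.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
adjust_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# Newton solve of trigamma(y) = x (vectorized), as used to fit the
# inverse-chi-square prior by matching moments of log-variances.
.trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(-dif / y, na.rm = TRUE) < 1e-8) break
  }
  y
}

#' Moderated one-sample differential-response test
#'
#' Per gene, tests whether the mean log2 fold-change differs from zero.
#' Residual variances are shrunk toward a common prior fitted by moments:
#' a scaled inverse-chi-square distribution is fitted to the observed
#' variances via the log-variance mean and spread (trigamma matching), the
#' posterior variance is the df-weighted blend of prior and observed, and the
#' moderated t gets `df + prior_df` degrees of freedom. When the observed
#' spread of log-variances is no larger than sampling noise the prior df is
#' infinite and all variances pool. BH adjustment across genes.
#'
#' @param resp Response matrix (genes x patients).
#' @param prior_df Optional override of the prior degrees of freedom;
#'   `0` recovers the ordinary one-sample t-test, `Inf` fully pools.
#' @param lfc_cutoff,padj_cutoff Thresholds for the `significant` flag
#'   (defaults 1 and 0.01: `|log2FC| > 1` and `Padj < 0.01`).
#' @return Data frame, one row per gene: `gene`, `log2fc`, `t`, `df_total`,
#'   `p`, `padj`, `significant`, plus attributes `prior_df` and `prior_var`.
#' @export
moderated_de <- function(resp, prior_df = NULL, lfc_cutoff = 1,
                         padj_cutoff = 0.01) {
  n <- ncol(resp)
  if (n < 3) stop("need at least 3 patients", call. = FALSE)
  m <- rowMeans(resp)
  s2 <- apply(resp, 1L, stats::var)
  df <- n - 1

  if (is.null(prior_df)) {
    z <- log(pmax(s2, 1e-300))
    e <- z - digamma(df / 2) + log(df / 2)
    ebar <- mean(e)
    evar <- sum((e - ebar)^2) / (length(e) - 1)
    excess <- evar - trigamma(df / 2)
    if (excess > 0) {
      d0 <- 2 * .trigamma_inverse(excess)
      s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
      d0 <- Inf
      s02 <- exp(ebar)
    }
  } else {
    d0 <- prior_df
    s02 <- if (is.finite(d0) && d0 > 0) exp(mean(log(pmax(s2, 1e-300)))) else mean(s2)
  }

  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + df * s2) / (d0 + df)
  tval <- m / sqrt(s2_post / n)
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(tval), df = df_total)
  padj <- adjust_fdr(p)
  out <- data.frame(gene = rownames(resp), log2fc = m, t = tval,
                    df_total = df_total, p = p, padj = padj,
                    significant = abs(m) > lfc_cutoff & padj < padj_cutoff,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s02
  out
}

#' Correlate features with clinical covariates
#'
#' Pearson (default) or Spearman correlation of every feature row against
#' every covariate, pairwise-complete; `t = r * sqrt(n - 2) / sqrt(1 - r^2)`
#' with a two-sided t-test, BH-adjusted per covariate across features.
#' Constant features or covariates yield `NA` (reported missing, not zero).
#'
#' @param features Numeric matrix, features x patients (column names are
#'   patient ids).
#' @param clin A `ClinicalTable`.
#' @param method `"pearson"` or `"spearman"`.
#' @param covariates Covariate names to test (default: all 14).
#' @return Data frame with columns `feature`, `covariate`, `r`, `t`, `n`,
#'   `p`, `padj`.
#' @export
trait_correlation <- function(features, clin,
                              method = c("pearson", "spearman"),
                              covariates = c(.BINARY_COVARIATES,
                                             .CONTINUOUS_COVARIATES)) {
  method <- match.arg(method)
  pat <- colnames(features)
  idx <- match(pat, clin$patient_id)
  rows <- vector("list", length(covariates))
  for (ci in seq_along(covariates)) {
    cv <- covariates[ci]
    v <- clin[[cv]][idx]
    r <- rep(NA_real_, nrow(features)); nn <- integer(nrow(features))
    for (fi in seq_len(nrow(features))) {
      x <- features[fi, ]
      ok <- !is.na(x) & !is.na(v)
      nn[fi] <- sum(ok)
      if (nn[fi] >= 4 && stats::sd(x[ok]) > 0 && stats::sd(v[ok]) > 0)
        r[fi] <- stats::cor(x[ok], v[ok], method = method)
    }
    tval <- r * sqrt(nn - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(tval), df = nn - 2)
    rows[[ci]] <- data.frame(feature = rownames(features), covariate = cv,
                             r = r, t = tval, n = nn, p = p,
                             padj = adjust_fdr(p),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Covariate-adjusted linear regression of a feature on a trait
#'
#' Ordinary least squares of `response ~ target + covariates` with per-term
#' two-sided t-tests. Collinear designs error out naming the aliased columns.
#'
#' @param response Named numeric vector (names are patient ids), e.g. a module
#'   eigengene.
#' @param clin A `ClinicalTable`.
#' @param target Covariate of interest (e.g. `"dbp"`).
#' @param covariates Adjustment covariates (default: diabetes, glucose,
#'   triglyceride, HDL, LDL).
#' @return Data frame with columns `term`, `estimate`, `se`, `t`, `p`.
#' @export
covariate_regression <- function(response, clin, target = "dbp",
                                 covariates = c("diabetes", "glucose",
                                                "triglyceride", "hdl", "ldl")) {
  idx <- match(names(response), clin$patient_id)
  vars <- c(target, covariates)
  df <- as.data.frame(lapply(vars, function(v) clin[[v]][idx]))
  names(df) <- vars
  df$.y <- as.numeric(response)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  X <- stats::model.matrix(~ ., data = df[, vars, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    qrX <- qr(X)
    aliased <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(.y ~ ., data = df)
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
             t = sm[, 3], p = sm[, 4], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Compare per-patient response medians between trait-defined groups
#'
#' Summarizes each patient's response by the median log2FC over the
#' significantly downregulated and upregulated gene sets separately
#' (significance per [moderated_de()]), splits patients into high
#' (`trait >= cutoff`) and low (`trait < cutoff`) groups, reports a
#' Shapiro-Wilk normality check (advisory), and runs a two-sample t-test per
#' direction.
#'
#' @param resp Response matrix.
#' @param de A [moderated_de()] result providing the significant sets.
#' @param clin A `ClinicalTable`.
#' @param trait `"dbp"` or `"sbp"`.
#' @param cutoff Group cutoff (80 mmHg for DBP, 130 for SBP by convention).
#' @return Data frame with one row per direction: group sizes and means,
#'   Shapiro-Wilk `W`/`p` per group, `t`, `p`.
#' @export
group_response_comparison <- function(resp, de, clin, trait = c("dbp", "sbp"),
                                      cutoff = if (trait[1] == "dbp") 80 else 130) {
  trait <- match.arg(trait)
  up <- de$gene[de$significant & de$log2fc > 0]
  down <- de$gene[de$significant & de$log2fc < 0]
  if (length(up) + length(down) == 0)
    stop("no significant genes; relax lfc/padj thresholds", call. = FALSE)
  v <- clin[[trait]][match(colnames(resp), clin$patient_id)]
  ok <- !is.na(v)
  high <- colnames(resp)[ok & v >= cutoff]
  low <- colnames(resp)[ok & v < cutoff]
  if (length(high) < 3 || length(low) < 3)
    stop(sprintf("group too small (high n=%d, low n=%d)", length(high),
                 length(low)), call. = FALSE)
  one_dir <- function(set, direction) {
    if (length(set) == 0) return(NULL)
    med <- apply(resp[set, , drop = FALSE], 2L, stats::median)
    sw_h <- stats::shapiro.test(med[high]); sw_l <- stats::shapiro.test(med[low])
    tt <- stats::t.test(med[high], med[low])
    data.frame(direction = direction, n_genes = length(set),
               n_high = length(high), n_low = length(low),
               mean_high = mean(med[high]), mean_low = mean(med[low]),
               shapiro_w_high = sw_h$statistic, shapiro_p_high = sw_h$p.value,
               shapiro_w_low = sw_l$statistic, shapiro_p_low = sw_l$p.value,
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- rbind(one_dir(down, "down"), one_dir(up, "up"))
  attr(out, "groups") <- list(high = high, low = low, trait = trait,
                              cutoff = cutoff)
  out
}
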