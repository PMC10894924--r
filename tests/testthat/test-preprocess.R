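make_detection_fixture <- function(n_genes = 20, detected = c(20, 10)) {
  # two baseline samples whose per-sample detectable-gene counts are given
  genes <- paste0("g", seq_len(n_genes))
  sid <- c("p1_baseline", "p2_baseline")
  vals <- matrix(4, n_genes, 2, dimnames = list(genes, sid))  # below controls
  for (j in 1:2) if (detected[j] > 0) vals[seq_len(detected[j]), j] <- 12
  expression_matrix(vals,
                    stats::setNames(rep("baseline", 2), sid),
                    stats::setNames(c("p1", "p2"), sid))
}

test_that("detection filter drops samples strictly below the threshold", {
  ctrl <- seq(4, 6, length.out = 100)  # 95th percentile ~ 5.9
  expr <- make_detection_fixture(detected = c(10, 9))
  out <- filter_samples_by_detection(expr, ctrl, min_detected = 10)
  expect_identical(out$qc$dropped_samples$sample_id, "p2_baseline")
  expect_identical(out$qc$dropped_samples$reason, "low_detection")
  # exactly at the threshold is retained (strict <)
  out2 <- filter_samples_by_detection(make_detection_fixture(detected = c(10, 10)),
                                      ctrl, min_detected = 10)
  expect_equal(ncol(out2$expr$values), 2L)
  # controls far below the data: everything detectable
  out3 <- filter_samples_by_detection(make_detection_fixture(detected = c(0, 0)),
                                      rep(2, 50), min_detected = 20)
  expect_equal(nrow(out3$qc$dropped_samples), 0L)
  expect_error(filter_samples_by_detection(expr, ctrl, min_detected = 21),
               "all samples dropped")
})

test_that("gene filters implement across-all-samples and response-SD semantics", {
  expr <- tiny_expression(n_genes = 6, n_patients = 5, seed = 2)
  v <- expr$values
  v["g1", ] <- 7.4                               # borderline everywhere -> out
  v["g2", ] <- 7.0; v["g2", 1] <- 7.6            # above 7.5 once -> kept
  v["g3", ] <- rep(c(10, 10), length.out = 10)   # zero response SD -> out
  expr <- expression_matrix(v, expr$condition, expr$patient_id)
  out <- filter_genes(expr, min_log2 = 7.5, min_sd = 0.5)
  kept <- rownames(out$expr$values)
  expect_false("g1" %in% kept)
  expect_true("g2" %in% kept || out$qc$dropped_genes["low_variance"] > 0)
  expect_false("g3" %in% kept)
  expect_identical(unname(out$qc$dropped_genes["borderline_intensity"]), 1L)
  expect_identical(out$qc$sd_scale, "log2fc")
  # idempotent: re-applying the filter changes nothing
  out2 <- filter_genes(out$expr, min_log2 = 7.5, min_sd = 0.5)
  expect_identical(rownames(out2$expr$values), kept)
})

test_that("response matrix pairs patients and is zero on identical conditions", {
  expr <- tiny_expression(n_genes = 4, n_patients = 3)
  # stimulated copy with the same values as baseline -> all-zero response
  base_only <- expression_matrix(
    expr$values[, expr$condition == "baseline"],
    expr$condition[expr$condition == "baseline"],
    expr$patient_id[expr$condition == "baseline"])
  sid <- sub("baseline", "stimulated", colnames(base_only$values))
  stim_same <- expression_matrix(
    `colnames<-`(base_only$values, sid),
    stats::setNames(rep("stimulated", 3), sid),
    stats::setNames(unname(base_only$patient_id), sid))
  rm0 <- build_response_matrix(base_only, stim_same)
  expect_true(all(rm0$response == 0))

  # a patient present only at baseline is excluded and logged
  rm1 <- build_response_matrix(expr, stim_same)
  expect_equal(sort(colnames(rm1$response)), c("p1", "p2", "p3"))
  extra <- expression_matrix(
    expr$values[, 1, drop = FALSE],
    expr$condition[1], stats::setNames("p9", names(expr$condition)[1]))
  both <- expression_matrix(cbind(expr$values,
                                  p9_baseline = expr$values[, 1]),
                            c(expr$condition, p9_baseline = "baseline"),
                            c(expr$patient_id, p9_baseline = "p9"))
  rm2 <- build_response_matrix(both, stim_same)
  expect_identical(rm2$qc$unpaired$baseline_only, "p9")
  expect_false("p9" %in% colnames(rm2$response))

  # differing gene sets raise an alignment error naming the difference
  sub <- expression_matrix(stim_same$values[-1, ], stim_same$condition,
                           stim_same$patient_id)
  expect_error(build_response_matrix(base_only, sub), "symmetric difference.*g1")
})

test_that("outlier detection flags a shifted patient but not homogeneous ones", {
  set.seed(4)
  resp <- matrix(stats::rnorm(100 * 10), 100, 10,
                 dimnames = list(paste0("g", 1:100), paste0("p", 1:10)))
  shifted <- resp
  shifted[, "p3"] <- shifted[, "p3"] + 10
  out <- detect_outliers(shifted, k = 3)
  expect_identical(out$qc$outlier_patients, "p3")
  expect_false("p3" %in% colnames(out$response))

  # null false positives rare at k = 3
  flags <- vapply(1:40, function(s) {
    set.seed(s)
    r <- matrix(stats::rnorm(60 * 10), 60, 10,
                dimnames = list(NULL, paste0("p", 1:10)))
    length(detect_outliers(r, k = 3)$qc$removed) > 0
  }, logical(1))
  expect_lte(mean(flags), 0.05)

  expect_error(detect_outliers(resp[, 1:3]), "at least 4")
})

test_that("top-expressed PCA reports sorted variance fractions and trait tests", {
  expr <- tiny_expression(n_genes = 40, n_patients = 6, seed = 3)
  clin <- tiny_clinical(6)
  out <- pca_top_expressed(expr, top_fraction = 0.25, clin = clin)
  vf <- out$variance_fraction
  expect_true(all(diff(vf) <= 1e-12))
  expect_lte(sum(vf), 1 + 1e-8)
  expect_true(all(c("pc", "covariate", "r", "p", "padj") %in%
                  names(out$trait_correlation)))
  # rank-1 matrix: PC1 carries everything
  v <- outer(stats::rnorm(20), stats::rnorm(8))
  sid <- paste0("p", 1:8, c(rep("_baseline", 4), rep("_stimulated", 4)))
  dimnames(v) <- list(paste0("g", 1:20), sid)
  em <- expression_matrix(v + 20,
                          stats::setNames(c(rep("baseline", 4),
                                            rep("stimulated", 4)), sid),
                          stats::setNames(paste0("p", 1:8), sid))
  o2 <- pca_top_expressed(em, top_fraction = 1)
  expect_gt(o2$variance_fraction[1], 0.999)
  expect_error(pca_top_expressed(expr, top_fraction = 0), "top_fraction")
})

test_that("condition-free planted data shows no PC-condition separation", {
  # baseline and stimulated drawn from one distribution: PCs should not
  # separate conditions (analogous to a null PCA check on real cohorts)
  ps <- vapply(1:12, function(s) {
    expr <- tiny_expression(n_genes = 60, n_patients = 8, seed = s + 100)
    min(pca_top_expressed(expr, 0.5)$condition_correlation$padj)
  }, numeric(1))
  expect_gt(mean(ps > 0.16), 0.5)
})
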