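test_that("BH adjustment matches the step-up oracle and preserves order", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.7), 0.7)
  set.seed(1)
  for (i in 1:100) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(adjust_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("moderated test reduces to the ordinary t and matches limma", {
  set.seed(2)
  resp <- matrix(stats::rnorm(200 * 10, 0.2, 1), 200, 10,
                 dimnames = list(paste0("g", 1:200), paste0("p", 1:10)))
  # prior df forced to 0: ordinary one-sample t recovered exactly
  de0 <- moderated_de(resp, prior_df = 0)
  ts <- apply(resp, 1L, function(x) stats::t.test(x)$statistic)
  expect_equal(unname(de0$t), unname(ts), tolerance = 1e-8)

  # equal-variance genes: moderated t equals ordinary t (shrinkage fixed point)
  z <- matrix(stats::rnorm(50 * 12), 50, 12)
  z <- t(scale(t(z)))  # exactly unit variance per gene
  dimnames(z) <- list(paste0("g", 1:50), paste0("p", 1:12))
  de_eq <- moderated_de(z)
  t_eq <- apply(z, 1L, function(x) stats::t.test(x)$statistic)
  expect_equal(unname(de_eq$t), unname(t_eq), tolerance = 1e-6)

  skip_if_not_installed("limma")
  fit <- limma::eBayes(limma::lmFit(resp, matrix(1, 10, 1)))
  de <- moderated_de(resp)
  expect_equal(attr(de, "prior_df"), fit$df.prior, tolerance = 1e-4)
  expect_equal(unname(de$t), unname(fit$t[, 1]), tolerance = 1e-6)
  expect_equal(unname(de$p), unname(fit$p.value[, 1]), tolerance = 1e-6)
})

test_that("moderated test is calibrated and flags by the lfc/padj rule", {
  set.seed(3)
  fracs <- vapply(1:25, function(i) {
    resp <- matrix(stats::rnorm(1000 * 38), 1000, 38,
                   dimnames = list(paste0("g", 1:1000), paste0("p", 1:38)))
    mean(moderated_de(resp)$p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.02)

  resp <- matrix(stats::rnorm(100 * 20, 0, 0.1), 100, 20,
                 dimnames = list(paste0("g", 1:100), paste0("p", 1:20)))
  resp[1:5, ] <- resp[1:5, ] + 2
  de <- moderated_de(resp)
  expect_true(all(de$significant[1:5]))
  expect_false(any(de$significant[-(1:5)]))
  expect_true(all(de$padj >= de$p - 1e-15))
  expect_error(moderated_de(resp[, 1:2]), "at least 3")
})

test_that("trait correlations match the closed form and cor.test", {
  clin <- tiny_clinical(38)
  feats <- rbind(dbp_copy = clin$dbp,
                 other = stats::rnorm(38))
  colnames(feats) <- clin$patient_id
  tc <- trait_correlation(feats, clin, covariates = c("dbp", "age"))
  r1 <- tc[tc$feature == "dbp_copy" & tc$covariate == "dbp", ]
  expect_equal(r1$r, 1, tolerance = 1e-12)
  expect_lt(r1$p, 1e-10)
  # t = r sqrt(n-2)/sqrt(1-r^2) for every computed row, vs cor.test
  for (i in seq_len(nrow(tc))) {
    ct <- stats::cor.test(feats[tc$feature[i], ], clin[[tc$covariate[i]]])
    expect_equal(tc$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(tc$p[i], ct$p.value, tolerance = 1e-10)
  }
  # worked closed form: r = -0.4, n = 38 -> two-sided p ~ 0.0128
  t0 <- -0.4 * sqrt(36) / sqrt(1 - 0.16)
  expect_equal(2 * stats::pt(t0, 36), 0.0128, tolerance = 5e-3)
  # constant feature reported missing, not zero
  feats2 <- rbind(flat = rep(1, 38)); colnames(feats2) <- clin$patient_id
  tc2 <- trait_correlation(feats2, clin, covariates = "dbp")
  expect_true(is.na(tc2$r))
})

test_that("null trait correlations have uniform p-values", {
  set.seed(9)
  clin <- tiny_clinical(40)
  clin$dbp <- sample(clin$dbp)
  feats <- matrix(stats::rnorm(300 * 40), 300, 40,
                  dimnames = list(paste0("f", 1:300), clin$patient_id))
  tc <- trait_correlation(feats, clin, covariates = "dbp")
  expect_gt(stats::ks.test(tc$p, "punif")$p.value, 0.01)
})

test_that("covariate regression recovers planted effects and names collinearity", {
  set.seed(5)
  hits <- vapply(1:60, function(s) {
    set.seed(s)
    clin <- tiny_clinical(40, seed = s)
    y <- stats::setNames(2 * clin$dbp + stats::rnorm(40, 0, 5), clin$patient_id)
    fit <- covariate_regression(y, clin)
    p <- stats::setNames(fit$p, fit$term)
    p[["dbp"]] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  clin <- tiny_clinical(30)
  y <- stats::setNames(3 * clin$dbp - 1, clin$patient_id)  # zero noise
  fit <- covariate_regression(y, clin, covariates = c("glucose", "hdl"))
  expect_equal(fit$estimate[fit$term == "dbp"], 3, tolerance = 1e-8)

  clin$dup <- clin$glucose
  expect_error(covariate_regression(y, clin, covariates = c("glucose", "dup")),
               "collinear.*dup")
})

test_that("group comparison splits by the cutoff and detects planted dampening", {
  set.seed(8)
  n <- 40
  clin <- tiny_clinical(n)
  resp <- matrix(stats::rnorm(200 * n, 0, 0.2), 200, n,
                 dimnames = list(paste0("g", 1:200), clin$patient_id))
  down <- 1:30
  resp[down, ] <- resp[down, ] - 2
  high <- clin$dbp >= 80
  # dampening: high-DBP patients' downregulation pulled toward zero
  resp[down, high] <- resp[down, high] + 1
  de <- moderated_de(resp)
  out <- group_response_comparison(resp, de, clin, trait = "dbp", cutoff = 80)
  row <- out[out$direction == "down", ]
  expect_equal(row$n_high + row$n_low, sum(!is.na(clin$dbp)))
  expect_equal(row$n_high, sum(high))
  expect_gt(row$mean_high, row$mean_low)
  expect_lt(row$p, 0.01)
  expect_true(all(c("shapiro_w_high", "shapiro_p_low") %in% names(out)))
  # empty significant set errors with advice
  de_none <- de; de_none$significant <- FALSE
  expect_error(group_response_comparison(resp, de_none, clin), "relax")
})
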