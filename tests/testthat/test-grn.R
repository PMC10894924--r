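test_that("MI estimator is symmetric, monotone-invariant, and calibrated", {
  set.seed(16)
  x <- stats::rnorm(300); y <- stats::rnorm(300)
  expect_equal(as.numeric(estimate_mi(x, y)), as.numeric(estimate_mi(y, x)),
               tolerance = 1e-12)
  expect_equal(as.numeric(estimate_mi(exp(x), y)),
               as.numeric(estimate_mi(x, y)), tolerance = 1e-12)
  # deterministic dependence saturates the histogram bound
  z <- stats::rnorm(1000)
  B <- floor(sqrt(1000 / 5))
  expect_gte(estimate_mi(z, z), 0.9 * log(B))
  # independent vectors give near-zero MI
  nulls <- vapply(1:20, function(s) {
    set.seed(s)
    estimate_mi(stats::rnorm(1000), stats::rnorm(1000))
  }, numeric(1))
  expect_gte(mean(nulls <= 0.05), 0.95)
  # Gaussian closed form at rho = 0.9: MI = -log(1 - rho^2)/2 = 0.830
  set.seed(17)
  a <- stats::rnorm(5000)
  b <- 0.9 * a + sqrt(1 - 0.81) * stats::rnorm(5000)
  expect_lt(abs(estimate_mi(a, b) - 0.830), 0.15)
  expect_error(estimate_mi(1:30, 1:29), "equal length")
  expect_error(estimate_mi(1:10, 1:10), "at least 20")
})

test_that("DPI removes the weakest triangle edge and matches the oracle", {
  tri <- data.frame(a = c("x", "x", "y"), b = c("y", "z", "z"),
                    w = c(0.9, 0.8, 0.3), stringsAsFactors = FALSE)
  out <- apply_dpi(tri, tolerance = 0)
  expect_equal(nrow(out), 2L)
  expect_false(any(out$w == 0.3))
  # tolerance >= 1 disables pruning
  expect_equal(nrow(apply_dpi(tri, tolerance = 1)), 3L)
  # chain without the closing edge is untouched
  chain <- tri[1:2, ]
  expect_equal(apply_dpi(chain, 0), chain)
  expect_error(apply_dpi(tri, tolerance = -1), ">= 0")
  # random graphs vs all-triangles oracle
  set.seed(18)
  for (i in 1:15) {
    nn <- sample(5:12, 1)
    nodes <- paste0("n", seq_len(nn))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.5
    ed <- data.frame(a = pairs[keep, 1], b = pairs[keep, 2],
                     w = stats::runif(sum(keep)), stringsAsFactors = FALSE)
    tol <- sample(c(0, 0.1, 0.3), 1)
    expect_equal(apply_dpi(ed, tol), dpi_oracle(ed, tol))
  }
})

test_that("planted regulons are recovered with signed modes of regulation", {
  cfg <- simulation_config(n_genes = 400, n_patients = 150, n_modules = 1,
                           module_sizes = 50, n_tfs = 8, targets_per_tf = 10,
                           repressor_fraction = 0.25, noise_sd = 0.5, seed = 19)
  sim <- simulate_cohort(cfg)
  resp <- build_response_matrix(sim$baseline, sim$stimulated)$response
  grn <- aracne_network(resp, sim$truth$tf_ids, n_boot = 40, seed = 20)
  grn <- mode_of_regulation(grn, resp)
  expect_s3_class(grn, "RegulonSet")
  # every regulator is a declared TF and no self-loops
  expect_true(all(names(grn) %in% sim$truth$tf_ids))
  for (tf in names(grn)) expect_false(tf %in% grn[[tf]]$target)
  pred <- unlist(lapply(names(grn), function(tf) paste(tf, grn[[tf]]$target)))
  truth <- unlist(lapply(names(sim$truth$regulons), function(tf)
    paste(tf, sim$truth$regulons[[tf]]$target)))
  tp <- length(intersect(pred, truth))
  expect_gte(tp / length(pred), 0.8)
  expect_gte(tp / length(truth), 0.8)
  # weights are bootstrap support fractions
  ws <- unlist(lapply(grn, function(r) r$weight))
  expect_true(all(ws > 0 & ws <= 1))
  # MoR signs match the planted modes on recovered true edges
  sign_ok <- unlist(lapply(names(grn), function(tf) {
    r <- grn[[tf]]; tr <- sim$truth$regulons[[tf]]
    ok <- r$target %in% tr$target
    sign(r$mor[ok]) == sign(tr$mor[match(r$target[ok], tr$target)])
  }))
  expect_gte(mean(sign_ok, na.rm = TRUE), 0.9)
  # regulon TSV round-trip
  path <- withr::local_tempfile(fileext = ".tsv")
  write_regulons(grn, path)
  back <- read_regulons(path)
  expect_setequal(names(back), names(grn))
})

test_that("shuffled-patient null yields an empty consensus", {
  empties <- vapply(1:5, function(s) {
    set.seed(s + 400)
    resp <- matrix(stats::rnorm(120 * 40), 120, 40,
                   dimnames = list(paste0("g", 1:120), paste0("p", 1:40)))
    suppressWarnings(
      length(aracne_network(resp, paste0("g", 1:10), n_boot = 20,
                            seed = s)) == 0)
  }, logical(1))
  expect_gte(mean(empties), 0.9)
})
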