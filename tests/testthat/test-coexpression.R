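test_that("soft adjacency implements the unsigned/signed transforms", {
  # two genes with correlation exactly +-0.5 by construction
  x <- c(1, 1, -1, -1, 1, -1)
  y <- c(1, 0, 0, -1, 0, 0)   # cor(x, y) = sqrt(...) not exact; build exact pair
  resp <- rbind(a = x, b = x * 0.5 + sqrt(1 - 0.25) * (y - mean(y)) / stats::sd(y))
  colnames(resp) <- paste0("p", 1:6)
  cc <- stats::cor(t(resp))[1, 2]
  adj <- soft_adjacency(resp, power = 5)
  expect_equal(adj[1, 2], abs(cc)^5, tolerance = 1e-12)
  expect_equal(diag(adj), c(a = 1, b = 1))
  # negative correlation gives the same unsigned adjacency
  respn <- rbind(a = x, b = -resp[2, ]); colnames(respn) <- paste0("p", 1:6)
  expect_equal(soft_adjacency(respn, 5)[1, 2], adj[1, 2], tolerance = 1e-12)
  # signed transform
  adjs <- soft_adjacency(resp, power = 5, signed = TRUE)
  expect_equal(adjs[1, 2], ((1 + cc) / 2)^5, tolerance = 1e-12)
  # perfect correlation -> 1
  respp <- rbind(a = x, b = 2 * x); colnames(respp) <- paste0("p", 1:6)
  expect_equal(soft_adjacency(respp, 5)[1, 2], 1, tolerance = 1e-12)
  # constant gene errors with its name
  respc <- rbind(a = x, flat = rep(1, 6)); colnames(respc) <- paste0("p", 1:6)
  expect_error(soft_adjacency(respc, 5), "flat")
})

test_that("TOM dissimilarity matches the brute-force oracle", {
  # complete graph with unit adjacency: dissimilarity 0
  a1 <- matrix(1, 3, 3)
  expect_equal(topological_overlap(a1), matrix(0, 3, 3), tolerance = 1e-12)
  # no edge, no shared neighbors: dissimilarity 1
  a2 <- diag(3)
  d2 <- topological_overlap(a2)
  expect_equal(d2[1, 2], 1, tolerance = 1e-12)
  # random instances vs oracle
  set.seed(6)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    r <- matrix(stats::runif(n * n), n)
    a <- (r + t(r)) / 2
    diag(a) <- 1
    d <- topological_overlap(a)
    expect_lt(max(abs(d - tom_oracle(a))), 1e-12)
    expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
    expect_equal(d, t(d), tolerance = 1e-12)
  }
  expect_error(topological_overlap(matrix(c(1, .2, .6, 1), 2)), "symmetric")
})

test_that("eigengenes match the eigendecomposition oracle with fixed sign", {
  set.seed(7)
  resp <- matrix(stats::rnorm(30 * 12), 30, 12,
                 dimnames = list(paste0("g", 1:30), paste0("p", 1:12)))
  labels <- stats::setNames(rep(c("M1", "M2", "unassigned"), each = 10),
                            rownames(resp))
  em <- module_eigengenes(resp, labels)
  for (m in c("M1", "M2")) {
    gi <- names(labels)[labels == m]
    xs <- t(scale(t(resp[gi, ])))
    ev <- eigen(crossprod(xs))  # patients x patients covariance route
    v <- ev$vectors[, 1]
    expect_equal(abs(stats::cor(em$eigengenes[m, ], v)), 1, tolerance = 1e-8)
    expect_equal(em$variance_explained[[m]], ev$values[1] / sum(ev$values),
                 tolerance = 1e-8)
    expect_gte(stats::cor(em$eigengenes[m, ], colMeans(xs)), 0)
  }
  expect_true(all(em$variance_explained > 0 & em$variance_explained <= 1))
  # identical profiles: |cor(eigengene, profile)| = 1
  resp2 <- matrix(rep(stats::rnorm(12), each = 5), 5, byrow = FALSE,
                  dimnames = list(paste0("g", 1:5), paste0("p", 1:12)))
  em2 <- module_eigengenes(resp2, stats::setNames(rep("M1", 5), rownames(resp2)))
  expect_equal(abs(stats::cor(em2$eigengenes["M1", ], resp2[1, ])), 1,
               tolerance = 1e-10)
})

test_that("planted blocks are recovered, undersized blocks left unassigned", {
  set.seed(10)
  n <- 38
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n); f3 <- stats::rnorm(n)
  mk <- function(f, k) t(sapply(seq_len(k), function(i)
    sqrt(0.8) * f + sqrt(0.2) * stats::rnorm(n)))
  resp <- rbind(mk(f1, 60), mk(f2, 60), mk(f3, 20),
                matrix(stats::rnorm(100 * n), 100, n))
  rownames(resp) <- paste0("g", seq_len(nrow(resp)))
  colnames(resp) <- paste0("p", 1:n)
  truth <- rep(c("A", "B", "small", "noise"), c(60, 60, 20, 100))
  mods <- suppressWarnings(
    detect_modules(topological_overlap(soft_adjacency(resp, 5)), resp))
  big <- truth %in% c("A", "B")
  expect_equal(ari_index(mods$labels[big], truth[big]), 1)
  # the 20-gene block is below min_size -> unassigned
  expect_true(all(mods$labels[truth == "small"] == "unassigned"))
  # most noise is unassigned
  expect_gte(mean(mods$labels[truth == "noise"] == "unassigned"), 0.9)
})

test_that("merging is idempotent and collapses near-duplicate modules", {
  set.seed(11)
  n <- 30
  f <- stats::rnorm(n)
  resp <- t(sapply(1:120, function(i) sqrt(0.8) * f + sqrt(0.2) * stats::rnorm(n)))
  dimnames(resp) <- list(paste0("g", 1:120), paste0("p", 1:n))
  # two halves of one factor: any split must merge into a single module
  mods <- suppressWarnings(
    detect_modules(topological_overlap(soft_adjacency(resp, 5)), resp))
  expect_equal(length(unique(mods$labels[mods$labels != "unassigned"])), 1L)
  # a second merge pass changes nothing
  em <- module_eigengenes(resp, mods$labels)
  if (nrow(em$eigengenes) > 1) {
    dd <- 1 - stats::cor(t(em$eigengenes)); diag(dd) <- Inf
    expect_gte(min(dd), 0.2)
  }
})

test_that("module-trait matrix finds a planted eigengene-trait link", {
  set.seed(12)
  n <- 200
  clin <- tiny_clinical(n, seed = 12)
  f <- 0.6 * scale(clin$dbp)[, 1] + sqrt(1 - 0.36) * stats::rnorm(n)
  eig <- rbind(M1 = f, M2 = stats::rnorm(n))
  colnames(eig) <- clin$patient_id
  mt <- module_trait_matrix(eig, clin, covariates = c("dbp", "sbp"))
  row <- mt[mt$feature == "M1" & mt$covariate == "dbp", ]
  expect_lt(row$padj, 0.05)
  expect_true(row$stars != "")
  expect_true(all(abs(mt$r) <= 1, na.rm = TRUE))
  # permuted trait: nothing significant in most seeds
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    clin2 <- clin; clin2$dbp <- sample(clin2$dbp)
    eig2 <- matrix(stats::rnorm(5 * n), 5, n,
                   dimnames = list(paste0("M", 1:5), clin$patient_id))
    any(module_trait_matrix(eig2, clin2, covariates = "dbp")$padj < 0.05)
  }, logical(1))
  expect_gte(mean(!hits), 0.9)
})
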