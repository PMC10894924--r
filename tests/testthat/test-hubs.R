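test_that("subnetwork extraction honors the weight cutoff and keeps isolates", {
  set.seed(26)
  resp <- matrix(stats::rnorm(30 * 12), 30, 12,
                 dimnames = list(paste0("g", 1:30), paste0("p", 1:12)))
  adj <- soft_adjacency(resp, 2)
  labels <- stats::setNames(rep(c("M1", "unassigned"), c(20, 10)),
                            rownames(resp))
  g <- extract_subnetwork(adj, labels, "M1", weight_cutoff = 0.4)
  expect_equal(igraph::vcount(g), 20)
  if (igraph::ecount(g) > 0) expect_true(all(igraph::E(g)$weight > 0.4))
  expect_equal(igraph::ecount(extract_subnetwork(adj, labels, "M1", 1)), 0)
  gfull <- extract_subnetwork(adj, labels, "M1", 0)
  expect_equal(igraph::ecount(gfull), choose(20, 2))
  expect_error(extract_subnetwork(adj, labels, "M9"), "empty")
})

test_that("centralities rank a star center first and match the betweenness oracle", {
  a <- matrix(0, 6, 6, dimnames = list(paste0("n", 1:6), paste0("n", 1:6)))
  a[1, 2:6] <- 1; a[2:6, 1] <- 1
  g <- igraph::graph_from_adjacency_matrix(a, "undirected", weighted = TRUE)
  ct <- centralities(g)
  for (m in c("degree", "betweenness", "closeness", "eigenvector", "pagerank"))
    expect_equal(which.max(ct[[m]]), 1L)
  # cycle graph: full symmetry, every measure ties
  cyc <- igraph::make_ring(6)
  igraph::E(cyc)$weight <- 1
  igraph::V(cyc)$name <- paste0("c", 1:6)
  cc <- centralities(cyc)
  for (m in c("degree", "betweenness", "closeness", "eigenvector", "pagerank"))
    expect_lt(diff(range(cc[[m]])), 1e-8)
  # random weighted graphs vs exhaustive path-enumeration betweenness
  set.seed(27)
  for (i in 1:5) {
    n <- 6
    am <- matrix(0, n, n)
    idx <- which(upper.tri(am))
    sel <- sample(idx, 9)
    am[sel] <- stats::runif(9, 0.2, 1)
    am <- am + t(am)
    dimnames(am) <- list(paste0("v", 1:n), paste0("v", 1:n))
    gg <- igraph::graph_from_adjacency_matrix(am, "undirected", weighted = TRUE)
    expect_equal(centralities(gg)$betweenness, betweenness_oracle(am),
                 tolerance = 1e-8)
  }
})

test_that("RRA reproduces the exact order-statistic worked case", {
  n <- 10; K <- 3
  lists <- lapply(1:K, function(k) {
    r <- c(1, sample(2:n))
    stats::setNames(r, paste0("g", 1:n))
  })
  out <- rra_aggregate(lists)
  g1 <- out[out$gene == "g1", ]
  # binomial tails at r = 0.1: (0.271, 0.028, 0.001)
  pk <- stats::pbinom(0:2, K, 0.1, lower.tail = FALSE)
  expect_equal(pk, c(0.271, 0.028, 0.001), tolerance = 1e-12)
  expect_equal(g1$rho, 0.001, tolerance = 1e-12)
  expect_equal(g1$score, 0.003, tolerance = 1e-12)
  expect_equal(g1$padj, 0.03, tolerance = 1e-12)
  expect_true(g1$hub)
  # beta order-statistic p equals the binomial tail for every k
  r <- 0.37
  expect_equal(stats::pbeta(r, 1:K, K - (1:K) + 1),
               stats::pbinom(0:(K - 1), K, r, lower.tail = FALSE),
               tolerance = 1e-12)
  # a gene ranked last everywhere is no hub
  last <- out[out$gene == out$gene[which.max(out$rho)], ]
  worst <- lapply(1:K, function(k) stats::setNames(c(n, 1:(n - 1)), paste0("g", 1:n)))
  outw <- rra_aggregate(worst)
  expect_equal(outw$score[outw$gene == "g1"], 1)
  expect_false(outw$hub[outw$gene == "g1"])
  expect_error(rra_aggregate(list(stats::setNames(1:3, c("a", "b", "c")),
                                  stats::setNames(1:3, c("a", "b", "x")))),
               "same gene set")
})

test_that("RRA is calibrated on random permutations", {
  set.seed(28)
  rates <- vapply(1:10, function(s) {
    lists <- lapply(1:5, function(k) stats::setNames(sample(50), paste0("g", 1:50)))
    mean(rra_aggregate(lists)$hub)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})

test_that("a planted wired hub is detected through the full module path", {
  hits <- vapply(1:10, function(s) {
    set.seed(s + 500)
    n <- 40
    a <- matrix(stats::runif(n * n, 0, 0.3), n)
    a <- (a + t(a)) / 2
    a[1, ] <- a[, 1] <- 0.9          # hub gene wired to everyone
    diag(a) <- 1
    dimnames(a) <- list(paste0("g", 1:n), paste0("g", 1:n))
    labels <- stats::setNames(rep("M1", n), rownames(a))
    hubs <- module_hubs(a, labels, "M1", weight_cutoff = 0.4)
    isTRUE(hubs$hub[hubs$gene == "g1"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
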