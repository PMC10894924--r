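# Independent brute-force oracles used across the suite.

# adjusted Rand index between two label vectors
ari_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sr <- sum(choose(rowSums(tab), 2))
  sc <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- sr * sc / choose(n, 2)
  (sij - e) / ((sr + sc) / 2 - e)
}

# textbook Benjamini-Hochberg step-up with cumulative minimum
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

# TOM dissimilarity by explicit double loop
tom_oracle <- function(adj) {
  a <- as.matrix(adj); diag(a) <- 0
  n <- nrow(a)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    d[i, j] <- 1 - (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(d) <- dimnames(adj)
  d
}

# hypergeometric upper tail P(X >= k) by explicit enumeration
hyper_tail_oracle <- function(k, set_size, bg_size, query_size) {
  ks <- k:min(set_size, query_size)
  sum(choose(set_size, ks) * choose(bg_size - set_size, query_size - ks)) /
    choose(bg_size, query_size)
}

# DPI by enumerating all triangles of the original graph
dpi_oracle <- function(edges, tolerance = 0) {
  nodes <- unique(c(edges$a, edges$b))
  w <- function(x, y) {
    hit <- (edges$a == x & edges$b == y) | (edges$a == y & edges$b == x)
    if (any(hit)) edges$w[hit][1] else 0
  }
  drop <- logical(nrow(edges))
  tri <- t(utils::combn(nodes, 3))
  for (r in seq_len(nrow(tri))) {
    x <- tri[r, 1]; y <- tri[r, 2]; z <- tri[r, 3]
    wxy <- w(x, y); wxz <- w(x, z); wyz <- w(y, z)
    if (wxy == 0 || wxz == 0 || wyz == 0) next
    ws <- c(wxy, wxz, wyz)
    pairs <- list(c(x, y), c(x, z), c(y, z))
    weakest <- which.min(ws)
    if (ws[weakest] < (1 - tolerance) * min(ws[-weakest])) {
      px <- pairs[[weakest]]
      hit <- (edges$a == px[1] & edges$b == px[2]) |
        (edges$a == px[2] & edges$b == px[1])
      drop[hit] <- TRUE
    }
  }
  edges[!drop, , drop = FALSE]
}

# weighted betweenness by exhaustive simple-path enumeration (tiny graphs)
betweenness_oracle <- function(adjmat) {
  n <- nrow(adjmat)
  dist <- ifelse(adjmat > 0, 1 / adjmat, Inf)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, seen, len) {
      if (v == t) { paths[[length(paths) + 1L]] <<- list(seen = seen, len = len); return() }
      for (u in seq_len(n)) {
        if (dist[v, u] < Inf && !(u %in% seen))
          walk(u, c(seen, u), len + dist[v, u])
      }
    }
    walk(s, s, 0)
    paths
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- all_paths(s, t)
    if (length(ps) == 0) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    sp <- ps[abs(lens - min(lens)) < 1e-12]
    for (pp in sp) {
      inner <- setdiff(pp$seen, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(sp)
    }
  }
  btw
}

# linear-Gaussian BIC of a full DAG, scored independently with lm()
dag_bic_oracle <- function(data, amat) {
  n <- nrow(data)
  total <- 0
  for (j in seq_len(ncol(data))) {
    parents <- which(amat[, j])
    df <- data.frame(y = data[, j])
    if (length(parents)) {
      df <- cbind(df, data[, parents, drop = FALSE])
      fit <- stats::lm(y ~ ., data = df)
    } else fit <- stats::lm(y ~ 1, data = df)
    rss <- sum(stats::residuals(fit)^2)
    ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
    total <- total + ll - (length(parents) + 2) / 2 * log(n)
  }
  total
}

# all 25 DAGs on 3 labeled nodes, as a list of adjacency matrices
all_dags3 <- function() {
  combos <- expand.grid(rep(list(0:2), 3))  # per pair: none, ->, <-
  out <- list()
  for (r in seq_len(nrow(combos))) {
    amat <- matrix(FALSE, 3, 3)
    st <- as.integer(combos[r, ])
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    for (k in 1:3) {
      if (st[k] == 1) amat[pairs[[k]][1], pairs[[k]][2]] <- TRUE
      if (st[k] == 2) amat[pairs[[k]][2], pairs[[k]][1]] <- TRUE
    }
    # cycles only arise with all three pairs oriented consistently
    m <- amat
    for (i in 1:3) m <- m | (m %*% amat > 0)
    if (any(diag(m))) next
    out[[length(out) + 1L]] <- amat
  }
  out
}

# small paired cohort expression fixture built in code
tiny_expression <- function(n_genes = 5, n_patients = 4, seed = 1) {
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  pats <- paste0("p", seq_len(n_patients))
  sid <- c(paste0(pats, "_baseline"), paste0(pats, "_stimulated"))
  vals <- matrix(stats::rnorm(n_genes * 2 * n_patients, 10, 1), n_genes,
                 dimnames = list(genes, sid))
  expression_matrix(vals,
                    condition = stats::setNames(rep(c("baseline", "stimulated"),
                                                    each = n_patients), sid),
                    patient_id = stats::setNames(rep(pats, 2), sid))
}

# clinical fixture with all 14 covariates
tiny_clinical <- function(n = 8, seed = 1) {
  set.seed(seed)
  clin <- data.frame(patient_id = paste0("p", seq_len(n)),
                     sex = rep_len(c(1L, 0L), n), renal_failure = 0L,
                     smoker = rep_len(c(0L, 0L, 1L), n),
                     diabetes = rep_len(c(0L, 1L), n),
                     age = stats::rnorm(n, 66, 8), bmi = stats::rnorm(n, 27, 4),
                     heart_rate = stats::rnorm(n, 63, 10),
                     dbp = stats::rnorm(n, 75, 12), sbp = stats::rnorm(n, 138, 21),
                     glucose = stats::rnorm(n, 6.4, 1),
                     triglyceride = stats::rnorm(n, 1.5, .6),
                     creatinine = stats::rnorm(n, 87, 20),
                     hdl = stats::rnorm(n, 1.1, .3), ldl = stats::rnorm(n, 2.6, .9),
                     stringsAsFactors = FALSE)
  class(clin) <- c("ClinicalTable", "data.frame")
  clin
}
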