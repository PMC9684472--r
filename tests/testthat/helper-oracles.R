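# Shared fixtures and independent brute-force oracles. All oracles here are
# deliberately naive (dense algebra, exhaustive enumeration) and share no code
# with the implementation paths they check.

rand_scaled_coords <- function(n, k = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scale_coordinates(spatial_coordinates(matrix(stats::rnorm(n * k), n, k)))
}

rand_std_expr <- function(m, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(stats::rnorm(m * n), m, n)
  v <- t(scale(t(v)))
  expression_matrix(array(v, dim(v)), state = "standardized")
}

full_rank_kernel <- function(coords, gamma = 1.5) {
  lowrank_eigen(build_kernel(coords, gamma), variance_threshold = 1)
}

# dense multivariate-normal log-density of the covariate-projected data:
# vec(Y M) ~ MVN(0, s2 * (tau * K (x) W W^T + I)), columns stacked
dense_loglik_oracle <- function(Y, K, W, tau, s2, X = NULL) {
  n <- ncol(Y); m <- nrow(Y)
  if (is.null(X)) X <- matrix(1, n, 1)
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  y <- as.vector(Y %*% M)
  Sig <- s2 * (tau * kronecker(K, tcrossprod(W)) + diag(m * n))
  -0.5 * (m * n * log(2 * pi) +
            as.numeric(determinant(Sig, logarithm = TRUE)$modulus) +
            as.numeric(crossprod(y, solve(Sig, y))))
}

# explicit Gaussian conditioning for the posterior factor mean: for the joint
# normal of (vec Z, vec Y M), E[Z | Y] row by row via dense solves
dense_posterior_oracle <- function(Y, K, W, tau, X = NULL) {
  n <- ncol(Y)
  if (is.null(X)) X <- matrix(1, n, 1)
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  A <- crossprod(W, Y %*% M)                       # d x n
  t(tau * K %*% solve(tau * K + diag(n), t(A)))
}

# simulate from the generative model on a given kernel (no standardization)
simulate_from_model <- function(m, n, d, tau, s2, kern, seed) {
  set.seed(seed)
  W <- qr.Q(qr(matrix(stats::rnorm(m * d), m, d)))
  ev <- eigen(kern$K, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  Z <- matrix(stats::rnorm(d * n), d, n) %*% t(L) * sqrt(s2 * tau)
  Y <- W %*% Z + matrix(stats::rnorm(m * n, sd = sqrt(s2)), m, n)
  list(expr = expression_matrix(Y, state = "standardized"), W = W, Z = Z)
}

largest_principal_angle <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(sv)))) * 180 / pi
}

# ARI by exhaustive pair enumeration
brute_ari <- function(a, b) {
  n <- length(a)
  both <- 0; same_a <- 0; same_b <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    same_a <- same_a + sa; same_b <- same_b + sb
    both <- both + (sa && sb)
  }
  P <- choose(n, 2)
  e <- same_a * same_b / P
  mx <- (same_a + same_b) / 2
  if (mx == e) return(0)
  (both - e) / (mx - e)
}

# PAS by exhaustive neighbor scan on the dense distance matrix
brute_pas <- function(labels, coords, k = 10, threshold = 6) {
  m <- coords$coords
  D <- as.matrix(stats::dist(m))
  n <- nrow(m)
  abnormal <- vapply(seq_len(n), function(i) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb_idx <- seq_len(n)[-i][nb]
    sum(labels[nb_idx] != labels[i]) >= threshold
  }, TRUE)
  mean(abnormal)
}

# CHAOS by direct edge enumeration
brute_chaos <- function(labels, coords) {
  m <- coords$coords
  total <- 0
  for (k in unique(labels)) {
    idx <- which(labels == k)
    if (length(idx) < 2) next
    for (i in idx) {
      d <- sqrt(colSums((t(m[setdiff(idx, i), , drop = FALSE]) - m[i, ])^2))
      total <- total + min(d)
    }
  }
  total / nrow(m)
}

# LISI by direct entropy calibration with uniroot on log(beta)
brute_lisi <- function(labels, coords, perplexity = 30) {
  m <- coords$coords
  n <- nrow(m)
  D <- as.matrix(stats::dist(m))
  k <- min(ceiling(3 * perplexity), n - 1)
  target <- log(perplexity)
  out <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(D[i, -i])[seq_len(k)]
    nb_idx <- seq_len(n)[-i][nb]
    d2 <- D[i, nb_idx]^2
    ent <- function(lb) {
      w <- exp(-d2 * exp(lb))
      if (sum(w) < .Machine$double.xmin) return(-target)
      p <- w / sum(w)
      -sum(p[p > 0] * log(p[p > 0])) - target
    }
    lb <- stats::uniroot(ent, c(-30, 30), tol = 1e-12)$root
    w <- exp(-d2 * exp(lb)); p <- w / sum(w)
    pk <- tapply(p, labels[nb_idx], sum)
    out[i] <- 1 / sum(pk^2)
  }
  out
}

# shortest-path hop counts by breadth-first search over an edge list
bfs_hops <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1; queue <- c(queue, w)
      }
    }
    D[s, ] <- dist
  }
  D
}

# small spot-level synthetic dataset for pipeline-style tests
make_spot_dataset <- function(n_cells = 800, n_genes = 300, scenario = "S2",
                              grid_edge = 3, seed = 1L,
                              lattice = c(60L, 60L)) {
  tissue <- make_layered_tissue(n_cells, lattice = lattice, layout = "bands4",
                                seed = seed)
  tissue <- assign_cell_types(tissue, scenario, seed = seed + 1L)
  tissue <- simulate_tissue_counts(tissue, n_genes, seed = seed + 2L)
  aggregate_to_spots(tissue, grid_edge)
}
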