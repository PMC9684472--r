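test_that("marginal likelihood matches the dense multivariate-normal oracle", {
  for (s in 1:8) {
    set.seed(100 + s)
    m <- sample(3:6, 1); n <- sample(5:10, 1); d <- sample(1:2, 1)
    co <- rand_scaled_coords(n)
    kern <- full_rank_kernel(co, gamma = runif(1, 0.5, 3))
    expr <- rand_std_expr(m, n)
    W <- qr.Q(qr(matrix(rnorm(m * d), m, d)))
    tau <- runif(1, 0, 5); s2 <- runif(1, 0.3, 2)
    got <- marginal_loglik(expr, kern, W, tau, s2)
    ref <- dense_loglik_oracle(expr$values, kern$K, W, tau, s2)
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("marginal likelihood closed forms hold at the boundaries", {
  n <- 7; m <- 4; d <- 2
  co <- rand_scaled_coords(n, seed = 110)
  kern <- full_rank_kernel(co, gamma = 1)
  W <- qr.Q(qr(matrix(rnorm(m * d), m, d)))
  zero <- expression_matrix(matrix(0, m, n), state = "standardized")
  tau <- 1.7; s2 <- 0.9
  ref <- -(m * n / 2) * log(2 * pi * s2) -
    (d / 2) * sum(log1p(tau * kern$eigvals))
  expect_equal(marginal_loglik(zero, kern, W, tau, s2), ref, tolerance = 1e-10)

  # tau = 0 collapses to the iid Gaussian density, independent of the kernel
  expr <- rand_std_expr(m, n, seed = 111)
  ll <- marginal_loglik(expr, kern, W, 0, s2)
  kern2 <- full_rank_kernel(rand_scaled_coords(n, seed = 112), gamma = 3)
  expect_equal(marginal_loglik(expr, kern2, W, 0, s2), ll, tolerance = 1e-10)
  Yp <- expr$values - rowMeans(expr$values)
  expect_equal(ll, sum(dnorm(Yp, sd = sqrt(s2), log = TRUE)), tolerance = 1e-8)

  expect_error(marginal_loglik(expr, kern, W, -1, s2), "tau")
  expect_error(marginal_loglik(expr, kern, W, 1, 0), "sigma0_sq")
})

test_that("posterior spatial PCs match explicit Gaussian conditioning", {
  for (s in 1:8) {
    set.seed(120 + s)
    m <- sample(4:6, 1); n <- sample(6:10, 1); d <- sample(1:2, 1)
    co <- rand_scaled_coords(n)
    kern <- full_rank_kernel(co, gamma = runif(1, 0.5, 2))
    expr <- rand_std_expr(m, n)
    fit <- spatial_pca_fit(expr, kern, d = d)
    ref <- dense_posterior_oracle(expr$values, kern$K, fit$W, fit$tau)
    expect_equal(unname(fit$Z), unname(ref), tolerance = 1e-8)
  }
})

test_that("posterior collapses to zero prior mean at tau = 0 and smooths fully on a rank-1 kernel", {
  m <- 5; n <- 8; d <- 2
  expr <- rand_std_expr(m, n, seed = 130)
  co <- rand_scaled_coords(n, seed = 131)
  kern <- full_rank_kernel(co)
  fit <- spatial_pca_fit(expr, kern, d = d)
  fit$tau <- 0
  expect_equal(posterior_spatial_pcs(fit, expr),
               matrix(0, d, n), ignore_attr = TRUE)

  ones <- structure(list(K = matrix(1, n, n), gamma = 1, coords = co,
                         kind = "custom"), class = "SpatialKernel")
  ones <- lowrank_eigen(ones, 0.9)
  fit1 <- spatial_pca_fit(expr, ones, d = 1)
  expect_lte(diff(range(fit1$Z[1, ])), 1e-8)
})

test_that("an identity kernel reduces the fit to ordinary PCA loadings", {
  for (s in 1:4) {
    set.seed(140 + s)
    m <- 8; n <- 12; d <- 3
    expr <- rand_std_expr(m, n)
    eye <- structure(list(K = diag(n), gamma = 1, coords = NULL,
                          kind = "custom"), class = "SpatialKernel")
    eye <- lowrank_eigen(eye, 1.0)
    fit <- spatial_pca_fit(expr, eye, d = d)
    Yp <- expr$values - rowMeans(expr$values)
    pca <- svd(Yp)$u[, 1:d]
    expect_lte(max(abs(abs(fit$W) - abs(pca))), 1e-6)
  }
})

test_that("fitted parameters achieve at least the non-spatial PCA likelihood", {
  for (s in 1:4) {
    set.seed(150 + s)
    n <- 20; m <- 10; d <- 3
    co <- rand_scaled_coords(n)
    kern <- full_rank_kernel(co, gamma = 1)
    sim <- simulate_from_model(m, n, d, tau = 3, s2 = 1, kern, seed = 150 + s)
    fit <- spatial_pca_fit(sim$expr, kern, d = d)
    Yp <- sim$expr$values - rowMeans(sim$expr$values)
    Wpca <- svd(Yp)$u[, 1:d]
    s2_mom <- sum(Yp^2) / (m * n)
    base <- marginal_loglik(sim$expr, kern, Wpca, 0, s2_mom)
    expect_gte(fit$loglik, base - 1e-8)
  }
})

test_that("the profile search is within 1e-4 of a black-box maximizer", {
  set.seed(160)
  n <- 15; m <- 8; d <- 2
  co <- rand_scaled_coords(n)
  kern <- full_rank_kernel(co, gamma = 1)
  sim <- simulate_from_model(m, n, d, tau = 4, s2 = 1, kern, seed = 161)
  fit <- spatial_pca_fit(sim$expr, kern, d = d)
  prof <- function(lt) {
    tau <- exp(lt)
    Yp <- sim$expr$values - rowMeans(sim$expr$values)
    ck <- tau * kern$eigvals / (1 + tau * kern$eigvals)
    G <- Yp %*% kern$eigvecs
    sv <- svd(sweep(G, 2, sqrt(ck), "*"), nu = 0, nv = 0)
    quad <- sum(Yp^2) - sum(sv$d[1:d]^2)
    s2 <- quad / (m * n)
    -0.5 * m * n * (log(2 * pi * s2) + 1) -
      0.5 * d * sum(log1p(tau * kern$eigvals))
  }
  black <- optimize(prof, c(log(1e-10), log(1e10)), maximum = TRUE,
                    tol = 1e-10)
  expect_equal(fit$loglik, black$objective, tolerance = 1e-4)
})

test_that("the spatial variance ratio separates signal from noise", {
  # under iid noise the maximum-likelihood tau retains a finite positive
  # value (the profile likelihood rewards any chance alignment with smooth
  # kernel directions), so the discriminating quantity is the gap between the
  # null fit and a fit on data with genuine spatial factors
  grid <- as.matrix(expand.grid(x = 1:8, y = 1:8))
  co <- scale_coordinates(spatial_coordinates(grid))
  kern <- full_rank_kernel(co, gamma = 1)
  null_stats <- vapply(1:5, function(s) {
    expr <- rand_std_expr(20, 64, seed = 170 + s)
    fit <- spatial_pca_fit(expr, kern, d = 3)
    Yp <- expr$values - rowMeans(expr$values)
    base <- marginal_loglik(expr, kern, fit$W, 0, sum(Yp^2) / (20 * 64))
    c(tau = fit$tau, gain = (fit$loglik - base) / (20 * 64))
  }, c(tau = 1, gain = 1))
  sig_taus <- vapply(1:5, function(s) {
    sim <- simulate_from_model(20, 64, 3, tau = 10, s2 = 1, kern,
                               seed = 175 + s)
    spatial_pca_fit(sim$expr, kern, d = 3)$tau
  }, 1)
  # the likelihood gain from spatial structure under the null is marginal
  expect_lte(median(null_stats["gain", ]), 0.05)
  # and the fitted tau under genuine spatial signal dwarfs the null one
  expect_gte(median(sig_taus), 5 * median(null_stats["tau", ]))
})

test_that("location permutation permutes factors and preserves the likelihood", {
  set.seed(180)
  n <- 14; m <- 7; d <- 2
  co <- rand_scaled_coords(n)
  kern <- full_rank_kernel(co, gamma = 1)
  sim <- simulate_from_model(m, n, d, tau = 3, s2 = 1, kern, seed = 181)
  fit <- spatial_pca_fit(sim$expr, kern, d = d)
  perm <- sample(n)
  co_p <- spatial_coordinates(co$coords[perm, , drop = FALSE], scaled = TRUE)
  kern_p <- full_rank_kernel(co_p, gamma = 1)
  expr_p <- expression_matrix(sim$expr$values[, perm],
                              location_ids = sim$expr$location_ids[perm],
                              state = "standardized")
  fit_p <- spatial_pca_fit(expr_p, kern_p, d = d)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)
  expect_equal(abs(unname(fit_p$Z)), abs(unname(fit$Z[, perm])),
               tolerance = 1e-5)
})

test_that("spatial smoothing only removes factor variance", {
  for (s in 1:5) {
    set.seed(190 + s)
    n <- 25; m <- 12; d <- 3
    kern <- full_rank_kernel(rand_scaled_coords(n), gamma = 1)
    sim <- simulate_from_model(m, n, d, tau = 5, s2 = 1, kern, seed = 190 + s)
    fit <- spatial_pca_fit(sim$expr, kern, d = d)
    Yp <- sim$expr$values - rowMeans(sim$expr$values)
    raw <- crossprod(fit$W, Yp)
    for (l in seq_len(d))
      expect_lte(var(fit$Z[l, ]), var(raw[l, ]) + 1e-10)
  }
})

test_that("loading subspace recovery matches the information-limit baseline", {
  # the subspace error of the fit should track (and not exceed) that of the
  # oracle PCA baseline on the same data, and tau should be recovered within
  # a factor of two
  res <- vapply(1:5, function(s) {
    grid <- as.matrix(expand.grid(x = 1:10, y = 1:10))
    co <- scale_coordinates(spatial_coordinates(grid))
    kern <- lowrank_eigen(build_kernel(co, gamma = 0.3), 0.99)
    sim <- simulate_from_model(40, 100, 3, tau = 10, s2 = 1, kern,
                               seed = 200 + s)
    fit <- spatial_pca_fit(sim$expr, kern, d = 3)
    Yp <- sim$expr$values - rowMeans(sim$expr$values)
    c(spca = largest_principal_angle(fit$W, sim$W),
      pca = largest_principal_angle(svd(Yp)$u[, 1:3], sim$W),
      tau = fit$tau)
  }, c(spca = 1, pca = 1, tau = 1))
  expect_lte(median(res["spca", ] - res["pca", ]), 1)
  expect_true(all(res["tau", ] > 5 & res["tau", ] < 20))
})
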