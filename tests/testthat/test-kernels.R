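test_that("coordinate scaling centers, scales and inverts exactly", {
  m <- matrix(c(0, 2, 0, 2,
                0, 0, 2, 2), 4, 2)
  co <- spatial_coordinates(m)
  sc <- scale_coordinates(co)
  expect_true(sc$scaled)
  expect_equal(unname(sc$axis_means), c(1, 1))
  expect_equal(unname(sc$axis_sds), rep(sd(c(0, 2, 0, 2)), 2))
  expect_equal(unname(colMeans(sc$coords)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(sc$coords, 2, sd)), c(1, 1), tolerance = 1e-12)
  # idempotent, and the inverse recovers platform units
  expect_identical(scale_coordinates(sc), sc)
  expect_equal(unscale_coordinates(sc)$coords, co$coords, tolerance = 1e-12)
  expect_error(scale_coordinates(spatial_coordinates(cbind(1:4, rep(2, 4)))),
               "constant")
})

test_that("Silverman bandwidth matches the printed formula and the median rule", {
  set.seed(31)
  n <- 10000
  g1 <- scale(rnorm(n))[, 1]
  e <- expression_matrix(matrix(c(g1, g1), 2, n, byrow = TRUE),
                         state = "standardized")
  got <- select_bandwidth(e, method = "silverman")
  ref <- 0.9 * min(sd(g1), IQR(g1) / 1.34) * n^(-1 / 5)
  expect_equal(got, ref, tolerance = 1e-12)

  # median across two genes with different spreads
  g2 <- scale(rnorm(n, sd = 3))[, 1] * 2   # not unit SD after the *2
  e2 <- expression_matrix(matrix(c(g1, g2), 2, n, byrow = TRUE),
                          state = "standardized")
  b1 <- 0.9 * min(sd(g1), IQR(g1) / 1.34) * n^(-1 / 5)
  b2 <- 0.9 * min(sd(g2), IQR(g2) / 1.34) * n^(-1 / 5)
  expect_equal(select_bandwidth(e2, method = "silverman"), (b1 + b2) / 2,
               tolerance = 1e-12)
})

test_that("auto bandwidth switches estimator at n = 5000", {
  set.seed(32)
  x <- rnorm(5001)
  e_big <- expression_matrix(matrix(c(x, x), 2, 5001, byrow = TRUE),
                             state = "standardized")
  e_small <- expression_matrix(matrix(c(x[1:5000], x[1:5000]), 2, 5000,
                                      byrow = TRUE),
                               state = "standardized")
  expect_equal(select_bandwidth(e_big, n = 5001, method = "auto"),
               select_bandwidth(e_big, n = 5001, method = "silverman"))
  expect_equal(select_bandwidth(e_small, n = 5000, method = "auto"),
               select_bandwidth(e_small, n = 5000, method = "sheather_jones"))
  expect_false(isTRUE(all.equal(
    select_bandwidth(e_small, n = 5000, method = "auto"),
    select_bandwidth(e_small, n = 5000, method = "silverman"))))
})

test_that("Gaussian kernel has unit diagonal, closed-form entries and limits", {
  co <- rand_scaled_coords(15, seed = 33)
  k <- build_kernel(co, gamma = 2)
  expect_equal(unname(diag(k$K)), rep(1, 15))
  expect_equal(k$K, t(k$K))
  d2 <- as.matrix(dist(co$coords))^2
  expect_equal(unname(k$K), unname(exp(-d2 / 2)), tolerance = 1e-12)
  # two points exactly one bandwidth apart
  co2 <- spatial_coordinates(rbind(c(0, 0), c(sqrt(2), 0), c(0, 1), c(1, 1)),
                             scaled = TRUE)
  k2 <- build_kernel(co2, gamma = 2)
  expect_equal(k2$K[1, 2], exp(-1), tolerance = 1e-12)
  # gamma -> Inf gives an all-ones kernel
  k3 <- build_kernel(co, gamma = 1e12)
  expect_true(all(abs(k3$K - 1) < 1e-10))
})

test_that("kernel is PSD, sparsification-stable and rotation-invariant", {
  for (s in 1:3) {
    co <- rand_scaled_coords(40, seed = 40 + s)
    k <- build_kernel(co, gamma = 1)
    ev <- eigen(k$K, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    # default cutoff moves no eigenvalue by more than n * cutoff
    ks <- build_kernel(co, gamma = 1, sparse_cutoff = 1e-20)
    evs <- eigen(ks$K, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev - evs)), 40 * 1e-20 + 1e-12)
    # rigid rotation of the scaled coordinates preserves the kernel
    th <- 0.7
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    co_rot <- spatial_coordinates(co$coords %*% R, scaled = TRUE)
    k_rot <- build_kernel(co_rot, gamma = 1)
    expect_equal(unname(k_rot$K), unname(k$K), tolerance = 1e-10)
  }
})

test_that("histology pseudo-dimensions enter the distance after z-scoring", {
  co <- rand_scaled_coords(20, seed = 51)
  h <- matrix(runif(20, 0, 10), 20, 1)
  k <- build_kernel(co, gamma = 1.5, histology = h)
  aug <- cbind(co$coords, scale(h))
  d2 <- as.matrix(dist(aug))^2
  ref <- exp(-d2 / 1.5); diag(ref) <- 1
  expect_equal(unname(k$K), unname(ref), tolerance = 1e-12)
})

test_that("Delaunay hop distances agree with a BFS oracle", {
  # triangle: every pair is a Delaunay neighbor
  tri <- spatial_coordinates(rbind(c(0, 0), c(1, 0), c(0.4, 1)), scaled = TRUE)
  D <- delaunay_distance_matrix(tri)
  expect_equal(unname(diag(D)), rep(0L, 3))
  expect_true(all(D[upper.tri(D)] == 1L))

  # unit square: opposite corners are 1 or 2 hops depending on the diagonal;
  # all hop counts must match BFS on the produced triangulation
  sq <- spatial_coordinates(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)),
                            scaled = TRUE)
  Dsq <- delaunay_distance_matrix(sq)
  expect_true(all(Dsq[Dsq > 0] %in% c(1L, 2L)))

  set.seed(52)
  co <- spatial_coordinates(matrix(runif(40), 20, 2), scaled = TRUE)
  D20 <- delaunay_distance_matrix(co)
  tr <- deldir::deldir(co$coords[, 1], co$coords[, 2], suppressMsge = TRUE)
  ref <- bfs_hops(as.matrix(tr$delsgs[, c("ind1", "ind2")]), 20)
  expect_equal(unname(D20), unname(ref), ignore_attr = TRUE)
})

test_that("low-rank truncation retains the prescribed variance fraction", {
  ones <- structure(list(K = matrix(1, 8, 8), gamma = 1, coords = NULL,
                         kind = "custom"), class = "SpatialKernel")
  expect_equal(lowrank_eigen(ones, 0.9)$rank, 1L)

  eye <- structure(list(K = diag(10), gamma = 1, coords = NULL,
                        kind = "custom"), class = "SpatialKernel")
  expect_equal(lowrank_eigen(eye, 0.9)$rank, 9L)

  for (s in 1:5) {
    co <- rand_scaled_coords(30, seed = 60 + s)
    k <- lowrank_eigen(build_kernel(co, gamma = 0.8), 0.9)
    expect_gte(k$variance_fraction, 0.9)
    expect_true(all(diff(k$eigvals) <= 1e-12))
    expect_equal(unname(crossprod(k$eigvecs)), diag(k$rank), tolerance = 1e-8)
    recon <- k$eigvecs %*% (k$eigvals * t(k$eigvecs))
    rel <- norm(k$K - recon, "F") / norm(k$K, "F")
    expect_lte(rel, sqrt(1 - k$variance_fraction) + 1e-10)
  }
})

test_that("block kernels are block-diagonal with the union spectrum", {
  k1 <- full_rank_kernel(rand_scaled_coords(6, seed = 71), gamma = 1)
  k2 <- full_rank_kernel(rand_scaled_coords(9, seed = 72), gamma = 1)
  rownames(k2$K) <- colnames(k2$K) <- paste0("b", 1:9)
  bk <- block_kernel(list(k1, k2))
  expect_true(all(bk$K[1:6, 7:15] == 0))
  expect_true(all(bk$K[7:15, 1:6] == 0))
  expect_equal(sort(bk$eigvals), sort(c(k1$eigvals, k2$eigvals)),
               tolerance = 1e-10)
  expect_equal(bk$K[1:6, 1:6], k1$K, ignore_attr = TRUE)
  # duplicated ids across samples are rejected
  expect_error(block_kernel(list(k1, k1)), "duplicated")
})
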