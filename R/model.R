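# Core latent factor model:
#   Y = (X B)^T + W Z + E,   E_ji ~ N(0, sigma0^2)
# with orthonormal loadings (W^T W = I_d) and a Gaussian-process prior on each
# factor row: Z_l. ~ MVN(0, sigma0^2 * tau * K). Integrating out B and Z gives
# a marginal likelihood in which, after projecting the data onto the orthogonal
# complement of the covariates, vec of the projected m x n matrix is
# MVN(0, sigma0^2 * (tau * K (x) W W^T + I)). All computations run in the
# kernel eigenbasis K = U diag(lambda) U^T: the covariance eigenvalues are
# 1 + tau * lambda_k (each with multiplicity d) and the quadratic form needs
# only A = W^T Y U.

project_out_covariates <- function(Y, covariates) {
  X <- covariates$values
  if (nrow(X) != ncol(Y)) stop("covariate rows must match location count")
  # Y M with M = I - X (X^T X)^{-1} X^T: remove covariate effects per gene
  Y - (Y %*% X) %*% solve(crossprod(X), t(X))
}

check_orthonormal <- function(W, tol = 1e-6) {
  d <- ncol(W)
  if (max(abs(crossprod(W) - diag(d))) > tol)
    stop("W is not orthonormal")
  invisible(W)
}

#' Marginal log-likelihood of the spatial factor model
#'
#' Evaluates the log-density of the covariate-projected expression matrix
#' under the generative model with loadings `W`, spatial variance ratio `tau`
#' and residual variance `sigma0_sq`, using the retained kernel eigenpairs.
#' On small instances this agrees with a dense multivariate-normal density
#' over the vectorized matrix with covariance
#' `sigma0_sq * (tau * K %x% W W^T + I)`.
#'
#' @param expr standardized `ExpressionMatrix` (genes x locations).
#' @param kernel a `SpatialKernel` with eigenpairs ([lowrank_eigen()]).
#' @param W m x d orthonormal loading matrix.
#' @param tau non-negative spatial variance ratio.
#' @param sigma0_sq positive residual variance.
#' @param covariates a [covariate_table()]; defaults to intercept-only.
#'
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(expr, kernel, W, tau, sigma0_sq,
                            covariates = covariate_table(ncol(expr$values))) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(kernel, "SpatialKernel"))
  if (expr$state != "standardized")
    stop("marginal_loglik expects standardized expression")
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  if (!is.finite(sigma0_sq) || sigma0_sq <= 0) stop("sigma0_sq must be > 0")
  if (is.null(kernel$eigvals)) stop("kernel eigenpairs missing; run lowrank_eigen()")
  W <- as.matrix(W)
  check_orthonormal(W)
  Y <- project_out_covariates(expr$values, covariates)
  m <- nrow(Y); n <- ncol(Y); d <- ncol(W)
  lam <- kernel$eigvals
  U <- kernel$eigvecs
  ck <- tau * lam / (1 + tau * lam)
  A <- crossprod(W, Y) %*% U                       # d x r
  quad <- sum(Y^2) - sum(sweep(A^2, 2, ck, "*"))
  -0.5 * m * n * log(2 * pi * sigma0_sq) -
    0.5 * d * sum(log1p(tau * lam)) -
    quad / (2 * sigma0_sq)
}

profile_fit_at_tau <- function(Y, U, lam, d, tau) {
  m <- nrow(Y); n <- ncol(Y)
  ck <- tau * lam / (1 + tau * lam)
  G <- Y %*% U                                     # m x r
  Gc <- sweep(G, 2, sqrt(ck), "*")
  sv <- svd(Gc, nu = min(d, ncol(Gc)), nv = 0)
  if (ncol(sv$u) < d)
    stop("kernel rank too small for the requested number of factors")
  W <- sv$u[, seq_len(d), drop = FALSE]
  quad <- sum(Y^2) - sum(sv$d[seq_len(d)]^2)
  quad <- max(quad, .Machine$double.eps)
  sigma0_sq <- quad / (m * n)
  ll <- -0.5 * m * n * (log(2 * pi * sigma0_sq) + 1) -
    0.5 * d * sum(log1p(tau * lam))
  list(W = W, sigma0_sq = sigma0_sq, loglik = ll)
}

fix_loading_signs <- function(W, Z = NULL) {
  for (j in seq_len(ncol(W))) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) {
      W[, j] <- -W[, j]
      if (!is.null(Z)) Z[j, ] <- -Z[j, ]
    }
  }
  list(W = W, Z = Z)
}

#' Fit the spatially aware probabilistic PCA model
#'
#' Maximum-likelihood estimation of the loadings `W`, the spatial variance
#' ratio `tau` and the residual variance `sigma0_sq`. For each candidate
#' `tau`, the optimal `W` is the top-`d` eigenvector set of the weighted
#' cross-product matrix `Y U diag(tau*lambda/(1+tau*lambda)) U^T Y^T`
#' (computed via an SVD in the kernel eigenbasis) and `sigma0_sq` is profiled
#' in closed form; `tau` itself is found by a 21-point log-spaced grid search
#' over [1e-10, 1e10] followed by golden-section refinement of the bracketing
#' interval, with ties broken toward smaller `tau`. The posterior spatial PCs
#' are attached to the returned fit.
#'
#' @param expr standardized `ExpressionMatrix`.
#' @param kernel a `SpatialKernel` with eigenpairs.
#' @param d number of factors (default 20).
#' @param covariates a [covariate_table()]; defaults to intercept-only.
#'
#' @return An object of class `SpatialPCAFit` with elements `W` (m x d,
#'   orthonormal, largest-magnitude entry of each column positive), `tau`,
#'   `sigma0_sq`, `Z` (d x n posterior spatial PCs), `d`, `loglik`, `kernel`,
#'   `covariates`.
#' @export
spatial_pca_fit <- function(expr, kernel, d = 20,
                            covariates = covariate_table(ncol(expr$values))) {
  stopifnot(inherits(expr, "ExpressionMatrix"), inherits(kernel, "SpatialKernel"))
  if (expr$state != "standardized")
    stop("spatial_pca_fit expects standardized expression")
  if (is.null(kernel$eigvals)) stop("kernel eigenpairs missing; run lowrank_eigen()")
  m <- nrow(expr$values); n <- ncol(expr$values)
  if (d >= min(m, n)) stop("d must be smaller than min(genes, locations)")
  Y <- project_out_covariates(expr$values, covariates)
  U <- kernel$eigvecs; lam <- kernel$eigvals
  obj <- function(log_tau) profile_fit_at_tau(Y, U, lam, d, exp(log_tau))$loglik

  grid <- seq(log(1e-10), log(1e10), length.out = 21)
  ll_grid <- vapply(grid, obj, 1)
  if (any(!is.finite(ll_grid))) stop("non-finite likelihood on the tau grid")
  best <- which(ll_grid == max(ll_grid))[1]      # ties -> smaller tau
  lo <- grid[max(1, best - 1)]
  hi <- grid[min(length(grid), best + 1)]
  opt <- stats::optimize(obj, lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-6)
  # keep whichever of grid point / refined point is better (guards plateaus)
  if (opt$objective >= ll_grid[best]) {
    log_tau <- opt$maximum; ll <- opt$objective
  } else {
    log_tau <- grid[best]; ll <- ll_grid[best]
  }
  tau <- exp(log_tau)
  at <- profile_fit_at_tau(Y, U, lam, d, tau)

  fit <- structure(list(W = at$W, tau = tau, sigma0_sq = at$sigma0_sq,
                        Z = NULL, d = d, loglik = at$loglik, kernel = kernel,
                        covariates = covariates,
                        gene_ids = expr$gene_ids,
                        location_ids = expr$location_ids),
                   class = "SpatialPCAFit")
  Z <- posterior_spatial_pcs(fit, expr)
  sg <- fix_loading_signs(fit$W, Z)
  fit$W <- sg$W
  fit$Z <- sg$Z
  rownames(fit$W) <- expr$gene_ids
  colnames(fit$Z) <- expr$location_ids
  fit
}

#' @export
print.SpatialPCAFit <- function(x, ...) {
  cat(sprintf(paste0("SpatialPCAFit: %d genes, %d locations, %d factors\n",
                     "  tau = %.4g, sigma0^2 = %.4g, loglik = %.4f\n"),
              nrow(x$W), length(x$location_ids), x$d, x$tau, x$sigma0_sq,
              x$loglik))
  invisible(x)
}

#' Posterior spatial PCs
#'
#' Computes the posterior mean of the latent factors given the data and the
#' fitted parameters. Because the loadings are orthonormal, the posterior for
#' factor `l` depends on the data only through `a_l = (W^T Y)_l` and equals
#' `U diag(tau*lambda/(1+tau*lambda)) U^T a_l`.
#'
#' @param fit a `SpatialPCAFit`.
#' @param expr the standardized `ExpressionMatrix` used for the fit.
#' @return The d x n matrix of posterior spatial PCs.
#' @export
posterior_spatial_pcs <- function(fit, expr) {
  stopifnot(inherits(fit, "SpatialPCAFit"), inherits(expr, "ExpressionMatrix"))
  if (nrow(expr$values) != nrow(fit$W)) stop("gene dimension mismatch")
  Y <- project_out_covariates(expr$values, fit$covariates)
  U <- fit$kernel$eigvecs; lam <- fit$kernel$eigvals
  ck <- fit$tau * lam / (1 + fit$tau * lam)
  A <- crossprod(fit$W, Y)                         # d x n
  t(U %*% (ck * crossprod(U, t(A))))               # d x n
}

#' Ordinary PCA loadings and scores
#'
#' Plain (non-spatial) PCA of a standardized expression matrix, provided as
#' the baseline dimension-reduction method. Computed by SVD after projecting
#' out the covariates.
#'
#' @param expr standardized `ExpressionMatrix`.
#' @param d number of components.
#' @param covariates a [covariate_table()].
#' @return List with `W` (m x d loadings) and `Z` (d x n scores).
#' @export
ordinary_pca <- function(expr, d = 20,
                         covariates = covariate_table(ncol(expr$values))) {
  Y <- project_out_covariates(expr$values, covariates)
  sv <- svd(Y, nu = d, nv = d)
  W <- sv$u
  Z <- t(sweep(sv$v, 2, sv$d[seq_len(d)], "*"))
  sg <- fix_loading_signs(W, Z)
  rownames(sg$W) <- expr$gene_ids
  colnames(sg$Z) <- expr$location_ids
  list(W = sg$W, Z = sg$Z)
}
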