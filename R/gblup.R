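#' Marker-product kinship matrix
#'
#' `K = Z Z' / m` over the additive codes as they stand — no centering and
#' no allele-frequency denominator — so that the relationship-form model is
#' exactly the integrated-out version of the marker-effect model with
#' `gamma_k ~ N(0, phi^2 / m)`.
#'
#' @param Z a fully encoded [geno_matrix()], or a numeric samples x markers
#'   matrix
#' @return symmetric n x n matrix with sample-id dimnames
#' @export
compute_kinship <- function(Z) {
  M <- if (inherits(Z, "geno_matrix")) Z$calls else as.matrix(Z)
  if (ncol(M) == 0) stop("kinship undefined for zero markers")
  if (anyNA(M)) stop("encode/impute genotypes before computing kinship")
  K <- tcrossprod(M) / ncol(M)
  (K + t(K)) / 2
}

check_kinship <- function(K, tol = -1e-8) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-10) stop("kinship matrix is not symmetric")
  K
}

# Profiled restricted log-likelihood pieces at lambda, in the eigenbasis of
# K = U diag(d) U'. X and y are pre-rotated (xt = U'X, yt = U'y).
reml_profile <- function(lambda, d, xt, yt, n, q) {
  w <- 1 / (lambda * d + 1)
  A <- crossprod(xt, xt * w)              # X' V^-1 X (unit sigma2)
  b <- crossprod(xt, yt * w)              # X' V^-1 y
  c0 <- sum(w * yt^2)
  Ainv_b <- solve(A, b)
  ypy <- c0 - sum(b * Ainv_b)             # y' P y
  sigma2 <- ypy / (n - q)
  ll <- -0.5 * (sum(log(lambda * d + 1)) + determinant(A)$modulus[1] +
                  (n - q) * log(sigma2))
  list(ll = as.numeric(ll), sigma2 = sigma2, beta = Ainv_b, w = w)
}

#' Fit GBLUP by profiled REML
#'
#' Estimates the variance ratio `lambda = phi^2 / sigma^2` of the mixed
#' model `y = X beta + g + e`, `g ~ N(0, K phi^2)`, `e ~ N(0, I sigma^2)`,
#' by maximising the restricted log-likelihood with `beta` and `sigma^2`
#' profiled out by their closed-form substitutions. The search runs in
#' `theta = log(lambda)` over `lambda` in `[1e-6, 1e6]` with a safeguarded
#' Newton iteration (bisection fallback whenever a Newton step leaves the
#' current sign-change bracket); a boundary solution is reported, not an
#' error. A single eigendecomposition of `K` makes each likelihood
#' evaluation O(n).
#'
#' @param y numeric phenotype vector (length n)
#' @param K n x n kinship matrix from [compute_kinship()]
#' @param X fixed-effect design matrix; default intercept-only
#' @return object of class `gblup_fit` with elements `lambda_hat`,
#'   `sigma2_hat`, `phi2_hat`, `beta_hat`, `restricted_loglik`, `boundary`,
#'   `n`, `q`, and the training references needed by [predict_gblup()]
#' @export
reml_fit <- function(y, K, X = NULL) {
  y <- as.numeric(y)
  n <- length(y)
  K <- check_kinship(K)
  stopifnot(nrow(K) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  q <- ncol(X)
  stopifnot(nrow(X) == n, q < n, qr(X)$rank == q)
  eg <- eigen(K, symmetric = TRUE)
  d <- eg$values
  if (min(d) < -1e-6 * max(abs(d), 1))
    stop("kinship matrix is not PSD within tolerance")
  d <- pmax(d, 0)
  U <- eg$vectors
  xt <- crossprod(U, X)
  yt <- drop(crossprod(U, y))

  lo <- log(1e-6); hi <- log(1e6)
  f <- function(theta) reml_profile(exp(theta), d, xt, yt, n, q)$ll
  h <- 1e-5
  dfun <- function(theta) (f(theta + h) - f(theta - h)) / (2 * h)
  g_lo <- dfun(lo); g_hi <- dfun(hi)
  boundary <- FALSE
  if (g_lo <= 0) {            # decreasing at lower bound: boundary optimum
    theta <- lo; boundary <- TRUE
  } else if (g_hi >= 0) {
    theta <- hi; boundary <- TRUE
  } else {
    a <- lo; b <- hi
    theta <- 0
    for (it in seq_len(100)) {
      g1 <- dfun(theta)
      if (abs(g1) < 1e-10) break
      if (g1 > 0) a <- theta else b <- theta
      g2 <- (dfun(theta + h) - g1) / h        # curvature of profile ll
      step <- if (is.finite(g2) && g2 < 0) -g1 / g2 else NA_real_
      cand <- theta + step
      if (!is.finite(cand) || cand <= a || cand >= b) cand <- (a + b) / 2
      if (abs(cand - theta) < 1e-8) { theta <- cand; break }
      theta <- cand
    }
  }
  lambda <- exp(theta)
  prof <- reml_profile(lambda, d, xt, yt, n, q)
  structure(list(lambda_hat = lambda, sigma2_hat = prof$sigma2,
                 phi2_hat = lambda * prof$sigma2,
                 beta_hat = drop(prof$beta),
                 restricted_loglik = prof$ll, boundary = boundary,
                 n = n, q = q, y_train = y, X_train = X, K_train = K,
                 eigen_K = eg),
            class = "gblup_fit")
}

#' Profiled restricted log-likelihood of the variance ratio
#'
#' Evaluates the objective maximised by [reml_fit()] at given values of
#' `lambda`, via the same eigendecomposition route. Useful for grid checks
#' and profiling plots.
#'
#' @param lambda numeric vector of variance ratios (> 0)
#' @inheritParams reml_fit
#' @return numeric vector of restricted log-likelihood values (up to an
#'   additive constant)
#' @export
reml_loglik <- function(lambda, y, K, X = NULL) {
  y <- as.numeric(y); n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  q <- ncol(X)
  eg <- eigen(check_kinship(K), symmetric = TRUE)
  d <- pmax(eg$values, 0)
  xt <- crossprod(eg$vectors, X)
  yt <- drop(crossprod(eg$vectors, y))
  vapply(lambda, function(l) reml_profile(l, d, xt, yt, n, q)$ll,
         numeric(1))
}

#' Predict untested individuals from a GBLUP fit
#'
#' `y_hat = X_test beta_hat + lambda K_cross (lambda K_train + I)^{-1}
#' (y - X_train beta_hat)`: prediction through genomic relationships alone,
#' without explicit marker effects.
#'
#' @param fit a [reml_fit()] result
#' @param K_cross test x train kinship block, columns ordered as the
#'   training samples (e.g. a block of `compute_kinship()` on the stacked
#'   panel)
#' @param X_test fixed-effect design of the test individuals; default
#'   intercept-only
#' @return numeric vector of predicted phenotypes
#' @export
predict_gblup <- function(fit, K_cross, X_test = NULL) {
  K_cross <- as.matrix(K_cross)
  if (ncol(K_cross) != fit$n)
    stop("K_cross must have one column per training sample")
  if (is.null(X_test)) X_test <- matrix(1, nrow(K_cross), 1)
  X_test <- as.matrix(X_test)
  stopifnot(ncol(X_test) == fit$q)
  resid <- fit$y_train - drop(fit$X_train %*% fit$beta_hat)
  U <- fit$eigen_K$vectors
  d <- pmax(fit$eigen_K$values, 0)
  alpha <- U %*% (crossprod(U, resid) / (fit$lambda_hat * d + 1))
  drop(X_test %*% fit$beta_hat) + fit$lambda_hat * drop(K_cross %*% alpha)
}
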