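#' BayesB chain settings and mixture-prior hyperparameters
#'
#' The per-marker effect variance prior is a two-component mixture: a point
#' mass at zero with probability `pi`, and a scaled inverse chi-square
#' `(v, S)` slab otherwise, with `v = 4.234` and `S = 0.0429` as defaults.
#' `pi` itself gets a weakly informative Beta prior with mean `pi0 = 0.5`
#' and concentration `p0 = 10` (shapes `pi0 * p0` and `(1 - pi0) * p0`).
#'
#' @param v slab prior degrees of freedom
#' @param S slab prior scale
#' @param pi0 prior mean of the exclusion probability `pi`
#' @param p0 prior concentration of `pi`
#' @param n_iter,burn_in,thin chain length, burn-in, thinning interval
#' @return list of class `bayesb_hyper`
#' @export
bayesb_hyper <- function(v = 4.234, S = 0.0429, pi0 = 0.5, p0 = 10,
                         n_iter = 12000, burn_in = 2000, thin = 5) {
  stopifnot(v > 0, S > 0, pi0 > 0, pi0 < 1, p0 > 0,
            burn_in < n_iter, thin >= 1)
  structure(list(v = v, S = S, pi0 = pi0, p0 = p0,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin)),
            class = "bayesb_hyper")
}

geno_calls <- function(Z) {
  if (inherits(Z, "geno_matrix")) Z$calls else as.matrix(Z)
}

new_gs_model <- function(method, state, marker_ids, training_sample_ids) {
  structure(list(method = method, state = state, marker_ids = marker_ids,
                 training_sample_ids = training_sample_ids),
            class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cat(sprintf("gs_model [%s]: trained on %d samples x %d markers\n",
              x$method, length(x$training_sample_ids),
              length(x$marker_ids)))
  invisible(x)
}

check_new_markers <- function(model, Z_new) {
  ids <- if (inherits(Z_new, "geno_matrix")) Z_new$markers$id else
    colnames(geno_calls(Z_new))
  if (!is.null(ids) && !identical(as.character(ids), model$marker_ids)) {
    first <- which(as.character(ids) != model$marker_ids)[1]
    stop("marker mismatch with training set at position ", first,
         ": '", ids[first], "' vs '", model$marker_ids[first], "'")
  }
  M <- geno_calls(Z_new)
  if (ncol(M) != length(model$marker_ids))
    stop("marker mismatch: ", ncol(M), " columns vs ",
         length(model$marker_ids), " training markers")
  M
}

#' Fit GBLUP as a generic predictor model
#'
#' Wraps [compute_kinship()] + [reml_fit()] under the common fit/predict
#' contract shared by all six methods, so GBLUP can be used interchangeably
#' with the marker-effect and kernel learners.
#'
#' @param Z training [geno_matrix()] (or coded matrix)
#' @param y phenotype vector aligned with the rows of `Z`
#' @return a `gs_model`
#' @export
fit_gblup <- function(Z, y) {
  M <- geno_calls(Z)
  fit <- reml_fit(y, compute_kinship(M))
  new_gs_model("gblup", list(fit = fit, Z_train = M),
               colnames(M), rownames(M))
}

#' Fit the LASSO by coordinate descent with internal cross-validation
#'
#' Minimises `||y - mu - Z gamma||^2 + lambda * sum |gamma_k|` along a
#' log-spaced lambda path (coordinate descent with warm starts); the
#' returned model uses the lambda minimising the internal k-fold
#' cross-validated mean squared error. Marker columns are standardised
#' internally and effects back-transformed, so exact zeros are preserved on
#' the original scale.
#'
#' @param Z training genotypes
#' @param y phenotype vector (must vary)
#' @param cv_folds internal CV folds for the shrinkage parameter
#' @param n_lambda path length
#' @param lambda optional fixed penalty (skips CV)
#' @param lambda_min_ratio path floor as a fraction of the smallest
#'   all-zero penalty
#' @param seed seed for the internal fold split
#' @return a `gs_model` with marker effects (`state$gamma`), intercept and
#'   chosen `lambda`
#' @export
fit_lasso <- function(Z, y, cv_folds = 5, n_lambda = 50, lambda = NULL,
                      lambda_min_ratio = 1e-3, seed = 1) {
  M <- geno_calls(Z)
  y <- as.numeric(y)
  n <- nrow(M)
  stopifnot(n >= 10 || !is.null(lambda), length(y) == n)
  if (sd(y) == 0) stop("degenerate phenotype: zero variance")
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  yc <- y - mean(y)
  lambda_max <- 2 * max(abs(crossprod(Xs, yc)))
  path <- if (is.null(lambda))
    exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
            length.out = n_lambda))
  else lambda
  if (is.null(lambda) && length(path) > 1) {
    set.seed(seed_stream(seed, "lasso-cv"))
    fold <- kfold_partition(n, cv_folds)$fold_of
    mse <- matrix(NA_real_, cv_folds, length(path))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      Xt <- Xs[tr, , drop = FALSE]
      yt <- yc[tr]
      ytc <- yt - mean(yt)
      B <- lasso_cd_path(sweep(Xt, 2, colMeans(Xt)), ytc, path)
      pred <- sweep(Xs[!tr, , drop = FALSE], 2, colMeans(Xt)) %*% B +
        mean(yt) + mean(y)
      mse[f, ] <- colMeans((y[!tr] - pred)^2)
    }
    best <- which.min(colMeans(mse))
    lam <- path[best]
  } else lam <- path[1]
  B <- lasso_cd_path(Xs, yc, lam)
  gamma_std <- drop(B)
  gamma <- gamma_std / scl
  intercept <- mean(y) - sum(gamma * ctr)
  new_gs_model("lasso",
               list(gamma = gamma, intercept = intercept, lambda = lam,
                    lambda_path = path),
               colnames(M), rownames(M))
}

#' Fit BayesB by collapsed Gibbs sampling
#'
#' Marker effects follow the mixture prior of [bayesb_hyper()]; indicators
#' are updated with the marker effect integrated out, then effect, slab
#' variance, mixture weight and residual variance are drawn in turn.
#' Raw genotype codes are used (no standardisation). Fixing the seed makes
#' the chain bit-reproducible.
#'
#' @param Z training genotypes
#' @param y phenotype vector
#' @param hyper a [bayesb_hyper()]
#' @param seed chain seed
#' @return a `gs_model` with posterior-mean effects (`state$gamma`),
#'   intercept, per-marker inclusion probabilities and posterior mean of
#'   the exclusion probability `pi`
#' @export
fit_bayesb <- function(Z, y, hyper = bayesb_hyper(), seed = 1) {
  M <- geno_calls(Z)
  y <- as.numeric(y)
  stopifnot(nrow(M) >= 10, length(y) == nrow(M),
            inherits(hyper, "bayesb_hyper"))
  set.seed(seed_stream(seed, "bayesb-chain"))
  res <- bayesb_gibbs(M, y, hyper$v, hyper$S, hyper$pi0, hyper$p0,
                      hyper$n_iter, hyper$burn_in, hyper$thin)
  new_gs_model("bayesb",
               list(gamma = drop(res$gamma_mean),
                    intercept = res$mu_mean,
                    inclusion = drop(res$inclusion),
                    pi_mean = res$pi_mean, sigma2_mean = res$sigma2_mean,
                    hyper = hyper, seed = seed),
               colnames(M), rownames(M))
}

#' Fit PLS1 regression with cross-validated component count
#'
#' Standard PLS1: successive covariance-maximising directions with
#' deflation of the predictor matrix, on internally standardised marker
#' columns. The number of components is the minimiser of the internal
#' k-fold cross-validated RMSE over `1..max_components`.
#'
#' @param Z training genotypes
#' @param y phenotype vector (must vary)
#' @param max_components upper bound on components
#'   (capped at `min(n - 1, m)`)
#' @param cv_folds internal CV folds
#' @param n_components optional fixed component count (skips CV)
#' @param seed seed for the internal fold split
#' @return a `gs_model`; the fitted state stores the regression
#'   coefficients implied by the chosen components plus weights, loadings
#'   and scores
#' @export
fit_pls <- function(Z, y, max_components = 20, cv_folds = 5,
                    n_components = NULL, seed = 1) {
  M <- geno_calls(Z)
  y <- as.numeric(y)
  n <- nrow(M)
  if (sd(y) == 0) stop("degenerate phenotype: zero variance")
  max_components <- min(max_components, n - 1, ncol(M))
  stopifnot(max_components >= 1)
  if (is.null(n_components)) {
    set.seed(seed_stream(seed, "pls-cv"))
    fold <- kfold_partition(n, min(cv_folds, n))$fold_of
    sse <- matrix(0, max(fold), max_components)
    for (f in seq_len(max(fold))) {
      tr <- fold != f
      fit <- pls1_core(M[tr, , drop = FALSE], y[tr], max_components)
      for (a in seq_len(ncol(fit$coef_by_ncomp))) {
        pred <- M[!tr, , drop = FALSE] %*% fit$coef_by_ncomp[, a] +
          fit$intercept_by_ncomp[a]
        sse[f, a] <- sum((y[!tr] - pred)^2)
      }
    }
    n_components <- which.min(colSums(sse))
  }
  fit <- pls1_core(M, y, max_components)
  a <- min(n_components, ncol(fit$coef_by_ncomp))
  new_gs_model("pls",
               list(gamma = fit$coef_by_ncomp[, a],
                    intercept = fit$intercept_by_ncomp[a],
                    n_components = a, scores = fit$scores[, seq_len(a),
                                                          drop = FALSE]),
               colnames(M), rownames(M))
}

# PLS1 (NIPALS with deflation of X only) on standardised columns; returns
# original-scale coefficients for every component count up to ncomp.
pls1_core <- function(M, y, ncomp) {
  n <- nrow(M); m <- ncol(M)
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd); scl[scl == 0] <- 1
  X <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  yc <- y - mean(y)
  W <- P <- matrix(0, m, ncomp)
  Tm <- matrix(0, n, ncomp)
  qv <- numeric(ncomp)
  Xd <- X
  used <- 0
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(Xd %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    p <- drop(crossprod(Xd, t)) / tt
    q <- sum(t * yc) / tt
    Xd <- Xd - tcrossprod(t, p)
    W[, a] <- w; P[, a] <- p; Tm[, a] <- t; qv[a] <- q
    used <- a
  }
  if (used == 0) stop("no usable PLS component (constant predictors?)")
  coef_std <- matrix(0, m, used)
  for (a in seq_len(used)) {
    Wa <- W[, seq_len(a), drop = FALSE]
    Pa <- P[, seq_len(a), drop = FALSE]
    R <- Wa %*% solve(crossprod(Pa, Wa))
    coef_std[, a] <- drop(R %*% qv[seq_len(a)])
  }
  coef <- coef_std / scl
  intercept <- mean(y) - drop(crossprod(coef, ctr))
  list(coef_by_ncomp = coef, intercept_by_ncomp = intercept, scores = Tm)
}

gaussian_kernel <- function(A, B, h) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * h^2))
}

#' Fit epsilon-insensitive support vector regression with a Gaussian kernel
#'
#' Solves the SVR dual by pairwise (SMO-style) coordinate ascent on the
#' kernel `exp(-||z_i - z_j||^2 / (2 h^2))`. Marker columns are
#' standardised internally. `bandwidth = "auto"` uses the median pairwise
#' Euclidean distance heuristic.
#'
#' @param Z training genotypes
#' @param y phenotype vector
#' @param C box constraint (> 0)
#' @param epsilon insensitive-tube half-width; default `0.1 * sd(y)`
#' @param bandwidth kernel bandwidth `h`, or `"auto"`
#' @param tol KKT violation tolerance of the dual solver
#' @return a `gs_model` with support coefficients, intercept, bandwidth and
#'   the dual objective value
#' @export
fit_svm_gauss <- function(Z, y, C = 1, epsilon = NULL, bandwidth = "auto",
                          tol = 1e-3) {
  M <- geno_calls(Z)
  y <- as.numeric(y)
  stopifnot(C > 0, nrow(M) == length(y))
  if (is.null(epsilon)) epsilon <- 0.1 * sd(y)
  stopifnot(epsilon >= 0)
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  if (identical(bandwidth, "auto")) {
    d2 <- dist(Xs)
    bandwidth <- median(d2)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  Q <- gaussian_kernel(Xs, Xs, bandwidth)
  if (any(!is.finite(Q))) stop("non-finite kernel entries")
  sol <- svr_smo(Q, y, C, epsilon, tol)
  new_gs_model("svm",
               list(beta = drop(sol$beta), b = sol$b,
                    objective = sol$objective, bandwidth = bandwidth,
                    C = C, epsilon = epsilon, center = ctr, scale = scl,
                    X_train = Xs),
               colnames(M), rownames(M))
}

#' Fit multi-kernel RKHS regression by Gibbs sampling
#'
#' Bayesian kernel regression `y = mu + sum_l u_l + e` with
#' `u_l ~ N(0, K_l s2_l)`, one Gaussian kernel per bandwidth
#' `h_l = multiplier x mean squared pairwise distance`
#' (`K_l = exp(-D^2 / h_l)`). Each kernel is eigendecomposed once and the
#' chain samples the kernel coefficients in the eigenbasis, with scaled
#' inverse chi-square updates for the variance components. With
#' `fix_ratio` supplied (a single kernel and a fixed `s2_l / s2` ratio) the
#' exact conditional posterior mean is returned instead of sampling, which
#' is the kernel-substituted GBLUP formula.
#'
#' @param Z training genotypes
#' @param y phenotype vector
#' @param bandwidth_multipliers numeric vector of kernel bandwidth
#'   multipliers
#' @param n_iter,burn_in,thin chain settings
#' @param seed chain seed
#' @param fix_ratio optional fixed variance ratio (single kernel only;
#'   deterministic closed-form posterior mean)
#' @return a `gs_model` storing per-kernel weight vectors
#'   `alpha_l = K_l^{-1} E[u_l | y]`, bandwidths, posterior variance
#'   component means and the training predictor matrix
#' @export
fit_rkhs <- function(Z, y, bandwidth_multipliers = c(0.2, 1, 5),
                     n_iter = 6000, burn_in = 1000, thin = 5, seed = 1,
                     fix_ratio = NULL) {
  M <- geno_calls(Z)
  y <- as.numeric(y)
  n <- nrow(M)
  stopifnot(length(bandwidth_multipliers) >= 1, length(y) == n)
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(Xs^2), "+") - 2 * tcrossprod(Xs)
  d2[d2 < 0] <- 0
  msd <- mean(d2)
  hs <- bandwidth_multipliers * msd
  Ks <- lapply(hs, function(h) exp(-d2 / h))
  eig <- lapply(Ks, function(K) {
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    if (min(eg$values) < -1e-6) stop("RKHS kernel not PSD within tolerance")
    keep <- eg$values > 1e-10
    list(U = eg$vectors[, keep, drop = FALSE], d = eg$values[keep])
  })
  L <- length(Ks)

  if (!is.null(fix_ratio)) {
    stopifnot(L == 1)
    K <- Ks[[1]]
    lam <- fix_ratio
    Vinv <- solve(lam * K + diag(n))
    one <- rep(1, n)
    mu <- drop(crossprod(one, Vinv %*% y) / crossprod(one, Vinv %*% one))
    alpha <- lam * Vinv %*% (y - mu)
    return(new_gs_model("rkhs",
      list(alpha = list(drop(alpha)), mu = mu, bandwidths = hs,
           multipliers = bandwidth_multipliers, center = ctr, scale = scl,
           X_train = Xs, fixed_ratio = lam),
      colnames(M), rownames(M)))
  }

  set.seed(seed_stream(seed, "rkhs-chain"))
  df0 <- 5
  S0_u <- 0.5 * var(y) / L * (df0 + 2)
  S0_e <- 0.5 * var(y) * (df0 + 2)
  a_l <- lapply(eig, function(e) numeric(length(e$d)))
  s2_l <- rep(0.5 * var(y) / L, L)
  sigma2 <- 0.5 * var(y)
  mu <- mean(y)
  u <- matrix(0, n, L)
  alpha_sum <- lapply(eig, function(e) numeric(n))
  mu_sum <- 0; s2l_sum <- numeric(L); s2_sum <- 0; kept <- 0
  for (it in seq_len(n_iter)) {
    mu <- mean(y - rowSums(u)) + rnorm(1, sd = sqrt(sigma2 / n))
    for (l in seq_len(L)) {
      r <- y - mu - rowSums(u[, -l, drop = FALSE])
      rt <- drop(crossprod(eig[[l]]$U, r))
      pv <- 1 / (1 / sigma2 + 1 / (eig[[l]]$d * s2_l[l]))
      a_l[[l]] <- rnorm(length(rt), mean = pv * rt / sigma2,
                        sd = sqrt(pv))
      u[, l] <- drop(eig[[l]]$U %*% a_l[[l]])
      quad <- sum(a_l[[l]]^2 / eig[[l]]$d)
      s2_l[l] <- (quad + df0 * S0_u) / rchisq(1, length(a_l[[l]]) + df0)
    }
    e <- y - mu - rowSums(u)
    sigma2 <- (sum(e^2) + df0 * S0_e) / rchisq(1, n + df0)
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1
      mu_sum <- mu_sum + mu
      s2l_sum <- s2l_sum + s2_l
      s2_sum <- s2_sum + sigma2
      for (l in seq_len(L))
        alpha_sum[[l]] <- alpha_sum[[l]] +
          drop(eig[[l]]$U %*% (a_l[[l]] / eig[[l]]$d))
    }
  }
  new_gs_model("rkhs",
               list(alpha = lapply(alpha_sum, `/`, kept),
                    mu = mu_sum / kept, bandwidths = hs,
                    multipliers = bandwidth_multipliers,
                    s2_kernel = s2l_sum / kept, sigma2 = s2_sum / kept,
                    center = ctr, scale = scl, X_train = Xs, seed = seed),
               colnames(M), rownames(M))
}

#' Predict phenotypes for new genotypes from any fitted model
#'
#' Uniform prediction contract over all six methods. `Z_new` must carry the
#' training markers in the training order; a mismatch names the first
#' discrepancy. Linear-effect models return
#' `intercept + Z_new %*% gamma`; GBLUP predicts through the cross-kinship
#' block; kernel models evaluate their kernels between new and training
#' rows.
#'
#' @param object a `gs_model`
#' @param Z_new a [geno_matrix()] (or coded matrix) over the training
#'   markers
#' @param ... unused
#' @return numeric vector of predictions, one per row of `Z_new`
#' @export
predict.gs_model <- function(object, Z_new, ...) {
  M <- check_new_markers(object, Z_new)
  if (nrow(M) == 0) return(numeric(0))
  st <- object$state
  out <- switch(object$method,
    gblup = {
      K_cross <- tcrossprod(M, st$Z_train) / ncol(M)
      predict_gblup(st$fit, K_cross)
    },
    lasso = ,
    bayesb = ,
    pls = drop(M %*% st$gamma) + st$intercept,
    svm = {
      Xn <- sweep(sweep(M, 2, st$center), 2, st$scale, "/")
      drop(gaussian_kernel(Xn, st$X_train, st$bandwidth) %*% st$beta) +
        st$b
    },
    rkhs = {
      Xn <- sweep(sweep(M, 2, st$center), 2, st$scale, "/")
      d2 <- outer(rowSums(Xn^2), rowSums(st$X_train^2), "+") -
        2 * tcrossprod(Xn, st$X_train)
      d2[d2 < 0] <- 0
      pred <- rep(st$mu, nrow(Xn))
      for (l in seq_along(st$alpha))
        pred <- pred + drop(exp(-d2 / st$bandwidths[l]) %*% st$alpha[[l]])
      pred
    },
    stop("unknown method: ", object$method))
  if (any(!is.finite(out))) stop("non-finite predictions")
  unname(out)
}

#' Fit a genomic prediction model by method name
#'
#' Dispatch layer used by [cross_validate()] and the workflow driver:
#' `"gblup"`, `"lasso"`, `"bayesb"`, `"pls"`, `"svm"` or `"rkhs"`, each
#' forwarded to its `fit_*` function with `control` as extra arguments.
#'
#' @param method method name
#' @param Z training genotypes
#' @param y phenotype vector
#' @param control named list of method-specific arguments
#' @return a `gs_model`
#' @export
fit_gs_model <- function(method, Z, y, control = list()) {
  method <- match.arg(method,
                      c("gblup", "lasso", "bayesb", "pls", "svm", "rkhs"))
  fn <- switch(method, gblup = fit_gblup, lasso = fit_lasso,
               bayesb = fit_bayesb, pls = fit_pls,
               svm = fit_svm_gauss, rkhs = fit_rkhs)
  do.call(fn, c(list(Z, y), control))
}
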