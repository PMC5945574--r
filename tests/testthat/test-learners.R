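test_that("lasso: saturation, orthogonal closed form, and glmnet agreement", {
  g <- random_homozygous(40, 30, seed = 21)
  sim <- simulate_additive_y(g, 0.7, 10, seed = 22)
  # huge penalty: all effects zero, prediction = mean(y)
  m_big <- fit_lasso(g, sim$y, lambda = 1e9)
  expect_true(all(m_big$state$gamma == 0))
  expect_equal(predict(m_big, g), rep(mean(sim$y), 40), tolerance = 1e-12)

  # orthogonal mean-zero design: soft-threshold closed form at lambda/2
  n <- 8
  Hm <- contr.helmert(n)[, 1:5]                    # orthogonal, sums to 0
  X <- apply(Hm, 2, function(x) x / sd(x))         # unit sd keeps orthogonality
  colnames(X) <- paste0("M", 1:5)
  set.seed(23)
  y <- drop(X %*% c(2, -1.5, 0.2, 0, 0)) + rnorm(n, sd = 0.3)
  lam <- 4
  fit <- fit_lasso(X, y, lambda = lam)
  yc <- y - mean(y)
  zz <- colSums(X^2)
  rho <- drop(crossprod(X, yc))
  expected <- sign(rho) * pmax(abs(rho) - lam / 2, 0) / zz
  expect_equal(unname(fit$state$gamma), unname(expected), tolerance = 1e-6)

  # glmnet solves the same objective (columns pre-standardised)
  Xs <- scale(g$calls)
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  lam2 <- 8
  ours <- fit_lasso(Xs, sim$y, lambda = lam2)
  gl <- glmnet::glmnet(Xs, sim$y, lambda = lam2 / (2 * 40),
                       standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(ours$state$gamma), unname(drop(coef(gl))[-1]),
               tolerance = 1e-4)
  expect_equal(ours$state$intercept, drop(coef(gl))[1], tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("lasso recovers most true QTL in a sparse architecture", {
  found <- vapply(1:10, function(rep) {
    g <- random_homozygous(250, 500, seed = 300 + rep)
    set.seed(400 + rep)
    qtl <- sample.int(500, 10)
    gval <- drop(g$calls[, qtl] %*% rnorm(10, sd = 1))
    gval <- (gval - mean(gval)) / sd(gval)
    y <- gval + rnorm(250, sd = sqrt(0.3 / 0.7))
    fit <- fit_lasso(g, y, seed = rep)
    sum(qtl %in% which(fit$state$gamma != 0))
  }, numeric(1))
  expect_gte(median(found), 8)
})

test_that("pls: rank-1 case, orthogonal scores, and OLS saturation", {
  # m = 1: prediction is the simple linear regression on that marker
  set.seed(31)
  x <- rnorm(25)
  y <- 1.5 * x + rnorm(25, sd = 0.4)
  X1 <- matrix(x, 25, 1, dimnames = list(NULL, "M1"))
  fit1 <- fit_pls(X1, y)
  lmfit <- lm(y ~ x)
  expect_equal(predict(fit1, X1), unname(fitted(lmfit)), tolerance = 1e-8)

  # scores mutually orthogonal on random data
  g <- random_homozygous(30, 50, seed = 32)
  sim <- simulate_additive_y(g, 0.6, 15, seed = 33)
  fit <- fit_pls(g, sim$y, max_components = 8, n_components = 8)
  Tm <- fit$state$scores
  G <- crossprod(Tm)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)

  # full-rank n > m with all components: equals OLS fitted values
  g2 <- random_homozygous(40, 10, seed = 34)
  sim2 <- simulate_additive_y(g2, 0.8, 5, seed = 35)
  fit_full <- fit_pls(g2, sim2$y, max_components = 10, n_components = 10)
  ols <- lm(sim2$y ~ g2$calls)
  expect_equal(predict(fit_full, g2), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("bayesb: seeded chains are bit-reproducible", {
  g <- random_homozygous(60, 80, seed = 41)
  sim <- simulate_additive_y(g, 0.6, 10, seed = 42)
  hyp <- bayesb_hyper(n_iter = 600, burn_in = 200, thin = 2)
  f1 <- fit_bayesb(g, sim$y, hyp, seed = 7)
  f2 <- fit_bayesb(g, sim$y, hyp, seed = 7)
  expect_identical(f1$state$gamma, f2$state$gamma)
  expect_identical(f1$state$inclusion, f2$state$inclusion)
  f3 <- fit_bayesb(g, sim$y, hyp, seed = 8)
  expect_false(identical(f1$state$gamma, f3$state$gamma))
})

test_that("svm: Gaussian kernel properties, tube saturation, and dual optimality", {
  g <- random_homozygous(25, 40, seed = 51)
  sim <- simulate_additive_y(g, 0.7, 10, seed = 52)
  # epsilon wider than the centred response range: constant prediction
  m_wide <- fit_svm_gauss(g, sim$y, epsilon = diff(range(sim$y)) + 1)
  expect_true(all(m_wide$state$beta == 0))
  expect_equal(sd(predict(m_wide, g)), 0)

  # dual objective matches libsvm (e1071) on a pre-standardised instance
  Xs <- scale(random_homozygous(30, 6, seed = 53)$calls)
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  colnames(Xs) <- paste0("M", 1:6)
  set.seed(54)
  y <- drop(Xs %*% rnorm(6)) + rnorm(30, sd = 0.3)
  h <- 2
  ours <- fit_svm_gauss(Xs, y, C = 2, epsilon = 0.2,
                        bandwidth = h, tol = 1e-5)
  ref <- e1071::svm(Xs, y, type = "eps-regression", kernel = "radial",
                    gamma = 1 / (2 * h^2), cost = 2, epsilon = 0.2,
                    scale = FALSE, tolerance = 1e-6)
  Q <- exp(-as.matrix(dist(Xs))^2 / (2 * h^2))
  beta_ref <- numeric(30)
  beta_ref[ref$index] <- ref$coefs
  dual_obj <- function(b) -0.5 * drop(crossprod(b, Q %*% b)) +
    sum(y * b) - 0.2 * sum(abs(b))
  expect_equal(ours$state$objective, dual_obj(beta_ref), tolerance = 1e-3)
  expect_equal(predict(ours, Xs),
               unname(predict(ref, Xs)), tolerance = 0.02)
})

test_that("rkhs: fixed-ratio posterior mean equals kernel-substituted GBLUP", {
  g <- random_homozygous(40, 60, seed = 61)
  sim <- simulate_additive_y(g, 0.7, 15, seed = 62)
  lam <- 2.5
  fit <- fit_rkhs(g, sim$y, bandwidth_multipliers = 1, fix_ratio = lam)
  # closed-form single-kernel BLUP with the Gaussian kernel in place of K
  Xs <- scale(g$calls)
  d2 <- as.matrix(dist(Xs))^2
  K <- exp(-d2 / mean(d2))
  n <- 40
  Vinv <- solve(lam * K + diag(n))
  one <- rep(1, n)
  mu <- drop(crossprod(one, Vinv %*% sim$y) / crossprod(one, Vinv %*% one))
  manual <- mu + lam * drop(K %*% Vinv %*% (sim$y - mu))
  expect_equal(predict(fit, g), manual, tolerance = 1e-6,
               ignore_attr = TRUE)

  # seeded chain reproducibility
  f1 <- fit_rkhs(g, sim$y, n_iter = 300, burn_in = 100, seed = 3)
  f2 <- fit_rkhs(g, sim$y, n_iter = 300, burn_in = 100, seed = 3)
  expect_identical(f1$state$alpha, f2$state$alpha)
})

test_that("the fit/predict contract is uniform across methods", {
  g <- random_homozygous(30, 40, seed = 71)
  sim <- simulate_additive_y(g, 0.7, 10, seed = 72)
  models <- list(
    fit_gblup(g, sim$y),
    fit_lasso(g, sim$y, seed = 1),
    fit_pls(g, sim$y, max_components = 5),
    fit_svm_gauss(g, sim$y),
    fit_bayesb(g, sim$y, bayesb_hyper(n_iter = 400, burn_in = 100), seed = 1),
    fit_rkhs(g, sim$y, n_iter = 300, burn_in = 100, seed = 1))
  set.seed(73)
  perm <- sample(30)
  for (m in models) {
    p <- predict(m, g)
    expect_length(p, 30)
    expect_true(all(is.finite(p)))
    # permuting rows permutes predictions identically
    g_perm <- g
    g_perm$calls <- g$calls[perm, ]
    expect_equal(predict(m, g_perm), p[perm], tolerance = 1e-12)
    # empty input -> empty output
    g0 <- g
    g0$calls <- g$calls[integer(0), , drop = FALSE]
    expect_length(predict(m, g0), 0)
    # marker mismatch names the first discrepancy
    g_bad <- subset_geno(g, markers = c(2:40, 1))
    expect_error(predict(m, g_bad), "marker mismatch")
  }
})

test_that("linear learners are equivariant to marker-order permutation", {
  g <- random_homozygous(35, 30, seed = 81)
  sim <- simulate_additive_y(g, 0.7, 8, seed = 82)
  set.seed(83)
  pidx <- sample(30)
  g_perm <- subset_geno(g, markers = pidx)
  for (method in c("gblup", "pls")) {
    m1 <- fit_gs_model(method, g, sim$y, list())
    m2 <- fit_gs_model(method, g_perm, sim$y, list())
    expect_equal(predict(m2, g_perm), predict(m1, g), tolerance = 1e-6)
  }
  l1 <- fit_lasso(g, sim$y, lambda = 5)
  l2 <- fit_lasso(g_perm, sim$y, lambda = 5)
  expect_equal(predict(l2, g_perm), predict(l1, g), tolerance = 1e-4)
})
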