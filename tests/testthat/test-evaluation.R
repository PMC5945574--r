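test_that("k-fold partitions are balanced, disjoint and seed-deterministic", {
  f <- kfold_partition(10, 5, seed = 1)
  expect_equal(as.vector(table(f$fold_of)), rep(2L, 5))
  f575 <- kfold_partition(575, 5, seed = 2)
  expect_equal(as.vector(table(f575$fold_of)), rep(115L, 5))
  expect_identical(kfold_partition(575, 5, seed = 2)$fold_of, f575$fold_of)
  expect_error(kfold_partition(3, 5), "n >= k")
})

test_that("predictability is the Pearson correlation", {
  x <- c(2, 4, 1, 7, 5)
  expect_equal(predictability(x, x), 1)
  expect_equal(predictability(x, -x), -1)
  expect_equal(predictability(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_error(predictability(rep(1, 5), x), "constant")
})

test_that("cross-validation pools out-of-fold predictions once per sample", {
  arch <- list(trait_architecture("T1", target_H = 1, n_qtl = 30))
  b <- small_bundle(n_females = 10, n_males = 3, n_markers = 120,
                    traits = arch)
  y <- b$pheno_means[, "T1"]
  truth <- b$truth$T1$g
  # oracle upper bound: true genetic values predict perfectly at H = 1
  cv <- cross_validate("oracle", b$hybrids, y, replicates = 2, seed = 4,
                       oracle = truth, trait = "T1")
  expect_equal(cv$summary$mean, 1, tolerance = 1e-12)
  expect_equal(nrow(cv$records), 2L)
  expect_true(all(cv$records$r >= -1 & cv$records$r <= 1))
})

test_that("higher-heritability traits are more predictable under GBLUP CV", {
  archs <- list(hi = trait_architecture("hi", 0.85, n_qtl = 60),
                lo = trait_architecture("lo", 0.30, n_qtl = 60))
  b <- small_bundle(n_females = 40, n_males = 5, n_markers = 400,
                    seed = 19, traits = archs)
  cv_hi <- cross_validate("gblup", b$hybrids, b$pheno_means[, "hi"],
                          replicates = 3, seed = 5, trait = "hi")
  cv_lo <- cross_validate("gblup", b$hybrids, b$pheno_means[, "lo"],
                          replicates = 3, seed = 5, trait = "lo")
  expect_gt(mean(cv_hi$records$r), mean(cv_lo$records$r))
})

test_that("predictability ANOVA has factorial df and exact SS decomposition", {
  # balanced 8 x 6 x 20 factorial
  set.seed(6)
  recs <- expand.grid(trait = paste0("t", 1:8), method = paste0("m", 1:6),
                      replicate = 1:20, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  recs$r <- runif(nrow(recs), 0.3, 0.9)
  tab <- predictability_anova(cv_result(recs))
  expect_equal(tab$df, c(7, 5, 35, 912))
  expect_equal(sum(tab$SS[1:3]) + tab$SS[4],
               sum((recs$r - mean(recs$r))^2), tolerance = 1e-8)

  # all records equal -> all SS zero
  recs0 <- recs
  recs0$r <- 0.5
  tab0 <- predictability_anova(cv_result(recs0))
  expect_equal(tab0$SS, rep(0, 4), tolerance = 1e-20)

  # 2 x 2 x 3 toy: SS match the brute-force mean decomposition
  toy <- expand.grid(trait = c("a", "b"), method = c("x", "y"),
                     replicate = 1:3, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)
  set.seed(7)
  toy$r <- runif(12)
  tt <- predictability_anova(cv_result(toy))
  gm <- mean(toy$r)
  mt <- tapply(toy$r, toy$trait, mean)
  mm <- tapply(toy$r, toy$method, mean)
  mtm <- tapply(toy$r, list(toy$trait, toy$method), mean)
  ss_t <- 6 * sum((mt - gm)^2)
  ss_m <- 6 * sum((mm - gm)^2)
  ss_i <- 3 * sum((mtm - outer(mt, rep(1, 2)) -
                     outer(rep(1, 2), mm) + gm)^2)
  ss_r <- sum((toy$r - mtm[cbind(factor(toy$trait), factor(toy$method))])^2)
  expect_equal(tt$SS, c(ss_t, ss_m, ss_i, ss_r), tolerance = 1e-10)
  expect_equal(tt$df, c(1, 1, 1, 8))
  expect_error(predictability_anova(cv_result(toy[-1, ])), "unbalanced")
})

test_that("Tukey letter groups separate exactly the significant level pairs", {
  set.seed(8)
  base <- expand.grid(method = c("m1", "m2", "m3"), replicate = 1:15,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$trait <- "t"
  # m1 and m2 identical distributions, m3 shifted by 10 x noise scale
  noise <- rnorm(nrow(base), sd = 0.01)
  base$r <- 0.5 + noise + ifelse(base$method == "m3", 0.3, 0)
  tg <- tukey_groups(cv_result(base), "method")
  l_of <- setNames(tg$letters, tg$level)
  expect_equal(l_of[["m1"]], l_of[["m2"]])          # share their letter
  expect_false(grepl(l_of[["m3"]], l_of[["m1"]], fixed = TRUE))

  # 4-level toy: letter sharing agrees with stats::TukeyHSD
  set.seed(9)
  toy <- expand.grid(method = paste0("m", 1:4), replicate = 1:12,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  toy$trait <- "t"
  toy$r <- 0.4 + c(m1 = 0, m2 = 0.01, m3 = 0.06, m4 = 0.2)[toy$method] +
    rnorm(nrow(toy), sd = 0.02)
  tg2 <- tukey_groups(cv_result(toy), "method")
  fit <- aov(r ~ method, data = transform(toy, method = factor(method)))
  hsd <- TukeyHSD(fit)$method
  shares_letter <- function(a, b) {
    la <- strsplit(tg2$letters[tg2$level == a], "")[[1]]
    lb <- strsplit(tg2$letters[tg2$level == b], "")[[1]]
    length(intersect(la, lb)) > 0
  }
  for (pair in rownames(hsd)) {
    ab <- strsplit(pair, "-")[[1]]
    expect_identical(!shares_letter(ab[1], ab[2]),
                     hsd[pair, "p adj"] < 0.05,
                     info = pair)
  }
})

test_that("subsampling at the full size reproduces plain cross-validation", {
  arch <- list(tr = trait_architecture("tr", 0.7, n_qtl = 50))
  b <- small_bundle(n_females = 15, n_males = 4, n_markers = 200,
                    seed = 23, traits = arch)
  y <- b$pheno_means[, "tr"]
  full <- cross_validate("gblup", b$hybrids, y, replicates = 8, seed = 3)
  sub <- subsample_experiment("individuals", n_samples(b$hybrids),
                              selections_per_size = 8, "gblup",
                              b$hybrids, y, seed = 3)
  pooled_sd <- sqrt((sd(full$records$r)^2 + sub$sd^2) / 2)
  expect_lt(abs(sub$mean - mean(full$records$r)), 2 * pooled_sd)
  expect_error(subsample_experiment("markers", 10^6, 2, "gblup",
                                    b$hybrids, y),
               "exceeds")
})

test_that("broad-sense heritability estimators recover the variance structure", {
  # no GxE, no residual -> H = 1 exactly
  arch1 <- trait_architecture("t", target_H = 1, n_qtl = 40)
  b <- small_bundle(n_females = 25, n_males = 4, n_markers = 150,
                    seed = 29, traits = list(arch1))
  vc1 <- estimate_broad_sense_H(b$pheno[b$pheno$trait == "t", ])
  expect_gt(vc1$H, 0.99)

  # closed-form case: (s2_g, s2_ge, s2_eps) = (1, 0.5, 1), e = r = 2
  set.seed(30)
  n_g <- 300
  lay <- expand.grid(hybrid_id = sprintf("h%03d", 1:n_g),
                     environment = c("E1", "E2"), replicate = 1:2,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g_eff <- setNames(rnorm(n_g, sd = 1), sprintf("h%03d", 1:n_g))
  ge_eff <- matrix(rnorm(n_g * 2, sd = sqrt(0.5)), n_g, 2,
                   dimnames = list(sprintf("h%03d", 1:n_g), c("E1", "E2")))
  lay$value <- g_eff[lay$hybrid_id] +
    ge_eff[cbind(lay$hybrid_id, lay$environment)] + rnorm(nrow(lay))
  vc <- estimate_broad_sense_H(lay)
  expect_lt(abs(vc$H - 2 / 3), 0.1)
  # invariant to shift and scale
  lay2 <- lay
  lay2$value <- 100 + 7 * lay$value
  expect_equal(estimate_broad_sense_H(lay2)$H, vc$H, tolerance = 1e-10)
  # mean squares agree with stats::aov on the same data
  fit <- aov(value ~ hybrid_id * environment,
             data = transform(lay, hybrid_id = factor(hybrid_id),
                              environment = factor(environment)))
  ms <- summary(fit)[[1]][, "Mean Sq"]
  expect_equal(unname(vc$mean_squares[c("G", "E", "GE", "residual")]),
               unname(ms), tolerance = 1e-8)

  # destroying the genotype signal drives H to ~0
  set.seed(31)
  lay3 <- lay
  for (env in c("E1", "E2")) for (rp in 1:2) {
    sel <- lay3$environment == env & lay3$replicate == rp
    lay3$value[sel] <- sample(lay3$value[sel])
  }
  expect_lt(estimate_broad_sense_H(lay3)$H, 0.15)

  expect_error(estimate_broad_sense_H(lay[lay$environment == "E1", ]),
               "environments")
  expect_error(estimate_broad_sense_H(lay[lay$replicate == 1, ]),
               "replicates")
})
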