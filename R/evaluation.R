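#' Balanced random k-fold partition
#'
#' Uniformly random assignment of `n` samples to `k` folds whose sizes
#' differ by at most one; deterministic given the seed.
#'
#' @param n sample count
#' @param k fold count (`2 <= k <= n`)
#' @param seed optional integer seed (no seeding when `NULL`)
#' @return list of class `fold_assignment` with `n`, `k`, `fold_of`
#'   (integer vector in `1..k`) and `seed`
#' @export
kfold_partition <- function(n, k, seed = NULL) {
  stopifnot(k >= 2, n >= k)
  if (!is.null(seed)) set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k), n))
  structure(list(n = n, k = k, fold_of = fold_of, seed = seed),
            class = "fold_assignment")
}

#' Predictability: correlation of observed and predicted phenotypes
#'
#' @param observed,predicted numeric vectors of equal length (>= 3), both
#'   non-constant
#' @return Pearson correlation coefficient
#' @export
predictability <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (sd(observed) == 0 || sd(predicted) == 0)
    stop("predictability undefined for constant input")
  cor(observed, predicted)
}

#' Replicated k-fold cross-validation predictability
#'
#' Per replicate a fresh balanced fold partition is drawn; every fold is
#' predicted once by a model trained on the remaining folds, and one
#' predictability is computed on the pooled out-of-fold predictions of all
#' samples. The summary averages the per-replicate correlations. The
#' special method `"oracle"` predicts with externally supplied true genetic
#' values (a test hook bounding what any learner can achieve).
#'
#' @param method method name for [fit_gs_model()], or `"oracle"`
#' @param geno training [geno_matrix()]
#' @param pheno phenotype vector aligned with `geno` rows (or named by
#'   sample id)
#' @param k folds (default 5)
#' @param replicates number of CV replicates (default 20)
#' @param seed master seed; each replicate uses a derived stream
#' @param control method options forwarded to [fit_gs_model()]
#' @param oracle true genetic values for `method = "oracle"`
#' @param trait trait label stored in the records
#' @return object of class `cv_result`: `records`
#'   (trait, method, replicate, r) and `summary` (trait, method, mean, sd)
#' @export
cross_validate <- function(method, geno, pheno, k = 5, replicates = 20,
                           seed = 1, control = list(), oracle = NULL,
                           trait = "trait") {
  M <- geno_calls(geno)
  n <- nrow(M)
  if (!is.null(names(pheno))) pheno <- pheno[rownames(M)]
  pheno <- as.numeric(pheno)
  stopifnot(length(pheno) == n, !anyNA(pheno))
  K_full <- if (method == "gblup") compute_kinship(M) else NULL
  r_vals <- numeric(replicates)
  for (rep_i in seq_len(replicates)) {
    fold <- kfold_partition(n, k,
                            seed_stream(seed, paste0("cv-fold-", rep_i)))
    pred <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      test <- fold$fold_of == f
      if (method == "oracle") {
        stopifnot(length(oracle) == n)
        pred[test] <- as.numeric(oracle)[test]
      } else if (method == "gblup") {
        fit <- reml_fit(pheno[!test], K_full[!test, !test, drop = FALSE])
        pred[test] <- predict_gblup(fit, K_full[test, !test, drop = FALSE])
      } else {
        ctl <- control
        if (method %in% c("lasso", "pls", "bayesb", "rkhs") &&
            is.null(ctl$seed))
          ctl$seed <- seed_stream(seed, paste0("cv-fit-", rep_i, "-", f))
        model <- fit_gs_model(method, M[!test, , drop = FALSE],
                              pheno[!test], ctl)
        pred[test] <- predict(model, M[test, , drop = FALSE])
      }
    }
    stopifnot(!anyNA(pred))
    r_vals[rep_i] <- predictability(pheno, pred)
  }
  records <- data.frame(trait = trait, method = method,
                        replicate = seq_len(replicates), r = r_vals,
                        stringsAsFactors = FALSE)
  cv_result(records)
}

#' Assemble a cross-validation result from per-replicate records
#'
#' @param records data.frame with columns `trait`, `method`, `replicate`,
#'   `r`
#' @return object of class `cv_result` with a per trait x method
#'   mean/sd `summary`
#' @export
cv_result <- function(records) {
  stopifnot(all(c("trait", "method", "replicate", "r") %in% names(records)),
            all(records$r >= -1 & records$r <= 1))
  agg <- aggregate(r ~ trait + method, data = records,
                   FUN = function(x) c(mean = mean(x), sd = sd(x)))
  summary <- data.frame(trait = agg$trait, method = agg$method,
                        mean = agg$r[, "mean"], sd = agg$r[, "sd"],
                        row.names = NULL, stringsAsFactors = FALSE)
  structure(list(records = records, summary = summary),
            class = "cv_result")
}

#' Combine cross-validation results
#' @param ... `cv_result` objects
#' @return a single `cv_result`
#' @export
combine_cv_results <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "cv_result"))
    parts <- parts[[1]]
  cv_result(do.call(rbind, lapply(parts, `[[`, "records")))
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", nrow(x$records), "records\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Two-way factorial ANOVA of predictabilities
#'
#' Fixed-effects trait x method factorial with interaction on the
#' per-replicate predictabilities; replicates supply the residual. For a
#' balanced table of `t` traits, `m` methods and `n` replicates the degrees
#' of freedom are `t - 1`, `m - 1`, `(t - 1)(m - 1)` and `t m (n - 1)`.
#'
#' @param cv a `cv_result` with balanced trait x method x replicate records
#' @return data.frame with columns `source`, `df`, `SS`, `MS`, `F`, `p`
#' @export
predictability_anova <- function(cv) {
  rec <- cv$records
  counts <- table(rec$trait, rec$method)
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0))
    stop("unbalanced trait x method records")
  rec$trait <- factor(rec$trait)
  rec$method <- factor(rec$method)
  # drop degenerate single-level factors (e.g. one trait in a toy table)
  terms <- c(if (nlevels(rec$trait) > 1) "trait",
             if (nlevels(rec$method) > 1) "method")
  if (length(terms) == 0) stop("need at least one factor with 2+ levels")
  fml <- stats::as.formula(paste("r ~", paste(terms, collapse = " * ")))
  fit <- aov(fml, data = rec)
  tab <- summary(fit)[[1]]
  label_of <- c(trait = "Trait", method = "Method",
                `trait:method` = "Method x Trait",
                Residuals = "Residual")
  src <- label_of[trimws(rownames(tab))]
  # a single replicate saturates the model: no residual, no F tests
  fv <- if ("F value" %in% colnames(tab)) tab[, "F value"] else
    rep(NA_real_, nrow(tab))
  pv <- if ("Pr(>F)" %in% colnames(tab)) tab[, "Pr(>F)"] else
    rep(NA_real_, nrow(tab))
  out <- data.frame(
    source = unname(src),
    df = tab[, "Df"], SS = tab[, "Sum Sq"], MS = tab[, "Mean Sq"],
    F = fv, p = pv,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

#' Tukey HSD letter groups for a main effect of the predictability ANOVA
#'
#' Tukey's honestly significant difference on the factor-level means, using
#' the residual mean square of the trait x method ANOVA. Levels that share
#' no letter differ significantly at level `alpha`; letters are assigned by
#' the standard sorted-means sweep (maximal runs of mutually
#' non-significant levels).
#'
#' @param cv a balanced `cv_result`
#' @param factor `"trait"` or `"method"`
#' @param alpha familywise significance level
#' @return data.frame with `level`, `mean` and `letters`, sorted by
#'   decreasing mean
#' @export
tukey_groups <- function(cv, factor = c("method", "trait"), alpha = 0.05) {
  factor <- match.arg(factor)
  an <- predictability_anova(cv)
  rec <- cv$records
  lev_vals <- split(rec$r, rec[[factor]])
  if (length(lev_vals) < 2) stop("need at least 2 levels")
  means <- sort(vapply(lev_vals, mean, numeric(1)), decreasing = TRUE)
  n_per <- vapply(lev_vals, length, integer(1))[names(means)]
  stopifnot(length(unique(n_per)) == 1)
  ms_res <- an$MS[an$source == "Residual"]
  df_res <- an$df[an$source == "Residual"]
  if (length(df_res) == 0 || df_res < 1)
    stop("Tukey groups need replicate records (positive residual df)")
  hsd <- qtukey(1 - alpha, length(means), df_res) *
    sqrt(ms_res / n_per[1])
  k <- length(means)
  differ <- abs(outer(means, means, "-")) > hsd
  # sorted-means sweep: one letter per maximal non-significant run
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && !differ[i, j + 1]) j <- j + 1
    runs[[length(runs) + 1]] <- i:j
  }
  keep <- rep(TRUE, length(runs))
  for (a in seq_along(runs)) for (b in seq_along(runs))
    if (a != b && keep[b] && all(runs[[a]] %in% runs[[b]])) keep[a] <- FALSE
  runs <- runs[keep]
  letters_of <- rep("", k)
  for (a in seq_along(runs))
    letters_of[runs[[a]]] <- paste0(letters_of[runs[[a]]], LETTERS[a])
  data.frame(level = names(means), mean = unname(means),
             letters = letters_of, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Marker-density / training-size subsampling experiment
#'
#' For each requested size draws repeated uniform random subsets without
#' replacement along the chosen axis (markers, or individuals = hybrids),
#' runs one five-fold cross-validation per subset, and aggregates the mean
#' and standard deviation of predictability across selections. Mirrors the
#' design in which the marker-density curve plateaus while predictability
#' keeps rising with training-population size.
#'
#' @param axis `"markers"` or `"individuals"`
#' @param sizes integer vector of subset sizes
#' @param selections_per_size random selections per size
#' @param method method name for [fit_gs_model()]
#' @param geno [geno_matrix()] of the full panel
#' @param pheno phenotype vector aligned with `geno`
#' @param k CV folds
#' @param seed master seed
#' @param control method options
#' @return data.frame with `size`, `mean`, `sd`, `n_selections`
#' @export
subsample_experiment <- function(axis = c("markers", "individuals"), sizes,
                                 selections_per_size = 20, method, geno,
                                 pheno, k = 5, seed = 1, control = list()) {
  axis <- match.arg(axis)
  M <- geno_calls(geno)
  if (!is.null(names(pheno))) pheno <- pheno[rownames(M)]
  limit <- if (axis == "markers") ncol(M) else nrow(M)
  if (any(sizes > limit))
    stop("subset size exceeds available ", axis, " (", limit, ")")
  rows <- lapply(sizes, function(sz) {
    r_sel <- vapply(seq_len(selections_per_size), function(s) {
      set.seed(seed_stream(seed, paste0("subsample-", axis, "-", sz,
                                        "-", s)))
      idx <- sort(sample.int(limit, sz))
      if (axis == "markers") {
        g_sub <- subset_geno(geno, markers = idx)
        y_sub <- pheno
      } else {
        g_sub <- subset_geno(geno, samples = idx)
        y_sub <- pheno[idx]
      }
      cv <- cross_validate(method, g_sub, y_sub, k = k, replicates = 1,
                           seed = seed_stream(seed,
                                              paste0("subcv-", sz, "-", s)),
                           control = control)
      cv$records$r[1]
    }, numeric(1))
    data.frame(size = sz, mean = mean(r_sel), sd = sd(r_sel),
               n_selections = selections_per_size)
  })
  do.call(rbind, rows)
}

#' Broad-sense heritability from a balanced multi-environment trial
#'
#' Expected-mean-squares estimators from the balanced two-way
#' genotype x environment ANOVA with replicates:
#' `s2_eps = MS_res`, `s2_ge = (MS_GE - MS_res) / r`,
#' `s2_g = (MS_G - MS_GE) / (e r)` (negative estimates clamped to zero),
#' and `H = s2_g / (s2_g + s2_ge / e + s2_eps / (e r))` on the
#' genotype-mean basis. Sums of squares are computed from the closed-form
#' group-mean decomposition, exact for balanced data.
#'
#' @param pheno long data.frame for one trait with columns `hybrid_id`,
#'   `environment`, `replicate`, `value`; every genotype must appear in
#'   every environment x replicate cell exactly once
#' @return list of class `variance_components`: `sigma2_g`, `sigma2_ge`,
#'   `sigma2_eps`, `e`, `r`, `H`, and the mean squares
#' @export
estimate_broad_sense_H <- function(pheno) {
  stopifnot(all(c("hybrid_id", "environment", "value") %in% names(pheno)))
  g_f <- factor(pheno$hybrid_id)
  e_f <- factor(pheno$environment)
  n_g <- nlevels(g_f); n_e <- nlevels(e_f)
  cell <- table(g_f, e_f)
  if (length(unique(as.vector(cell))) != 1)
    stop("unbalanced genotype x environment layout")
  r <- unique(as.vector(cell))
  if (n_e < 2) stop("need >= 2 environments to separate GxE")
  if (r < 2) stop("need >= 2 replicates to separate the residual")
  y <- pheno$value
  grand <- mean(y)
  m_g <- tapply(y, g_f, mean)
  m_e <- tapply(y, e_f, mean)
  m_ge <- tapply(y, list(g_f, e_f), mean)
  ss_g <- n_e * r * sum((m_g - grand)^2)
  ss_e <- n_g * r * sum((m_e - grand)^2)
  ss_ge <- r * sum((m_ge - outer(m_g, rep(1, n_e)) -
                      outer(rep(1, n_g), m_e) + grand)^2)
  ss_res <- sum((y - m_ge[cbind(g_f, e_f)])^2)
  ms_g <- ss_g / (n_g - 1)
  ms_ge <- ss_ge / ((n_g - 1) * (n_e - 1))
  ms_res <- ss_res / (n_g * n_e * (r - 1))
  s2_eps <- ms_res
  s2_ge <- max((ms_ge - ms_res) / r, 0)
  s2_g <- max((ms_g - ms_ge) / (n_e * r), 0)
  H <- s2_g / (s2_g + s2_ge / n_e + s2_eps / (n_e * r))
  structure(list(sigma2_g = s2_g, sigma2_ge = s2_ge, sigma2_eps = s2_eps,
                 e = n_e, r = r, H = H,
                 mean_squares = c(G = ms_g, E = ss_e / (n_e - 1),
                                  GE = ms_ge, residual = ms_res)),
            class = "variance_components")
}
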