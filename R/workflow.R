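#' Default study configuration
#'
#' Desk-scale defaults for [run_full_study()]: the full NC II design
#' (115 x 5 training hybrids), 2000 markers, eight traits at the design's
#' heritability targets, all six methods, five-fold cross-validation with
#' 20 replicates, both subsampling axes, and top-100 selection among the
#' candidate crosses.
#'
#' @return named list understood by [run_full_study()]
#' @export
default_study_config <- function() {
  list(
    sim = list(n_females = 115, n_males = 5, n_candidates = 200,
               n_markers = 2000, maf_range = c(0.1, 0.5), ld_rho = 0),
    n_qtl = 200,
    methods = c("gblup", "lasso", "bayesb", "pls", "svm", "rkhs"),
    cv = list(k = 5, replicates = 20),
    subsample = list(
      marker_sizes = c(100, 250, 500, 1000, 2000),
      individual_sizes = c(115, 230, 345, 460, 575),
      selections_per_size = 20,
      method = "gblup"),
    selection = list(trait = "GY", method = "gblup", top_k = 100),
    control = list(bayesb = list(hyper = bayesb_hyper(n_iter = 3000,
                                                      burn_in = 1000,
                                                      thin = 2)),
                   rkhs = list(n_iter = 2000, burn_in = 500))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(override[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full study skeleton on a synthetic bundle
#'
#' Chains every stage at desk scale: simulate an NC II study bundle,
#' cross-validate the requested methods on every trait, run the
#' trait x method ANOVA with Tukey letter groups, run the marker-density
#' and training-size subsampling experiments, and predict, rank and select
#' candidate crosses with top-k gains per trait. Idempotent for a fixed
#' seed; every table in the report is regenerable from the embedded config
#' and seed alone.
#'
#' @param config a config list (see [default_study_config()]), a YAML file
#'   path, or `NULL` for the defaults; partial lists override defaults
#' @param seed master seed
#' @param outdir optional directory for TSV/JSON copies of the report
#' @param stages subset of
#'   `c("cv", "anova", "subsample", "selection")` to run after simulation
#' @return list of class `study_report`
#' @export
run_full_study <- function(config = NULL, seed = 1, outdir = NULL,
                           stages = c("cv", "anova", "subsample",
                                      "selection")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_study_config(), config %||% list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  sim_args <- cfg$sim
  sim_args$seed <- seed
  bundle <- stage("simulate", {
    make_study_bundle(do.call(sim_config, sim_args),
                      default_trait_architectures(n_qtl = cfg$n_qtl),
                      seed = seed)
  })
  traits <- colnames(bundle$pheno_means)
  report <- list(config = cfg, seed = seed,
                 heritability = vapply(bundle$truth, `[[`, numeric(1),
                                       "realized_H"))

  if ("cv" %in% stages) {
    report$cv <- stage("cv", {
      parts <- list()
      for (tr in traits) for (me in cfg$methods) {
        parts[[paste(tr, me)]] <- cross_validate(
          me, bundle$hybrids, bundle$pheno_means[, tr],
          k = cfg$cv$k, replicates = cfg$cv$replicates,
          seed = seed_stream(seed, paste0("study-cv-", tr, "-", me)),
          control = cfg$control[[me]] %||% list(), trait = tr)
      }
      combine_cv_results(parts)
    })
    if ("anova" %in% stages) {
      report$anova <- stage("anova", predictability_anova(report$cv))
      report$tukey <- stage("tukey", list(
        method = tukey_groups(report$cv, "method"),
        trait = tukey_groups(report$cv, "trait")))
    }
  }

  if ("subsample" %in% stages) {
    sc <- cfg$subsample
    tr <- cfg$selection$trait
    report$subsample <- stage("subsample", list(
      markers = subsample_experiment(
        "markers", sc$marker_sizes, sc$selections_per_size, sc$method,
        bundle$hybrids, bundle$pheno_means[, tr],
        seed = seed_stream(seed, "study-sub-markers")),
      individuals = subsample_experiment(
        "individuals",
        pmin(sc$individual_sizes, n_samples(bundle$hybrids)),
        sc$selections_per_size, sc$method,
        bundle$hybrids, bundle$pheno_means[, tr],
        seed = seed_stream(seed, "study-sub-individuals"))))
  }

  if ("selection" %in% stages) {
    report$selection <- stage("selection", {
      out <- list()
      for (tr in traits) {
        model <- fit_gs_model(cfg$selection$method, bundle$hybrids,
                              bundle$pheno_means[, tr],
                              cfg$control[[cfg$selection$method]] %||%
                                list())
        ranked <- predict_all_crosses(model, bundle$parents,
                                      bundle$candidates,
                                      bundle$females, trait = tr)
        gain <- top_k_gain(ranked, cfg$selection$top_k)
        out[[tr]] <- c(list(trait = tr, n_crosses = nrow(ranked),
                            k = cfg$selection$top_k), gain)
      }
      do.call(rbind, lapply(out, as.data.frame))
    })
  }

  class(report) <- "study_report"
  if (!is.null(outdir)) write_study_report(report, outdir)
  report
}

#' Write a study report to disk
#'
#' TSV copies of every table plus a JSON header with config and seed.
#'
#' @param report a `study_report`
#' @param outdir output directory (created if needed)
#' @return invisibly, `outdir`
#' @export
write_study_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name)
    write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(report$cv)) {
    wt(report$cv$summary, "cv_summary.tsv")
    wt(report$cv$records, "cv_records.tsv")
  }
  if (!is.null(report$anova)) wt(report$anova, "anova.tsv")
  if (!is.null(report$tukey)) {
    wt(report$tukey$method, "tukey_method.tsv")
    wt(report$tukey$trait, "tukey_trait.tsv")
  }
  if (!is.null(report$subsample)) {
    wt(report$subsample$markers, "subsample_markers.tsv")
    wt(report$subsample$individuals, "subsample_individuals.tsv")
  }
  if (!is.null(report$selection)) wt(report$selection, "selection_gain.tsv")
  strip_classes <- function(x)
    if (is.list(x)) lapply(unclass(x), strip_classes) else x
  header <- list(seed = report$seed,
                 heritability = as.list(report$heritability),
                 config = strip_classes(report$config))
  jsonlite::write_json(header, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}
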