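#' Configuration for the synthetic NC II study generator
#'
#' Defaults emulate the study design the package targets: 115 inbred female
#' lines crossed to 5 male-sterile testers (575 training hybrids), plus a
#' candidate panel standing in for a large public accession panel, all
#' genotyped at biallelic SNPs with minor-allele frequencies drawn uniformly
#' from `maf_range`. `ld_rho` introduces first-order linkage disequilibrium
#' by Markov allele copying between adjacent markers.
#'
#' @param n_females number of inbred female lines (default 115)
#' @param n_males number of male-sterile testers (default 5)
#' @param n_candidates size of the candidate parent panel (default 200, a
#'   desk-scale stand-in for a 3,023-accession panel)
#' @param n_markers number of SNPs (default 2000)
#' @param maf_range minor-allele-frequency interval, subset of (0, 0.5]
#' @param ld_rho adjacent-marker copying probability in [0, 1)
#' @param seed integer master seed
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_females = 115, n_males = 5, n_candidates = 200,
                       n_markers = 2000, maf_range = c(0.1, 0.5),
                       ld_rho = 0, seed = 1) {
  stopifnot(n_females >= 1, n_males >= 1, n_candidates >= 1, n_markers >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2], ld_rho >= 0, ld_rho < 1)
  structure(list(n_females = n_females, n_males = n_males,
                 n_candidates = n_candidates, n_markers = n_markers,
                 maf_range = maf_range, ld_rho = ld_rho,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Trait architecture for phenotype simulation
#'
#' Describes one simulated trait: the number of additive QTL drawn from the
#' marker panel, the effect distribution, the target broad-sense
#' heritability on a genotype-mean basis across `e` environments and `r`
#' replicates, and an optional dominance component.
#'
#' @param name trait name
#' @param target_H target broad-sense heritability in (0, 1]
#' @param n_qtl number of causal markers
#' @param effect_distribution `"normal"` (polygenic) or `"mixture"`
#'   (point mass at zero plus a normal slab, emulating major-gene traits)
#' @param mixture_prop proportion of the `n_qtl` effects drawn from the slab
#'   when `effect_distribution = "mixture"`
#' @param e number of environments (default 2 locations)
#' @param r number of replicates per environment (default 2)
#' @param dominance_ratio dominance-to-additive variance ratio (default 0)
#' @param mu trait grand mean
#' @return list of class `trait_architecture`
#' @export
trait_architecture <- function(name, target_H, n_qtl = 200,
                               effect_distribution = c("normal", "mixture"),
                               mixture_prop = 0.1, e = 2L, r = 2L,
                               dominance_ratio = 0, mu = 0) {
  effect_distribution <- match.arg(effect_distribution)
  stopifnot(target_H > 0, target_H <= 1, n_qtl >= 1, e >= 1, r >= 1,
            dominance_ratio >= 0)
  if (target_H < 0.01) stop("target_H below sanity cap 0.01")
  structure(list(name = name, target_H = target_H, n_qtl = n_qtl,
                 effect_distribution = effect_distribution,
                 mixture_prop = mixture_prop, e = as.integer(e),
                 r = as.integer(r), dominance_ratio = dominance_ratio,
                 mu = mu),
            class = "trait_architecture")
}

#' The eight default trait architectures
#'
#' Eight agronomic traits at the broad-sense heritabilities the study design
#' spans (0.2550 to 0.8501): grain yield per plant (GY), thousand-grain
#' weight (TGW), panicle number (PN), plant height (PH), secondary branch
#' number (SB), grain number per panicle (GN), panicle length (PL) and
#' primary branch number (PB).
#'
#' Grand means are set to realistic magnitudes for the crop (grams,
#' centimetres, counts) so selection gains can be reported in percent;
#' genetic variance is 1 on every trait, so effects are in genetic-sd
#' units.
#'
#' @param n_qtl causal markers per trait
#' @return named list of [trait_architecture()] objects
#' @export
default_trait_architectures <- function(n_qtl = 200) {
  H <- c(GY = 0.3031, TGW = 0.8501, PN = 0.2550, PH = 0.7501,
         SB = 0.6676, GN = 0.6262, PL = 0.7802, PB = 0.6944)
  mu <- c(GY = 38, TGW = 25, PN = 10, PH = 110,
          SB = 25, GN = 150, PL = 23, PB = 12)
  out <- lapply(names(H), function(tr)
    trait_architecture(tr, target_H = H[[tr]], n_qtl = n_qtl,
                       mu = mu[[tr]]))
  names(out) <- names(H)
  out
}

sim_markers_meta <- function(n_markers) {
  if (n_markers == 0)
    return(data.frame(id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  data.frame(id = sprintf("M%05d", seq_len(n_markers)),
             chrom = as.character(((seq_len(n_markers) - 1) %% 12) + 1),
             pos = as.integer(((seq_len(n_markers) - 1) %/% 12) + 1) * 100L,
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

sim_homozygous_panel <- function(n, n_markers, maf, ld_rho, prefix) {
  # allele indicator per individual x marker; Markov copying along markers
  X <- matrix(0L, n, n_markers)
  X[, 1] <- rbinom(n, 1, maf[1])
  if (n_markers > 1) {
    for (j in 2:n_markers) {
      copy <- if (ld_rho > 0) runif(n) < ld_rho else rep(FALSE, n)
      fresh <- rbinom(n, 1, maf[j])
      X[, j] <- ifelse(copy, X[, j - 1], fresh)
    }
  }
  calls <- 1 - 2 * X   # carrying the minor allele (homozygous) -> -1
  rownames(calls) <- sprintf("%s%03d", prefix, seq_len(n))
  calls
}

#' Simulate homozygous parental genotype panels
#'
#' Generates fully homozygous inbred parents (codes in `{-1, +1}`): female
#' lines, male-sterile testers and a candidate panel drawn from the same
#' allele-frequency process. Group labels are `"line"`, `"tester"` and
#' `"candidate"`.
#'
#' @param cfg a [sim_config()]
#' @return list with [geno_matrix()] elements `parents` (lines + testers)
#'   and `candidates`, plus `females` and `males` id vectors
#' @export
simulate_parent_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed_stream(cfg$seed, "parent-genotypes"))
  m <- cfg$n_markers
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  markers <- sim_markers_meta(m)
  fem <- sim_homozygous_panel(cfg$n_females, m, maf, cfg$ld_rho, "L")
  mal <- sim_homozygous_panel(cfg$n_males, m, maf, cfg$ld_rho, "T")
  cand <- sim_homozygous_panel(cfg$n_candidates, m, maf, cfg$ld_rho, "C")
  calls <- rbind(fem, mal)
  groups <- stats::setNames(c(rep("line", cfg$n_females),
                              rep("tester", cfg$n_males)), rownames(calls))
  cand_groups <- stats::setNames(rep("candidate", nrow(cand)),
                                 rownames(cand))
  list(parents = geno_matrix(calls, markers, groups),
       candidates = geno_matrix(cand, markers, cand_groups),
       females = rownames(fem), males = rownames(mal))
}

#' Simulate multi-environment phenotypes at a target heritability
#'
#' Genetic values are an additive sum over a random QTL subset (plus
#' dominance deviations when requested), rescaled so the realised genetic
#' variance across hybrids is exactly 1. Noise variances are then fixed so
#' the broad-sense heritability on a genotype-mean basis,
#' `H = s2_g / (s2_g + s2_ge/e + s2_e/(e*r))`, hits `target_H` exactly by
#' construction, the non-genetic share being split 50/50 between
#' genotype-by-environment interaction and plot residual. Phenotypes are
#' emitted for every environment x replicate together with the per-hybrid
#' mean used for prediction.
#'
#' @param hybrids a fully encoded [geno_matrix()] of the phenotyped hybrids
#' @param arch a [trait_architecture()]
#' @param seed integer seed
#' @return list with `pheno` (long data.frame: `hybrid_id`, `trait`,
#'   `environment`, `replicate`, `value`), `means` (named per-hybrid mean
#'   vector), and `truth` (QTL ids, effects, variance components, realised H)
#' @export
simulate_phenotypes <- function(hybrids, arch, seed = 1) {
  stopifnot(inherits(arch, "trait_architecture"),
            arch$n_qtl <= n_markers(hybrids))
  set.seed(seed_stream(seed, paste0("phenotypes-", arch$name)))
  Z <- hybrids$calls
  n <- nrow(Z)
  qtl <- sort(sample.int(ncol(Z), arch$n_qtl))
  gamma <- rnorm(arch$n_qtl)
  if (arch$effect_distribution == "mixture") {
    slab <- runif(arch$n_qtl) < arch$mixture_prop
    if (!any(slab)) slab[sample.int(arch$n_qtl, 1)] <- TRUE
    gamma[!slab] <- 0
    gamma[slab] <- rnorm(sum(slab), sd = 3)
  }
  g <- drop(Z[, qtl, drop = FALSE] %*% gamma)
  if (arch$dominance_ratio > 0) {
    d_eff <- rnorm(arch$n_qtl)
    Het <- 1 - abs(Z[, qtl, drop = FALSE])   # 1 at heterozygous codes
    d <- drop(Het %*% d_eff)
    if (var(d) > 0)
      d <- d * sqrt(arch$dominance_ratio * var(g) / var(d))
    g <- g + d
  }
  if (var(g) == 0) stop("degenerate genetic values (no variance)")
  sc <- sqrt(1 / var(g))
  g <- (g - mean(g)) * sc
  gamma_scaled <- gamma * sc
  e <- arch$e; r <- arch$r; H <- arch$target_H
  noise <- (1 - H) / H               # s2_ge/e + s2_e/(e r), with s2_g = 1
  s2_ge <- e * noise / 2
  s2_eps <- e * r * noise / 2
  ge <- matrix(rnorm(n * e, sd = sqrt(s2_ge)), n, e)
  if (H == 1) ge[] <- 0
  recs <- expand.grid(replicate = seq_len(r), environment = seq_len(e),
                      hybrid = seq_len(n), KEEP.OUT.ATTRS = FALSE)
  eps <- if (H == 1) rep(0, nrow(recs)) else
    rnorm(nrow(recs), sd = sqrt(s2_eps))
  value <- arch$mu + g[recs$hybrid] +
    ge[cbind(recs$hybrid, recs$environment)] + eps
  pheno <- data.frame(hybrid_id = rownames(Z)[recs$hybrid],
                      trait = arch$name,
                      environment = paste0("E", recs$environment),
                      replicate = recs$replicate,
                      value = value, stringsAsFactors = FALSE)
  means <- tapply(pheno$value, pheno$hybrid_id, mean)[rownames(Z)]
  means <- setNames(as.numeric(means), rownames(Z))
  truth <- list(trait = arch$name, qtl_ids = hybrids$markers$id[qtl],
                gamma = gamma_scaled, g = stats::setNames(g, rownames(Z)),
                sigma2_g = 1, sigma2_ge = s2_ge, sigma2_eps = s2_eps,
                e = e, r = r,
                realized_H = 1 / (1 + s2_ge / e + s2_eps / (e * r)))
  list(pheno = pheno, means = means, truth = truth)
}

#' Generate a complete synthetic study bundle
#'
#' One call yields every input the analysis needs: homozygous parents, the
#' full NC II cross set, deduced training-hybrid genotypes, a long-format
#' multi-trait phenotype table with per-hybrid means, a candidate parent
#' panel for cross selection, and the simulation truth. Fully reproducible
#' from the master seed. When `outdir` is given, the genotype panels
#' (TSV dialect), cross list and phenotype table are also written to disk.
#'
#' @param cfg a [sim_config()]
#' @param architectures list of [trait_architecture()]; defaults to
#'   [default_trait_architectures()]
#' @param seed master seed; defaults to `cfg$seed`
#' @param outdir optional output directory
#' @return list of class `study_bundle` with elements `parents`,
#'   `candidates`, `females`, `males`, `crosses`, `hybrids`, `pheno`,
#'   `pheno_means` (hybrids x traits matrix), `truth`, `config`
#' @export
make_study_bundle <- function(cfg = sim_config(), architectures = NULL,
                              seed = NULL, outdir = NULL) {
  if (is.null(seed)) seed <- cfg$seed
  cfg$seed <- as.integer(seed)
  if (is.null(architectures)) architectures <- default_trait_architectures()
  names(architectures) <- vapply(architectures, `[[`, character(1), "name")
  pan <- simulate_parent_genotypes(cfg)
  crosses <- enumerate_crosses(pan$females, pan$males)
  hybrids <- deduce_hybrid_genotypes(pan$parents, crosses)
  pheno_list <- lapply(architectures, simulate_phenotypes,
                       hybrids = hybrids, seed = seed)
  pheno <- do.call(rbind, lapply(pheno_list, `[[`, "pheno"))
  rownames(pheno) <- NULL
  pheno_means <- vapply(pheno_list, `[[`, numeric(n_samples(hybrids)),
                        "means")
  rownames(pheno_means) <- rownames(hybrids$calls)
  bundle <- structure(
    list(parents = pan$parents, candidates = pan$candidates,
         females = pan$females, males = pan$males, crosses = crosses,
         hybrids = hybrids, pheno = pheno, pheno_means = pheno_means,
         truth = lapply(pheno_list, `[[`, "truth"), config = cfg),
    class = "study_bundle")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_genotype_table(pan$parents, file.path(outdir, "parents.tsv"))
    write_genotype_table(pan$candidates, file.path(outdir, "candidates.tsv"))
    write_genotype_table(hybrids, file.path(outdir, "hybrids.tsv"))
    write.table(crosses, file.path(outdir, "crosses.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pheno, file.path(outdir, "phenotypes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  bundle
}
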