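# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# small geno_matrix with explicit codes (rows = samples)
make_geno <- function(calls, groups = NULL, chrom = NULL, pos = NULL,
                      ref = "A", alt = "G") {
  m <- ncol(calls)
  markers <- data.frame(
    id = colnames(calls) %||% sprintf("M%03d", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos = pos %||% seq_len(m) * 10L,
    ref = rep_len(ref, m), alt = rep_len(alt, m),
    stringsAsFactors = FALSE)
  hybridgs::geno_matrix(calls, markers, groups)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a VCF text fixture; geno_rows is a list of body lines
write_vcf_fixture <- function(path, samples, body_lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body_lines), path)
  path
}

# homozygous random parent codes, n x m in {-1, +1}
random_homozygous <- function(n, m, seed = 1, maf = 0.3) {
  set.seed(seed)
  calls <- matrix(ifelse(runif(n * m) < maf, -1, 1), n, m,
                  dimnames = list(sprintf("P%03d", seq_len(n)),
                                  sprintf("M%03d", seq_len(m))))
  make_geno(calls)
}

# small NC II bundle used by several suites
small_bundle <- function(n_females = 20, n_males = 3, n_markers = 300,
                         n_candidates = 15, seed = 7, n_qtl = 50,
                         traits = NULL) {
  cfg <- sim_config(n_females = n_females, n_males = n_males,
                    n_candidates = n_candidates, n_markers = n_markers,
                    seed = seed)
  make_study_bundle(cfg, traits %||% default_trait_architectures(n_qtl))
}

# additive phenotype on a genotype panel with known architecture
simulate_additive_y <- function(Z, h2, n_qtl, seed) {
  set.seed(seed)
  M <- if (inherits(Z, "geno_matrix")) Z$calls else Z
  qtl <- sample.int(ncol(M), n_qtl)
  g <- drop(M[, qtl, drop = FALSE] %*% rnorm(n_qtl))
  g <- (g - mean(g)) / sd(g)
  y <- g + rnorm(nrow(M), sd = sqrt((1 - h2) / h2))
  list(y = y, g = g, qtl = qtl)
}
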