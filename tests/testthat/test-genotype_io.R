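test_that("VCF reading preserves missing calls and skips multi-allelic sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path, c("s1", "s2", "s3"), c(
    "1\t100\tm1\tA\tG\t.\t.\t.\tGT\t0/0\t0/1\t./.",
    "1\t200\tm2\tC\tT\t.\t.\t.\tGT\t1/1\t0/0\t0/0"))
  g <- read_genotype_table(path, "vcf")
  expect_equal(dim(g), c(3L, 2L))
  expect_equal(sum(is.na(g$calls)), 1L)
  expect_equal(unname(g$calls[, "m1"]), c(1, 0, NA))
  expect_equal(unname(g$calls[, "m2"]), c(-1, 1, 1))

  # one triallelic site among 5 -> 4 markers retained
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(path2, c("s1", "s2"), c(
    "1\t100\ta\tA\tG\t.\t.\t.\tGT\t0/0\t0/1",
    "1\t200\tb\tC\tT\t.\t.\t.\tGT\t0/0\t0/0",
    "1\t300\tc\tA\tG,T\t.\t.\t.\tGT\t0/0\t0/2",
    "1\t400\td\tG\tA\t.\t.\t.\tGT\t1/1\t0/0",
    "1\t500\te\tT\tC\t.\t.\t.\tGT\t0/1\t0/1"))
  expect_message(g2 <- read_genotype_table(path2, "vcf"), "skipped")
  expect_equal(n_markers(g2), 4L)
  expect_false("c" %in% g2$markers$id)
})

test_that("read/write round-trips are the identity in both dialects", {
  calls <- matrix(c(1, 0, -1, NA, 1, 1, -1, 0), 2, 4,
                  dimnames = list(c("a", "b"), NULL))
  g <- make_geno(calls)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(g, tsv, "tsv")
  g2 <- read_genotype_table(tsv, "tsv")
  expect_identical(g2$calls, g$calls)
  expect_identical(g2$markers, g$markers)

  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_table(g, vcf, "vcf")
  expect_match(readLines(vcf), "\\./\\.", all = FALSE)  # MISSING as ./.
  g3 <- read_genotype_table(vcf, "vcf")
  expect_identical(unname(g3$calls), unname(g$calls))
  expect_identical(g3$markers[, c("chrom", "pos", "ref", "alt")],
                   g$markers[, c("chrom", "pos", "ref", "alt")])

  # larger simulated hybrid panel round-trips exactly
  b <- small_bundle(n_females = 10, n_males = 2, n_markers = 100)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(b$hybrids, tsv2, "tsv")
  expect_identical(read_genotype_table(tsv2, "tsv")$calls, b$hybrids$calls)

  # 0-marker matrix -> header-only file, re-readable
  g0 <- subset_geno(g, markers = integer(0))
  vcf0 <- withr::local_tempfile(fileext = ".vcf")
  write_genotype_table(g0, vcf0, "vcf")
  g0r <- read_genotype_table(vcf0, "vcf")
  expect_equal(dim(g0r), c(2L, 0L))
  expect_identical(rownames(g0r$calls), c("a", "b"))
})

test_that("missing-rate QC uses strict per-group thresholds", {
  # 5 testers + 4 lines; marker1 missing in 2/5 testers (40% > 20%),
  # marker2 missing in 1/5 testers (20%, not above), marker3 complete
  calls <- rbind(
    matrix(c(NA, NA, 1, 1, 1,   NA, 1, 1, 1, 1,   1, 1, 1, 1, 1), 5, 3),
    matrix(c(NA, NA, 1, 1,      1, 1, 1, 1,       1, 1, 1, 1), 4, 3))
  rownames(calls) <- c(paste0("t", 1:5), paste0("l", 1:4))
  groups <- setNames(c(rep("tester", 5), rep("line", 4)), rownames(calls))
  g <- make_geno(calls, groups)
  thr <- c(tester = 0.2, line = 0.5)
  out <- qc_filter_missing(g, thr)
  expect_equal(out$markers$id, g$markers$id[2:3])
  expect_equal(n_samples(out), 9L)              # samples unchanged

  # no missing anywhere -> everything retained
  g_full <- make_geno(matrix(1, 5, 3,
                             dimnames = list(paste0("t", 1:5), NULL)),
                      setNames(rep("tester", 5), paste0("t", 1:5)))
  expect_equal(n_markers(qc_filter_missing(g_full, thr)), 3L)

  # monotone: lowering a threshold never enlarges the retained set
  set.seed(42)
  calls_r <- matrix(sample(c(1, 0, -1, NA), 200, TRUE,
                           prob = c(.3, .2, .3, .2)), 10, 20)
  rownames(calls_r) <- c(paste0("t", 1:5), paste0("l", 1:5))
  gr <- make_geno(calls_r, setNames(c(rep("tester", 5), rep("line", 5)),
                                    rownames(calls_r)))
  kept_prev <- NULL
  for (t_val in c(0.8, 0.4, 0.2, 0)) {
    kept <- qc_filter_missing(gr, c(tester = t_val, line = t_val))$markers$id
    if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
    kept_prev <- kept
  }
})

test_that("encoding orients to the minor allele and imputes by marker mode", {
  # counts AA:8, AG:1, GG:1 -> AA homozygotes coded +1 (majority is major)
  x1 <- c(rep(1, 8), 0, -1)
  # 50/50 frequency, alleles A and G -> A major by the lexicographic tie rule
  x2 <- c(rep(1, 5), rep(-1, 5))
  # mode imputation: one NA among {+1, +1, -1, ...}
  x3 <- c(1, 1, -1, NA, rep(1, 6))
  g <- make_geno(cbind(m1 = x1, m2 = x2, m3 = x3))
  enc <- impute_and_encode(g)
  expect_equal(unname(enc$calls[, "m1"]), x1)       # already major-oriented
  expect_equal(enc$markers$ref[1], "A")
  expect_equal(unname(enc$calls[, "m2"]), x2)       # A stays major
  expect_equal(enc$markers$ref[2], "A")
  expect_equal(unname(enc$calls[4, "m3"]), 1)       # imputed to mode

  # minor-oriented marker gets flipped, alleles swapped
  g_flip <- make_geno(cbind(m1 = -x1))
  enc_f <- impute_and_encode(g_flip)
  expect_equal(unname(enc_f$calls[, 1]), x1)
  expect_equal(enc_f$markers$ref[1], "G")

  # involution: negating codes and re-encoding restores the encoding
  set.seed(5)
  gr <- make_geno(matrix(sample(c(-1, 0, 1), 60, TRUE, c(.2, .2, .6)),
                         10, 6))
  e1 <- impute_and_encode(gr)
  neg <- e1
  neg$calls <- -neg$calls
  e2 <- impute_and_encode(geno_matrix(neg$calls, e1$markers))
  expect_equal(e2$calls, e1$calls)

  # mode tie -> 0; all-missing marker dropped with warning
  g_tie <- make_geno(cbind(m1 = c(1, 1, -1, -1, NA),
                           m2 = rep(NA_real_, 5)))
  expect_warning(enc_t <- impute_and_encode(g_tie), "dropped")
  expect_equal(n_markers(enc_t), 1L)
  expect_equal(unname(enc_t$calls[5, 1]), 0)
})

test_that("marker-set intersection matches on position and re-orients swapped alleles", {
  a <- make_geno(matrix(c(1, -1, 0, 1, 1, -1), 2, 3), pos = c(10L, 20L, 30L))
  # identical panels -> unchanged
  both <- intersect_marker_sets(a, a)
  expect_identical(both$a$calls, a$calls)
  expect_identical(both$b$calls, a$calls)

  # b has alleles swapped at site 2 -> codes negated to a's orientation
  b <- a
  b$markers$ref[2] <- "G"; b$markers$alt[2] <- "A"
  b$calls[, 2] <- -b$calls[, 2]
  out <- intersect_marker_sets(a, b)
  expect_equal(n_markers(out$a), 3L)
  expect_identical(out$b$calls, a$calls)
  expect_identical(out$b$markers$ref, a$markers$ref)

  # disjoint positions -> two 0-marker panels
  dis <- make_geno(matrix(0, 2, 3), pos = c(11L, 21L, 31L))
  none <- intersect_marker_sets(a, dis)
  expect_equal(n_markers(none$a), 0L)
  expect_equal(n_markers(none$b), 0L)
})
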