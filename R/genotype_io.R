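#' Construct a genotype matrix object
#'
#' The central genotype container: a samples x markers matrix of additive
#' codes together with marker metadata and optional sample group labels.
#' Codes follow the ref/alt orientation recorded in `markers`: `+1` is the
#' homozygote of `ref_allele`, `-1` the homozygote of `alt_allele`, `0` the
#' heterozygote, and `NA` a missing call. After [impute_and_encode()] the
#' orientation is normalised so that `ref_allele` is the major allele, i.e.
#' `-1` codes the minor-allele homozygote. Deduced hybrids of a residually
#' heterozygous parent may carry expected dosages of `+-0.5`.
#'
#' @param calls numeric matrix, samples in rows, markers in columns;
#'   dimnames are sample ids and marker ids.
#' @param markers data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per column of `calls`. `(chrom, pos)` must be unique.
#' @param groups optional named character vector mapping sample id to a
#'   group label (e.g. `"tester"`, `"line"`, `"hybrid"`, `"candidate"`).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(calls, markers, groups = NULL) {
  calls <- as.matrix(calls)
  stopifnot(is.data.frame(markers),
            all(c("id", "chrom", "pos", "ref", "alt") %in% names(markers)),
            ncol(calls) == nrow(markers))
  if (nrow(markers) > 0) {
    stopifnot(all(markers$pos >= 1), !any(markers$ref == markers$alt),
              !anyDuplicated(paste(markers$chrom, markers$pos)))
  }
  colnames(calls) <- markers$id
  if (is.null(rownames(calls)))
    rownames(calls) <- paste0("S", seq_len(nrow(calls)))
  if (!is.null(groups)) {
    groups <- groups[rownames(calls)]
    names(groups) <- rownames(calls)
  }
  ok <- is.na(calls) | calls %in% c(-1, -0.5, 0, 0.5, 1)
  if (!all(ok)) stop("genotype codes must be in {-1, -0.5, 0, 0.5, 1} or NA")
  structure(list(calls = calls, markers = markers, groups = groups),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d markers (%d missing calls)\n",
              nrow(x$calls), ncol(x$calls), sum(is.na(x$calls))))
  if (!is.null(x$groups))
    print(table(x$groups))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Number of samples / markers in a genotype matrix
#' @param g a [geno_matrix()]
#' @return integer count
#' @export
n_samples <- function(g) nrow(g$calls)

#' @rdname n_samples
#' @export
n_markers <- function(g) ncol(g$calls)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param g a [geno_matrix()]
#' @param samples sample indices, logical mask, or ids
#' @param markers marker indices, logical mask, or ids
#' @return a [geno_matrix()]
#' @export
subset_geno <- function(g, samples = NULL, markers = NULL) {
  calls <- g$calls
  info <- g$markers
  if (!is.null(markers)) {
    idx <- if (is.character(markers)) match(markers, info$id) else
      seq_len(ncol(calls))[markers]
    calls <- calls[, idx, drop = FALSE]
    info <- info[idx, , drop = FALSE]
  }
  if (!is.null(samples)) {
    sidx <- if (is.character(samples)) match(samples, rownames(calls)) else
      seq_len(nrow(calls))[samples]
    calls <- calls[sidx, , drop = FALSE]
  }
  geno_matrix(calls, info, g$groups)
}

#' Read a genotype table (VCF or TSV dialect)
#'
#' VCF input keeps only biallelic SNP records (multi-allelic records are
#' skipped with a message); genotypes are taken from the GT field, `./.`
#' becoming missing, and codes follow the file's ref/alt orientation
#' (`+1` = ref homozygote). The TSV dialect is tab-separated with sample ids
#' in the first column, marker ids as header, values in `{-1, 0, 1, NA}`
#' (half dosages allowed), and a sidecar `<path>.markers.tsv` holding marker
#' metadata (`id`, `chrom`, `pos`, `ref`, `alt`).
#'
#' @param path input file path
#' @param format `"vcf"` or `"tsv"`
#' @return a [geno_matrix()] with missing calls preserved
#' @export
read_genotype_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  g <- if (format == "vcf") read_geno_vcf(path) else read_geno_tsv(path)
  if (n_markers(g) == 0 && n_samples(g) == 0)
    stop("no usable markers or samples in ", path)
  g
}

read_geno_vcf <- function(path) {
  header_cols <- grep("^#CHROM", readLines(path), value = TRUE)
  if (length(header_cols) != 1) stop("malformed VCF (no #CHROM line): ", path)
  samples <- strsplit(header_cols, "\t")[[1]][-(1:9)]
  n_records <- sum(!startsWith(readLines(path), "#"))
  if (n_records == 0) {                     # header-only file round-trips
    calls <- matrix(numeric(0), length(samples), 0,
                    dimnames = list(samples, NULL))
    return(geno_matrix(calls, sim_markers_meta(0)))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1 &
    nchar(fix$ALT) == 1 & !is.na(fix$ALT)
  n_skip <- sum(!biallelic)
  if (n_skip > 0)
    message(n_skip, " non-biallelic-SNP record(s) skipped")
  if (!any(biallelic)) stop("zero usable biallelic markers in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID)
  # count alt alleles in the GT string; +1 = ref hom, -1 = alt hom
  code_one <- function(s) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(s, "[/|]")[[1]]
    if (any(al == ".")) return(NA_real_)
    1 - sum(as.integer(al))
  }
  calls <- t(apply(gt, c(1, 2), code_one))
  rownames(calls) <- colnames(gt)
  markers <- data.frame(id = ids, chrom = fix$CHROM,
                        pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  geno_matrix(calls, markers)
}

read_geno_tsv <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  side <- paste0(path, ".markers.tsv")
  if (!file.exists(side)) stop("marker metadata sidecar not found: ", side)
  markers <- read.table(side, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE,
                        colClasses = c(id = "character", chrom = "character",
                                       pos = "integer", ref = "character",
                                       alt = "character"))
  calls <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(calls) <- "double"
  rownames(calls) <- as.character(tab[[1]])
  if (!identical(colnames(calls), markers$id))
    stop("marker ids in table and sidecar disagree")
  geno_matrix(calls, markers)
}

#' Write a genotype table (VCF or TSV dialect)
#'
#' Round-trips through [read_genotype_table()]: samples, markers and calls
#' are reproduced exactly. VCF output encodes `+1/0/-1/NA` as
#' `0/0`, `0/1`, `1/1`, `./.`; half-dosage codes are not representable in
#' VCF and raise an error (use the TSV dialect for deduced hybrids).
#'
#' @param g a [geno_matrix()]
#' @param path output path
#' @param format `"vcf"` or `"tsv"`
#' @return invisibly, `path`
#' @export
write_genotype_table <- function(g, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- data.frame(sample_id = rownames(g$calls), g$calls,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(g$markers[, c("id", "chrom", "pos", "ref", "alt")],
                paste0(path, ".markers.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (any(!is.na(g$calls) & !(g$calls %in% c(-1, 0, 1))))
      stop("half-dosage codes cannot be written as VCF; use format = 'tsv'")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(g$calls)),
                       collapse = "\t")), con)
    if (n_markers(g) > 0) {
      gt_of <- c(`1` = "0/0", `0` = "0/1", `-1` = "1/1")
      for (j in seq_len(n_markers(g))) {
        codes <- g$calls[, j]
        gt <- ifelse(is.na(codes), "./.", gt_of[as.character(codes)])
        m <- g$markers[j, ]
        writeLines(paste(c(m$chrom, m$pos, m$id, m$ref, m$alt, ".", ".",
                           ".", "GT", gt), collapse = "\t"), con)
      }
    }
  }
  invisible(path)
}

#' Filter markers on per-group missing rate
#'
#' A marker is kept iff, within every group listed in `max_missing_by_group`,
#' its missing fraction is less than or equal to the group's threshold
#' (removal requires the rate to be strictly above the threshold). Samples
#' whose group is not listed impose no constraint. The study design this
#' mirrors removes SNPs missing in more than 20% of the male-sterile testers
#' or more than 50% of the inbred female lines.
#'
#' @param g a [geno_matrix()] with group labels for every constrained sample
#' @param max_missing_by_group named numeric vector of fractions in `[0, 1]`,
#'   names are group labels
#' @return a [geno_matrix()] with the surviving markers, sample set unchanged
#' @export
qc_filter_missing <- function(g, max_missing_by_group) {
  stopifnot(is.numeric(max_missing_by_group),
            all(max_missing_by_group >= 0 & max_missing_by_group <= 1),
            !is.null(names(max_missing_by_group)))
  keep <- rep(TRUE, n_markers(g))
  for (grp in names(max_missing_by_group)) {
    in_grp <- !is.null(g$groups) & g$groups == grp
    if (!any(in_grp, na.rm = TRUE)) next
    sub <- g$calls[which(in_grp), , drop = FALSE]
    rate <- colMeans(is.na(sub))
    keep <- keep & (rate <= max_missing_by_group[[grp]])
  }
  if (!any(keep)) message("qc_filter_missing: no markers survive")
  subset_geno(g, markers = keep)
}

#' Impute missing calls and normalise coding to the minor allele
#'
#' Determines the minor allele of each marker from the non-missing calls of
#' all samples and re-orients codes so that `-1` is the minor-allele
#' homozygote and `+1` the major-allele homozygote (swapping the stored
#' ref/alt alleles where needed). A 50/50 allele-frequency tie is broken
#' lexicographically: the alphabetically smaller allele is treated as major.
#' Missing calls are then replaced by the per-marker mode of the observed
#' codes, a tie among modes giving `0`. Markers with no observed call are
#' dropped with a warning.
#'
#' @param g a [geno_matrix()], possibly with missing calls
#' @return a fully observed [geno_matrix()] in minor-allele orientation
#' @export
impute_and_encode <- function(g) {
  calls <- g$calls
  markers <- g$markers
  all_missing <- colSums(!is.na(calls)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " marker(s) with no observed call dropped")
    calls <- calls[, !all_missing, drop = FALSE]
    markers <- markers[!all_missing, , drop = FALSE]
  }
  for (j in seq_len(ncol(calls))) {
    x <- calls[, j]
    obs <- x[!is.na(x)]
    # frequency of the ref allele under +1 = ref-hom coding
    p_ref <- mean((obs + 1) / 2)
    flip <- if (p_ref < 0.5) TRUE
      else if (p_ref > 0.5) FALSE
      else markers$ref[j] > markers$alt[j]  # tie: smaller allele is major
    if (flip) {
      x <- -x
      tmp <- markers$ref[j]
      markers$ref[j] <- markers$alt[j]
      markers$alt[j] <- tmp
    }
    if (anyNA(x)) {
      obs <- x[!is.na(x)]
      counts <- table(obs)
      top <- names(counts)[counts == max(counts)]
      fill <- if (length(top) == 1) as.numeric(top) else 0
      x[is.na(x)] <- fill
    }
    calls[, j] <- x
  }
  geno_matrix(calls, markers, g$groups)
}

#' Intersect the marker sets of two genotype panels
#'
#' Keeps markers present in both panels, matched on `(chrom, pos)` with
#' allele sets `{ref, alt}` equal. Where panel `b` records the alleles in the
#' opposite order, its codes are negated to `a`'s orientation (a warning
#' notes strand-ambiguous A/T and C/G swaps, which are treated like any
#' other swap). Output marker order is `a`'s order.
#'
#' @param a,b [geno_matrix()] panels with marker metadata
#' @return list with elements `a` and `b`, both restricted to the shared
#'   markers and encoded in `a`'s orientation
#' @export
intersect_marker_sets <- function(a, b) {
  key_a <- paste(a$markers$chrom, a$markers$pos)
  key_b <- paste(b$markers$chrom, b$markers$pos)
  idx_b <- match(key_a, key_b)
  same <- !is.na(idx_b) &
    a$markers$ref == b$markers$ref[idx_b] &
    a$markers$alt == b$markers$alt[idx_b]
  swap <- !is.na(idx_b) &
    a$markers$ref == b$markers$alt[idx_b] &
    a$markers$alt == b$markers$ref[idx_b]
  keep_a <- which(same | swap)
  keep_b <- idx_b[keep_a]
  ambiguous <- swap[keep_a] &
    paste0(a$markers$ref[keep_a], a$markers$alt[keep_a]) %in%
      c("AT", "TA", "CG", "GC")
  if (any(ambiguous))
    warning(sum(ambiguous),
            " strand-ambiguous allele swap(s) re-oriented by negation")
  a2 <- subset_geno(a, markers = keep_a)
  calls_b <- b$calls[, keep_b, drop = FALSE]
  if (any(swap[keep_a]))
    calls_b[, swap[keep_a]] <- -calls_b[, swap[keep_a], drop = FALSE]
  b2 <- geno_matrix(calls_b, a2$markers, b$groups)
  list(a = a2, b = b2)
}
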