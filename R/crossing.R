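#' Enumerate a full factorial cross set
#'
#' Builds the NC II cross list: every female parent mated to every male
#' parent, ordered female-major then male. Hybrid ids are
#' `"female x male"` with the female first, the stable join key used
#' throughout the package.
#'
#' @param females,males character vectors of parent ids, unique within each
#'   list
#' @return data.frame of class `cross_set` with columns `hybrid_id`,
#'   `female`, `male`; `|females| * |males|` rows
#' @export
enumerate_crosses <- function(females, males) {
  stopifnot(length(females) > 0, length(males) > 0)
  if (anyDuplicated(females)) stop("duplicate id in females")
  if (anyDuplicated(males)) stop("duplicate id in males")
  grid <- expand.grid(male = males, female = females,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(hybrid_id = paste0(grid$female, "x", grid$male),
                    female = grid$female, male = grid$male,
                    stringsAsFactors = FALSE)
  class(out) <- c("cross_set", "data.frame")
  out
}

#' Deduce hybrid genotypes from parental genotypes
#'
#' Each hybrid's additive code at a marker is the mean of its two parents'
#' codes: opposite homozygotes give a heterozygous `0`, identical
#' homozygotes reproduce the parental code. A residually heterozygous parent
#' (code `0`) yields the expected dosage `+-0.5`, which is permitted and
#' flagged with a warning. Deduction is symmetric in the parents.
#'
#' @param parents a fully encoded [geno_matrix()] (no missing calls)
#'   containing every parent named in `crosses`
#' @param crosses a cross set from [enumerate_crosses()] (or any data.frame
#'   with `hybrid_id`, `female`, `male`)
#' @return a [geno_matrix()] of the hybrids, sample order = cross order
#' @export
deduce_hybrid_genotypes <- function(parents, crosses) {
  if (anyNA(parents$calls))
    stop("parents must be imputed/encoded before hybrid deduction")
  fidx <- match(crosses$female, rownames(parents$calls))
  midx <- match(crosses$male, rownames(parents$calls))
  if (anyNA(fidx) || anyNA(midx)) {
    bad <- unique(c(crosses$female[is.na(fidx)], crosses$male[is.na(midx)]))
    stop("unknown parent id(s): ", paste(head(bad, 5), collapse = ", "))
  }
  calls <- (parents$calls[fidx, , drop = FALSE] +
            parents$calls[midx, , drop = FALSE]) / 2
  rownames(calls) <- crosses$hybrid_id
  if (any(calls %in% c(-0.5, 0.5)))
    warning("heterozygous parent(s): hybrid codes include expected dosages of +-0.5")
  groups <- stats::setNames(rep("hybrid", nrow(calls)), rownames(calls))
  geno_matrix(calls, parents$markers, groups)
}
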