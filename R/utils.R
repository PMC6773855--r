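`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
#' Evaluate `expr` under a fixed RNG seed, restoring global RNG state on exit.
#' All simulators route randomness through this so no global state leaks.
local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Canonical variant identifier
#'
#' @param chrom,pos,ref,alt vectors describing decomposed biallelic variants.
#' @return character vector `chrom:pos:ref:alt`.
#' @keywords internal
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Alternate-allele dosage of a diploid genotype string
#'
#' @param gt character vector of unphased VCF genotypes (`"0/0"`, `"0/1"`,
#'   `"1/1"`, `"./."`).
#' @return integer dosage 0/1/2, `NA` for missing.
#' @export
gt_dose <- function(gt) {
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

#' Allele frequency from allele counts
#'
#' Plain ratio of allele count over allele number, the quantity population
#' databases print (e.g. gnomAD 18/24850 = 0.000724...).
#'
#' @param ac allele count (non-negative integer).
#' @param an allele number (positive integer, `an >= ac`).
#' @return numeric frequency in \[0, 1\].
#' @examples
#' allele_frequency(18, 24850)
#' @export
allele_frequency <- function(ac, an) {
  stopifnot(all(an > 0), all(ac >= 0), all(ac <= an))
  ac / an
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of comparisons.
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 6) # 0.00833...
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}
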