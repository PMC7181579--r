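#' Cross-tabulate a SNP pair against disease status
#'
#' Builds the 3 x 3 x 2 contingency tensor `X[i, j, k]` counting individuals
#' with `i` copies of the minor allele at the first locus, `j` copies at the
#' second locus, and disease status `k` (0 = unaffected, 1 = affected). This
#' tensor is the sole input of every pairwise entropy statistic.
#'
#' Individuals with a missing genotype at either locus are excluded pairwise,
#' so the effective sample size `N` may vary between SNP pairs.
#'
#' @param g1,g2 Integer genotype vectors coded 0/1/2 (minor-allele count);
#'   `NA` marks a missing genotype.
#' @param pheno Integer phenotype vector, 0 = unaffected, 1 = affected.
#' @return A `pair_counts` object: a 3 x 3 x 2 integer array with an `N`
#'   attribute giving the number of individuals counted.
#' @examples
#' count_pair(c(0, 0, 1), c(0, 1, 1), c(0, 1, 1))
#' @export
count_pair <- function(g1, g2, pheno) {
  n <- length(pheno)
  if (length(g1) != n || length(g2) != n) {
    stop("genotype columns and phenotype must have equal length")
  }
  if (!all(pheno[!is.na(pheno)] %in% c(0L, 1L))) {
    stop("phenotype must be binary 0/1")
  }
  keep <- !is.na(g1) & !is.na(g2) & !is.na(pheno)
  if (!any(keep)) stop("no individuals with complete data for this pair")
  g1 <- g1[keep]; g2 <- g2[keep]; pheno <- pheno[keep]
  if (!all(g1 %in% 0:2) || !all(g2 %in% 0:2)) {
    stop("genotypes must be coded 0/1/2 (minor-allele count) or NA")
  }
  counts <- array(
    tabulate(1L + g1 + 3L * g2 + 9L * pheno, nbins = 18L),
    dim = c(3, 3, 2),
    dimnames = list(g1 = 0:2, g2 = 0:2, status = 0:1)
  )
  pair_counts(counts)
}

#' Construct a pair-counts tensor from raw counts
#'
#' @param counts A 3 x 3 x 2 array (or 18-vector in column-major order) of
#'   non-negative integer counts; dimension 3 indexes disease status
#'   (unaffected, affected).
#' @return A validated `pair_counts` object with attribute `N`.
#' @export
pair_counts <- function(counts) {
  counts <- array(as.numeric(counts), dim = c(3, 3, 2),
                  dimnames = list(g1 = 0:2, g2 = 0:2, status = 0:1))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1) stop("pair_counts requires N >= 1")
  structure(counts, N = n, class = c("pair_counts", "array"))
}

#' @export
print.pair_counts <- function(x, ...) {
  cat("SNP-pair contingency tensor, N =", attr(x, "N"), "\n")
  print(unclass(x))
  invisible(x)
}

#' Relative frequencies, margins and dependence factors of a pair tensor
#'
#' Converts counts to plug-in probabilities `p[i, j, k] = X[i, j, k] / N` and
#' derives every margin the entropy statistics use, together with the
#' conditional-dependence factor
#' `e[i, j, k] = p_ijk * p_..k / (p_i.k * p_.jk)` (1 when the two genotypes
#' are conditionally independent given status) and the LD factor
#' `l[i, j] = p_ij. / (p_i.. * p_.j.)` (1 under linkage equilibrium).
#' Ratios whose denominator is zero are returned as `NA`; downstream
#' statistics never touch them because the matching numerator term is zero.
#'
#' @param counts A `pair_counts` object.
#' @return A list of class `prob_table` with elements `p` (3 x 3 x 2),
#'   margins `p_ij`, `p_i`, `p_j`, `p_ik`, `p_jk`, `p_k`, factors `e` and
#'   `l`, and the sample size `N`.
#' @export
normalize_counts <- function(counts) {
  counts <- pair_counts(counts)
  n <- attr(counts, "N")
  p <- unclass(counts) / n
  p_ij <- apply(p, c(1, 2), sum)
  p_ik <- apply(p, c(1, 3), sum)
  p_jk <- apply(p, c(2, 3), sum)
  p_i <- rowSums(p_ij)
  p_j <- colSums(p_ij)
  p_k <- colSums(p_ik)
  safe_div <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  e <- array(NA_real_, dim = c(3, 3, 2))
  for (k in 1:2) {
    e[, , k] <- safe_div(p[, , k] * p_k[k], outer(p_ik[, k], p_jk[, k]))
  }
  l <- safe_div(p_ij, outer(p_i, p_j))
  structure(
    list(p = p, p_ij = p_ij, p_i = p_i, p_j = p_j,
         p_ik = p_ik, p_jk = p_jk, p_k = p_k, e = e, l = l, N = n),
    class = "prob_table"
  )
}
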