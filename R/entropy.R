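# Plug-in entropy statistics for a 3x3x2 genotype-by-status tensor.
# Convention: 0 * log 0 := 0; any term with a zero numerator contributes
# nothing, which restricts the plug-in estimator to the observed support.

# sum of p * log2(p / q) over cells with p > 0
.xlogx_sum <- function(p, q) {
  i <- p > 0
  sum(p[i] * log2(p[i] / q[i]))
}

.as_counts <- function(counts) {
  if (!inherits(counts, "pair_counts")) counts <- pair_counts(counts)
  counts
}

.check_two_classes <- function(counts) {
  nk <- apply(unclass(counts), 3, sum)
  if (any(nk == 0)) stop("both phenotype classes must be present")
  nk
}

#' Shannon entropy of a discrete distribution
#'
#' @param probs Non-negative probability vector summing to 1.
#' @return Entropy in bits, with the convention 0·log2(0) = 0.
#' @examples
#' shannon_entropy(c(0.5, 0.5)) # 1 bit
#' @export
shannon_entropy <- function(probs) {
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) stop("probabilities must sum to 1")
  p <- probs[probs > 0]
  -sum(p * log2(p))
}

#' Mutual information of a two-way count table
#'
#' Plug-in estimate `sum_ij p_ij log2(p_ij / (p_i. p_.j))` in bits.
#'
#' @param tab A non-negative count (or probability) matrix, typically 3 x 3
#'   genotype-by-genotype.
#' @return Mutual information in bits.
#' @export
mutual_info <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  n <- sum(tab)
  if (n <= 0) stop("table must have positive total")
  p <- tab / n
  .xlogx_sum(p, outer(rowSums(p), colSums(p)))
}

#' Second-order information gain IG(D|G)
#'
#' The reduction in phenotype entropy from knowing the joint genotype at two
#' loci, `H(D) - H(D|G) = sum_ijk p_ijk log2(p_ijk / (p_ij. p_..k))`.
#' Sensitive to main effects as well as interaction.
#'
#' @param counts A `pair_counts` tensor (see [count_pair()]).
#' @return Information gain in bits (>= 0).
#' @export
info_gain2 <- function(counts) {
  counts <- .as_counts(counts)
  .check_two_classes(counts)
  pt <- normalize_counts(counts)
  q <- outer(c(pt$p_ij), pt$p_k)
  .xlogx_sum(c(pt$p), q)
}

#' First-order (single-locus) information gain IG(D|G1) or IG(D|G2)
#'
#' Main-effect information gain of one locus:
#' `sum_ik p_i.k log2(p_i.k / (p_i.. p_..k))`.
#'
#' @param counts A `pair_counts` tensor.
#' @param locus 1 or 2, which locus's margin to use.
#' @return Information gain in bits (>= 0).
#' @export
info_gain1 <- function(counts, locus) {
  counts <- .as_counts(counts)
  .check_two_classes(counts)
  pt <- normalize_counts(counts)
  if (locus == 1) {
    .xlogx_sum(c(pt$p_ik), c(outer(pt$p_i, pt$p_k)))
  } else if (locus == 2) {
    .xlogx_sum(c(pt$p_jk), c(outer(pt$p_j, pt$p_k)))
  } else stop("locus must be 1 or 2")
}

#' Modified information gain: interaction-only entropy statistic
#'
#' Removes both single-locus main effects from the second-order information
#' gain: `IGmod = IG(D|G) - IG(D|G1) - IG(D|G2)`. Under linkage equilibrium
#' this equals the conditional mutual information of the two genotypes given
#' disease status ([igmod0()]); with LD between the loci the two differ by a
#' term driven by the LD factor.
#'
#' @param counts A `pair_counts` tensor.
#' @return Statistic in bits (may be slightly negative under LD).
#' @export
igmod <- function(counts) {
  counts <- .as_counts(counts)
  info_gain2(counts) - info_gain1(counts, 1) - info_gain1(counts, 2)
}

#' Conditional mutual information of two genotypes given disease status
#'
#' The interaction statistic used for testing:
#' `IGmod0 = sum_k sum_ij p_ijk log2( p^k_ij / (p^k_i. p^k_.j) )`, the
#' case-stratum and control-stratum genotype-genotype mutual informations
#' weighted by the stratum frequencies. Always non-negative; under the null
#' of conditional independence it is approximately gamma distributed (see
#' [gamma_null()]).
#'
#' @param counts A `pair_counts` tensor.
#' @return Statistic in bits.
#' @export
igmod0 <- function(counts) {
  counts <- .as_counts(counts)
  nk <- .check_two_classes(counts)
  n <- attr(counts, "N")
  x <- unclass(counts)
  sum(vapply(1:2, function(k) nk[k] / n * mutual_info(x[, , k]), 0))
}

#' GenoCMI: conditional mutual information in nats
#'
#' Identical summation to [igmod0()] but with the natural logarithm, so
#' `geno_cmi = igmod0 * ln(2)`. Its asymptotic null is chi-squared(8)/(2N).
#'
#' @param counts A `pair_counts` tensor.
#' @return Statistic in nats.
#' @export
geno_cmi <- function(counts) {
  igmod0(counts) * log(2)
}

#' Case/control mutual-information difference T_IG
#'
#' The signed difference `MI(G1;G2 | cases) - MI(G1;G2 | controls)` in bits.
#' Significance is assessed by label permutation ([tig_test()]).
#'
#' @param counts A `pair_counts` tensor.
#' @return Signed statistic in bits.
#' @export
t_ig <- function(counts) {
  counts <- .as_counts(counts)
  .check_two_classes(counts)
  x <- unclass(counts)
  mutual_info(x[, , 2]) - mutual_info(x[, , 1])
}
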