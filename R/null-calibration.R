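#' Gamma null distribution for the conditional-mutual-information statistic
#'
#' Under the null hypothesis of conditional independence of the two
#' genotypes given disease status, the interaction statistics follow,
#' asymptotically and approximately, gamma distributions with scale
#' `1/(N ln 2)`. The conservative criterion uses shape 4, the law of the
#' plug-in conditional mutual information [igmod0()] — equivalent to
#' chi-squared(8)/(2N) for the natural-log statistic. The liberal criterion
#' (default) uses shape 2, i.e. chi-squared(4)/(2N): the law of the full
#' modification [igmod()], whose subtraction of the sample genotype-genotype
#' association removes half the degrees of freedom; empirically it calibrates
#' genome-scan type-I error closely, whereas shape 4 is conservative.
#'
#' @param n Sample size (individuals behind the statistic); must be >= 2.
#' @param criterion `"liberal"` (shape 2, default) or `"conservative"`
#'   (shape 4).
#' @return A `gamma_null` object with fields `shape`, `scale`, `n`.
#' @examples
#' gamma_null(1600, "liberal")
#' @export
gamma_null <- function(n, criterion = c("liberal", "conservative")) {
  criterion <- match.arg(criterion)
  if (!is.numeric(n) || length(n) != 1 || n < 2) stop("n must be >= 2")
  structure(
    list(shape = if (criterion == "liberal") 2 else 4,
         scale = 1 / (n * log(2)),
         n = n, criterion = criterion),
    class = "gamma_null"
  )
}

#' @export
print.gamma_null <- function(x, ...) {
  cat(sprintf("gamma null: shape %d, scale 1/(%g ln 2) = %.6g (%s)\n",
              x$shape, x$n, x$scale, x$criterion))
  invisible(x)
}

#' Upper-tail p-value of an interaction statistic under the gamma null
#'
#' Negative statistic values (possible for the full modification [igmod()],
#' whose LD term can exceed the conditional dependence term) carry no
#' evidence against the null and are clamped to 0, giving p = 1.
#'
#' @param stat Statistic in bits.
#' @param null A [gamma_null()] object.
#' @return P-value(s) in `[0, 1]`.
#' @export
pvalue_gamma <- function(stat, null) {
  stopifnot(inherits(null, "gamma_null"))
  stat <- pmax(stat, 0)
  stats::pgamma(stat, shape = null$shape, scale = null$scale,
                lower.tail = FALSE)
}

#' Decision threshold on the statistic scale
#'
#' Inverts the gamma survival function at the per-test significance level,
#' either given directly (`level`) or as a Bonferroni-corrected global level
#' (`alpha / m`). A statistic exceeding the returned cutoff is significant.
#'
#' @param null A [gamma_null()] object.
#' @param level Per-test significance level; exactly one of `level` or
#'   `alpha` must be given.
#' @param alpha Global significance level, Bonferroni-corrected by `m`.
#' @param m Number of tests for the Bonferroni correction.
#' @return Cutoff in bits such that `pvalue_gamma(cutoff, null)` equals the
#'   per-test level.
#' @examples
#' cutoff_gamma(gamma_null(1600, "liberal"), level = 1e-5) # 0.012837
#' @export
cutoff_gamma <- function(null, level = NULL, alpha = NULL, m = NULL) {
  stopifnot(inherits(null, "gamma_null"))
  if (is.null(level)) {
    if (is.null(alpha) || is.null(m)) {
      stop("give either a per-test `level` or both `alpha` and `m`")
    }
    if (alpha <= 0 || alpha >= 1 || m < 1) stop("need 0 < alpha < 1, m >= 1")
    level <- alpha / m
  } else if (!is.null(alpha) || !is.null(m)) {
    stop("give either `level` or (`alpha`, `m`), not both")
  }
  if (level <= 0) stop("per-test level underflows to zero")
  stats::qgamma(level, shape = null$shape, scale = null$scale,
                lower.tail = FALSE)
}
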