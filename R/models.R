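# Two-locus disease models: odds tables, penetrance conversion, prevalence,
# heritability, and the (alpha, theta) constraint solver.
#
# Rows index the first locus (aa, aA, AA = 0/1/2 minor alleles), columns the
# second (bb, bB, BB). Four models are parameterized by a prevalence
# parameter alpha and a multiplicative interaction parameter theta; the
# fifth ("no_margin") is a fixed table chosen so that all marginal odds are
# (approximately) equal, i.e. pure interaction with no main effects.

.model_names <- c("multiplicative", "epistasis", "two_allele", "xor",
                  "no_margin")

# exponent of (1 + theta) per cell for the parameterized models
.model_exponents <- list(
  multiplicative = rbind(c(0, 0, 0),
                         c(0, 1, 2),
                         c(0, 2, 4)),
  epistasis      = rbind(c(0, 1, 1),
                         c(1, 0, 0),
                         c(1, 0, 0)),
  two_allele     = rbind(c(0, 0, 1),
                         c(0, 1, 0),
                         c(1, 0, 0)),
  xor            = rbind(c(0, 1, 0),
                         c(1, 0, 1),
                         c(0, 1, 0))
)

.no_margin_odds <- rbind(c(0.03, 0.10, 0.08),
                         c(0.09, 0.01, 0.04),
                         c(0.10, 0.01, 0.00))

# ideal large-sample H/L/O risk patterns (see hlo.R)
.ideal_hlo <- list(
  multiplicative = c("HLL", "LHH", "LHH"),
  epistasis      = c("LHH", "HLL", "HLL"),
  two_allele     = c("LLH", "LHL", "HLL"),
  xor            = c("LHL", "HLH", "LHL"),
  no_margin      = c("LHH", "HLL", "HLO")
)

.geno_labels <- list(c("aa", "aA", "AA"), c("bb", "bB", "BB"))

#' Two-locus odds table for a named interaction model
#'
#' @param model One of `"multiplicative"`, `"epistasis"`, `"two_allele"`,
#'   `"xor"`, `"no_margin"`.
#' @param alpha Prevalence parameter (> 0); ignored for `"no_margin"`.
#' @param theta Multiplicative interaction parameter (> -1); ignored for
#'   `"no_margin"`.
#' @return A 3 x 3 matrix of disease odds, rows = first-locus genotypes
#'   aa/aA/AA, columns = second-locus genotypes bb/bB/BB, with attributes
#'   `model`, `alpha`, `theta`.
#' @examples
#' odds_table("epistasis", alpha = 0.1, theta = 1)
#' @export
odds_table <- function(model, alpha = NULL, theta = NULL) {
  model <- match.arg(model, .model_names)
  if (model == "no_margin") {
    o <- .no_margin_odds
    alpha <- NA_real_; theta <- NA_real_
  } else {
    if (is.null(alpha) || is.null(theta)) {
      stop("alpha and theta are required for model '", model, "'")
    }
    if (alpha <= 0) stop("alpha must be > 0")
    if (theta <= -1) stop("theta must be > -1")
    o <- alpha * (1 + theta)^.model_exponents[[model]]
  }
  dimnames(o) <- .geno_labels
  structure(o, model = model, alpha = alpha, theta = theta)
}

#' Convert disease odds to penetrances (or back)
#'
#' `penetrance = odds / (1 + odds)`; the inverse map is
#' `odds = penetrance / (1 - penetrance)`.
#'
#' @param odds Non-negative odds (any shape).
#' @return Penetrances in `[0, 1)`, same shape and attributes.
#' @export
odds_to_penetrance <- function(odds) {
  if (any(odds < 0)) stop("odds must be non-negative")
  out <- odds / (1 + odds)
  attributes(out) <- attributes(odds)
  out
}

#' Hardy-Weinberg genotype probabilities
#'
#' @param maf Minor allele frequency, in (0, 0.5].
#' @return Probability vector over 0/1/2 minor-allele copies:
#'   `((1-q)^2, 2q(1-q), q^2)`.
#' @export
hwe_probs <- function(maf) {
  if (maf <= 0 || maf > 0.5) stop("maf must lie in (0, 0.5]")
  c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
}

#' Population prevalence implied by a penetrance table
#'
#' Assumes the two loci are independent (linkage equilibrium) and each in
#' Hardy-Weinberg proportions: `K = sum_ij P(G_ij) f_ij`.
#'
#' @param pen 3 x 3 penetrance table.
#' @param maf1,maf2 Minor allele frequencies of the two loci.
#' @return Prevalence K.
#' @export
model_prevalence <- function(pen, maf1, maf2 = maf1) {
  sum(outer(hwe_probs(maf1), hwe_probs(maf2)) * pen)
}

#' Broad-sense heritability of a two-locus penetrance table
#'
#' `h2 = sum_ij P(G_ij) (f_ij - K)^2 / (K (1 - K))` with K the prevalence.
#'
#' @inheritParams model_prevalence
#' @return Heritability h2 in `[0, 1]`.
#' @export
model_heritability <- function(pen, maf1, maf2 = maf1) {
  k <- model_prevalence(pen, maf1, maf2)
  if (k <= 0 || k >= 1) stop("degenerate prevalence; heritability undefined")
  w <- outer(hwe_probs(maf1), hwe_probs(maf2))
  sum(w * (pen - k)^2) / (k * (1 - k))
}

#' Solve a parameterized model for target prevalence and heritability
#'
#' Finds `(alpha, theta)` such that the penetrance table derived from the
#' model's odds table has the requested prevalence and heritability. Nested
#' bisection: the inner solve picks `alpha` matching the prevalence for a
#' trial `theta` (prevalence is strictly increasing in `alpha`); the outer
#' solve picks `theta` matching the heritability (increasing in `theta`
#' once `alpha` is re-solved). Deterministic; both constraints verified to
#' 1e-8 on exit.
#'
#' @param model One of the four parameterized models (not `"no_margin"`).
#' @param maf Shared minor allele frequency of both interacting loci.
#' @param prevalence Target prevalence K (default 0.1).
#' @param h2 Target heritability (e.g. 0.03 multiplicative, 0.02 others).
#' @return A `model_spec` list: `model`, `maf`, `prevalence`, `h2`,
#'   `alpha`, `theta`, the solved `odds` and `penetrance` tables.
#' @examples
#' spec <- solve_model_params("epistasis", maf = 0.1, h2 = 0.02)
#' model_prevalence(spec$penetrance, 0.1)
#' @export
solve_model_params <- function(model, maf, prevalence = 0.1, h2) {
  model <- match.arg(model, setdiff(.model_names, "no_margin"))
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
  if (h2 < 0) stop("h2 must be >= 0")

  alpha_for <- function(theta) {
    f <- function(a) {
      model_prevalence(odds_to_penetrance(odds_table(model, a, theta)),
                       maf) - prevalence
    }
    stats::uniroot(f, c(1e-9, 1e3), tol = 1e-14)$root
  }
  h2_at <- function(theta) {
    a <- alpha_for(theta)
    model_heritability(odds_to_penetrance(odds_table(model, a, theta)), maf)
  }
  if (h2 == 0) {
    theta <- 0
  } else {
    g <- function(theta) h2_at(theta) - h2
    hi <- 1
    while (g(hi) < 0 && hi < 1e3) hi <- hi * 2
    if (g(hi) < 0) stop("heritability target unattainable for this model/MAF")
    theta <- stats::uniroot(g, c(1e-8, hi), tol = 1e-13)$root
  }
  alpha <- alpha_for(theta)
  odds <- odds_table(model, alpha, theta)
  pen <- odds_to_penetrance(odds)
  k_chk <- model_prevalence(pen, maf)
  h2_chk <- model_heritability(pen, maf)
  if (abs(k_chk - prevalence) > 1e-8 || abs(h2_chk - h2) > 1e-8) {
    stop(sprintf("solver did not converge: K=%.3e (target %.3e), h2=%.3e (target %.3e)",
                 k_chk, prevalence, h2_chk, h2))
  }
  structure(
    list(model = model, maf = maf, prevalence = prevalence, h2 = h2,
         alpha = alpha, theta = theta, odds = odds, penetrance = pen),
    class = "model_spec"
  )
}

#' Model specification for the fixed pure-interaction table
#'
#' The `"no_margin"` model is given directly as a 3 x 3 table (default
#' reading: odds, per the table's header; set `as_penetrance = TRUE` to
#' interpret the same values as penetrances, the convention of the model's
#' original source). Its nominal MAF is 0.25, at which the marginal effects
#' essentially vanish.
#'
#' @param maf Minor allele frequency of both loci (default 0.25).
#' @param as_penetrance Interpret the tabulated values as penetrances
#'   rather than odds.
#' @return A `model_spec` list (with `alpha`, `theta`, `h2` set to `NA`).
#' @export
no_margin_spec <- function(maf = 0.25, as_penetrance = FALSE) {
  odds <- odds_table("no_margin")
  pen <- if (as_penetrance) {
    structure(unclass(odds), dimnames = .geno_labels)
  } else {
    odds_to_penetrance(odds)
  }
  structure(
    list(model = "no_margin", maf = maf,
         prevalence = model_prevalence(pen, maf),
         h2 = model_heritability(pen, maf),
         alpha = NA_real_, theta = NA_real_, odds = odds, penetrance = pen),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("two-locus model '%s', MAF %.3g, K = %.4g, h2 = %.4g\n",
              x$model, x$maf, x$prevalence, x$h2))
  if (!is.na(x$alpha)) {
    cat(sprintf("  alpha = %.6g, theta = %.6g\n", x$alpha, x$theta))
  }
  cat("penetrance table:\n")
  print(round(matrix(as.numeric(x$penetrance), 3, 3,
                     dimnames = .geno_labels), 4))
  invisible(x)
}

#' Expected per-cell case:control odds in a case-control sample
#'
#' In a retrospective design with `n_case` cases and `n_control` controls
#' drawn from a population with prevalence K, the expected ratio of case to
#' control counts in genotype cell (i, j) is
#' `f_ij / (1 - f_ij) * (n_case / n_control) * (1 - K) / K`.
#'
#' @param pen 3 x 3 penetrance table.
#' @param maf1,maf2 Minor allele frequencies (used for the prevalence).
#' @param n_case,n_control Sample sizes of the two strata.
#' @return 3 x 3 matrix of expected case:control count ratios; cells with
#'   penetrance 1 are `Inf`.
#' @export
case_control_odds <- function(pen, maf1, maf2 = maf1,
                              n_case = 800, n_control = 800) {
  k <- model_prevalence(pen, maf1, maf2)
  out <- ifelse(pen < 1, pen / (1 - pen), Inf) *
    (n_case / n_control) * (1 - k) / k
  dimnames(out) <- .geno_labels
  out
}

#' Ideal large-sample High/Low/O pattern of a named model
#'
#' @param model Model name.
#' @return An `hlo_matrix` (see [classify_hlo()]) with the model's ideal
#'   risk-cell pattern.
#' @export
ideal_hlo <- function(model) {
  model <- match.arg(model, .model_names)
  hlo_matrix(do.call(rbind, strsplit(.ideal_hlo[[model]], "")))
}
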