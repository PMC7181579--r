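# Reference interaction tests used for benchmarking the entropy statistic.

#' 1-df additive logistic interaction test
#'
#' Fits `logit P(D=1) = b0 + b1 g1 + b2 g2 + b3 g1 g2` with additive 0/1/2
#' genotype coding and Wald-tests `b3` (the convention of PLINK's epistasis
#' module). Non-converged or separated fits are flagged and their p-value
#' reported as `NA` (counted as non-detection in power studies).
#'
#' @param g1,g2 Genotype vectors coded 0/1/2.
#' @param pheno Binary phenotype vector (0/1).
#' @return List: `method`, `statistic` (Wald z), `df`, `p`, `converged`.
#' @export
logreg_interaction <- function(g1, g2, pheno) {
  keep <- !is.na(g1) & !is.na(g2) & !is.na(pheno)
  g1 <- g1[keep]; g2 <- g2[keep]; pheno <- pheno[keep]
  if (length(unique(pheno)) != 2) stop("both phenotype classes required")
  fit <- suppressWarnings(
    stats::glm(pheno ~ g1 + g2 + I(g1 * g2), family = stats::binomial())
  )
  co <- summary(fit)$coefficients
  ok <- fit$converged && "I(g1 * g2)" %in% rownames(co) &&
    co["I(g1 * g2)", "Std. Error"] < 100
  if (!ok) {
    return(list(method = "logreg1df", statistic = NA_real_, df = 1,
                p = NA_real_, converged = FALSE))
  }
  z <- co["I(g1 * g2)", "z value"]
  list(method = "logreg1df", statistic = z, df = 1,
       p = 2 * stats::pnorm(-abs(z)), converged = TRUE)
}

# additive (0/1/2) and dominance (heterozygote indicator) codings
.add_dom <- function(g) list(a = as.numeric(g), d = as.numeric(g == 1))

#' 4-df likelihood-ratio test for interaction
#'
#' Compares a logistic model with 4 genetic parameters (additive and
#' dominance terms for each locus) against the full model adding the four
#' products a1a2, a1d2, d1a2, d1d2. The statistic is asymptotically
#' chi-squared with 4 df; when empty genotype cells make interaction terms
#' collinear, the reduced df is used and flagged.
#'
#' @inheritParams logreg_interaction
#' @return List: `method`, `statistic` (deviance difference), `df`, `p`,
#'   `converged`, `reduced_df` flag.
#' @export
lrt_interaction <- function(g1, g2, pheno) {
  keep <- !is.na(g1) & !is.na(g2) & !is.na(pheno)
  g1 <- g1[keep]; g2 <- g2[keep]; pheno <- pheno[keep]
  if (length(unique(pheno)) != 2) stop("both phenotype classes required")
  c1 <- .add_dom(g1); c2 <- .add_dom(g2)
  x0 <- cbind(1, c1$a, c1$d, c2$a, c2$d)
  x1 <- cbind(x0, c1$a * c2$a, c1$a * c2$d, c1$d * c2$a, c1$d * c2$d)
  f0 <- suppressWarnings(
    stats::glm.fit(x0, pheno, family = stats::binomial())
  )
  f1 <- suppressWarnings(
    stats::glm.fit(x1, pheno, family = stats::binomial())
  )
  df <- f1$rank - f0$rank
  stat <- max(f0$deviance - f1$deviance, 0)
  conv <- f0$converged && f1$converged
  list(method = "lrt4df", statistic = stat, df = df,
       p = if (df >= 1) stats::pchisq(stat, df, lower.tail = FALSE)
           else NA_real_,
       converged = conv, reduced_df = df < 4)
}

#' Permutation test for the case/control mutual-information difference
#'
#' Two-sided permutation p-value for [t_ig()], shuffling case/control
#' labels with the stratum sizes fixed:
#' `p = (1 + #{|T*| >= |T|}) / (1 + n_perm)`.
#'
#' @param counts A `pair_counts` tensor.
#' @param n_perm Number of permutations (>= 100).
#' @return List: `method`, `statistic` (observed T in bits), `p`,
#'   `n_perm`.
#' @export
tig_test <- function(counts, n_perm = 1000) {
  if (!inherits(counts, "pair_counts")) counts <- pair_counts(counts)
  if (n_perm < 100) stop("n_perm must be >= 100")
  obs <- t_ig(counts)
  x <- unclass(counts)
  tot <- x[, , 1] + x[, , 2]
  n1 <- sum(x[, , 2])
  # expand to per-individual cell memberships, permute labels among them
  cells <- rep(seq_len(9L), times = c(tot))
  n <- length(cells)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    lab1 <- sample.int(n, n1)
    case_cells <- tabulate(cells[lab1], nbins = 9L)
    perm <- array(c(c(tot) - case_cells, case_cells), dim = c(3, 3, 2))
    if (abs(t_ig(pair_counts(perm))) >= abs(obs) - 1e-15) {
      exceed <- exceed + 1L
    }
  }
  list(method = "tig", statistic = obs,
       p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}
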