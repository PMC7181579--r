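# Independent brute-force oracles: every statistic re-derived by direct
# triple-loop summation of its defining formula, sharing no code with the
# package internals.

oracle_probs <- function(x) {
  x <- unclass(x)
  p <- x / sum(x)
  list(
    p = p,
    p_ij = apply(p, c(1, 2), sum),
    p_ik = apply(p, c(1, 3), sum),
    p_jk = apply(p, c(2, 3), sum),
    p_i = apply(p, 1, sum),
    p_j = apply(p, 2, sum),
    p_k = apply(p, 3, sum)
  )
}

oracle_ig2 <- function(x) {
  m <- oracle_probs(x)
  s <- 0
  for (i in 1:3) for (j in 1:3) for (k in 1:2) {
    if (m$p[i, j, k] > 0) {
      s <- s + m$p[i, j, k] *
        log2(m$p[i, j, k] / (m$p_ij[i, j] * m$p_k[k]))
    }
  }
  s
}

oracle_ig1 <- function(x, locus) {
  m <- oracle_probs(x)
  marg <- if (locus == 1) m$p_ik else m$p_jk
  tot <- if (locus == 1) m$p_i else m$p_j
  s <- 0
  for (i in 1:3) for (k in 1:2) {
    if (marg[i, k] > 0) {
      s <- s + marg[i, k] * log2(marg[i, k] / (tot[i] * m$p_k[k]))
    }
  }
  s
}

oracle_mi <- function(tab) {
  p <- tab / sum(tab)
  ri <- rowSums(p); cj <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (ri[i] * cj[j]))
  }
  s
}

# stratum-weighted within-stratum MI (Eq.-11 form, term by term)
oracle_igmod0 <- function(x) {
  x <- unclass(x)
  m <- oracle_probs(x)
  s <- 0
  for (k in 1:2) {
    pk <- m$p_k[k]
    if (pk == 0) next
    for (i in 1:3) for (j in 1:3) {
      pij <- m$p[i, j, k]
      if (pij > 0) {
        s <- s + pij * log2((pij / pk) /
                              ((m$p_ik[i, k] / pk) * (m$p_jk[j, k] / pk)))
      }
    }
  }
  s
}

oracle_tig <- function(x) {
  x <- unclass(x)
  oracle_mi(x[, , 2]) - oracle_mi(x[, , 1])
}

# random non-degenerate count tensor with both strata occupied
rand_tensor <- function(n_max = 500) {
  repeat {
    x <- array(rpois(18, lambda = runif(1, 0.5, n_max / 18)), c(3, 3, 2))
    if (sum(x) >= 2 && sum(x[, , 1]) > 0 && sum(x[, , 2]) > 0) return(x)
  }
}

# tensor whose pooled 3x3 genotype margin is an exact outer product
rand_outer_tensor <- function() {
  u <- sample(1:4, 3, replace = TRUE)
  v <- sample(1:4, 3, replace = TRUE)
  pooled <- outer(u, v) * sample(1:3, 1)
  cases <- array(0L, c(3, 3))
  for (i in 1:3) for (j in 1:3) {
    cases[i, j] <- sample(0:pooled[i, j], 1)
  }
  x <- array(c(pooled - cases, cases), c(3, 3, 2))
  if (sum(x[, , 1]) == 0 || sum(x[, , 2]) == 0) return(rand_outer_tensor())
  x
}

# independent logistic fit by Newton-Raphson on the log-likelihood
oracle_logistic <- function(X, y, maxit = 200, tol = 1e-12) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * w, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  loglik <- sum(y * log(mu) + (1 - y) * log(1 - mu))
  list(beta = beta,
       vcov = solve(crossprod(X * (mu * (1 - mu)), X)),
       loglik = loglik)
}

solved_model <- local({
  cache <- list()
  function(model, maf) {
    key <- paste(model, maf)
    if (is.null(cache[[key]])) {
      h2 <- if (model == "multiplicative") 0.03 else 0.02
      cache[[key]] <<- solve_model_params(model, maf, 0.1, h2)
    }
    cache[[key]]
  }
})
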