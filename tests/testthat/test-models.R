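test_that("odds tables match the model patterns exactly", {
  set.seed(1)
  for (rep in 1:10) {
    a <- runif(1, 0.01, 2); th <- runif(1, -0.5, 5)
    bare <- function(o) matrix(as.numeric(o), 3, 3)
    expect_equal(bare(odds_table("multiplicative", a, th)),
                 a * (1 + th)^rbind(c(0, 0, 0), c(0, 1, 2), c(0, 2, 4)))
    expect_equal(bare(odds_table("epistasis", a, th)),
                 a * (1 + th)^rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0)))
    expect_equal(bare(odds_table("two_allele", a, th)),
                 a * (1 + th)^rbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0)))
    expect_equal(bare(odds_table("xor", a, th)),
                 a * (1 + th)^rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
    # theta = 0: no interaction, constant odds
    expect_true(all(odds_table("multiplicative", a, 0) == a))
  }
  o <- odds_table("no_margin")
  expect_equal(o["aa", "bb"], 0.03)
  expect_equal(o["aA", "bB"], 0.01)
  expect_equal(o["AA", "BB"], 0)
  expect_equal(o["aa", "bB"], 0.10)
  expect_error(odds_table("banana", 1, 1))
  expect_error(odds_table("xor", -1, 1), "alpha")
})

test_that("odds/penetrance conversion is the right bijection", {
  expect_equal(odds_to_penetrance(1), 0.5)
  expect_equal(odds_to_penetrance(0), 0)
  expect_equal(odds_to_penetrance(0.03), 0.03 / 1.03)
  o <- 10^runif(50, -3, 3)
  p <- odds_to_penetrance(o)
  expect_equal(p / (1 - p), o, tolerance = 1e-12)
  expect_error(odds_to_penetrance(-0.1), "non-negative")
})

test_that("Hardy-Weinberg probabilities", {
  expect_equal(hwe_probs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_probs(0.25), c(0.5625, 0.375, 0.0625))
  expect_equal(sum(hwe_probs(0.123)), 1)
  expect_equal(hwe_probs(1e-9), c(1, 0, 0), tolerance = 1e-8)
  expect_error(hwe_probs(0.6), "maf")
  expect_error(hwe_probs(0), "maf")
})

test_that("prevalence and heritability: closed-form and 9-term oracle", {
  pen_c <- matrix(0.07, 3, 3)
  expect_equal(model_prevalence(pen_c, 0.3), 0.07)
  expect_equal(model_heritability(pen_c, 0.3), 0)
  expect_equal(model_prevalence(matrix(0, 3, 3), 0.2), 0)

  pen <- odds_to_penetrance(unclass(odds_table("no_margin")))
  w1 <- hwe_probs(0.25)
  k_oracle <- 0; h_oracle <- 0
  for (i in 1:3) for (j in 1:3) {
    k_oracle <- k_oracle + w1[i] * w1[j] * pen[i, j]
  }
  for (i in 1:3) for (j in 1:3) {
    h_oracle <- h_oracle + w1[i] * w1[j] * (pen[i, j] - k_oracle)^2
  }
  h_oracle <- h_oracle / (k_oracle * (1 - k_oracle))
  expect_equal(model_prevalence(pen, 0.25), k_oracle, tolerance = 1e-14)
  expect_equal(model_heritability(pen, 0.25), h_oracle, tolerance = 1e-14)

  # deterministic penetrance with P(pen = 1) = K has heritability 1
  pen_d <- matrix(0, 3, 3); pen_d[1, 1] <- 1
  q <- 0.3; k <- hwe_probs(q)[1]^2
  expect_equal(model_heritability(pen_d, q), 1, tolerance = 1e-12)
  expect_error(model_heritability(matrix(0, 3, 3), 0.2), "degenerate")
})

test_that("solver round-trips prevalence and heritability for all 12 designs", {
  for (model in c("multiplicative", "epistasis", "two_allele", "xor")) {
    h2 <- if (model == "multiplicative") 0.03 else 0.02
    for (maf in c(0.1, 0.2, 0.4)) {
      sp <- solved_model(model, maf)
      expect_equal(model_prevalence(sp$penetrance, maf), 0.1,
                   tolerance = 1e-8)
      expect_equal(model_heritability(sp$penetrance, maf), h2,
                   tolerance = 1e-8)
      expect_gt(sp$theta, 0)
      # deterministic: resolving reproduces the same parameters
      sp2 <- solve_model_params(model, maf, 0.1, h2)
      expect_equal(sp2$alpha, sp$alpha, tolerance = 1e-10)
      expect_equal(sp2$theta, sp$theta, tolerance = 1e-10)
    }
  }
})

test_that("h2 = 0 collapses to the analytic constant-odds solution", {
  sp <- solve_model_params("epistasis", 0.2, 0.1, 0)
  expect_equal(sp$theta, 0)
  expect_equal(sp$alpha, 0.1 / 0.9, tolerance = 1e-8)
  expect_true(all(abs(sp$penetrance - 0.1) < 1e-8))
})

test_that("case-control odds follow the retrospective sampling identity", {
  k <- 0.1
  pen <- matrix(k, 3, 3)
  cco <- case_control_odds(pen, 0.3, n_case = 800, n_control = 800)
  expect_true(all(abs(cco - 1) < 1e-12))

  sp <- solved_model("multiplicative", 0.4)
  cco <- case_control_odds(sp$penetrance, 0.4)
  oracle <- unclass(sp$penetrance) / (1 - unclass(sp$penetrance)) *
    (1 - 0.1) / 0.1
  expect_equal(unclass(cco), oracle, tolerance = 1e-8, ignore_attr = TRUE)

  pen1 <- matrix(0.5, 3, 3); pen1[3, 3] <- 1
  expect_true(is.infinite(case_control_odds(pen1, 0.3)[3, 3]))
})

test_that("no_margin spec supports both readings of the fixed table", {
  sp_odds <- no_margin_spec()
  expect_equal(unclass(sp_odds$penetrance)[1, 1], 0.03 / 1.03)
  sp_pen <- no_margin_spec(as_penetrance = TRUE)
  expect_equal(unclass(sp_pen$penetrance)[1, 1], 0.03)
  expect_equal(unclass(sp_pen$penetrance)[3, 3], 0)
  # marginal penetrances approximately flat at MAF 0.25 (no main effects)
  w <- hwe_probs(0.25)
  marg1 <- as.vector(unclass(sp_odds$penetrance) %*% w)
  expect_lt(diff(range(marg1)) / mean(marg1), 0.12)
})
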