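test_that("ld_r2 behaves as squared genotype correlation", {
  set.seed(91)
  g1 <- sample(0:2, 500, replace = TRUE, prob = hwe_probs(0.3))
  expect_equal(ld_r2(g1, g1), 1)
  expect_equal(ld_r2(g1, 2 - g1), 1)      # allele-flip invariant
  g2 <- sample(0:2, 500, replace = TRUE, prob = hwe_probs(0.3))
  expect_equal(ld_r2(g1, g2), cor(g1, g2)^2, tolerance = 1e-12)
  expect_true(is.na(ld_r2(rep(1, 10), sample(0:2, 10, replace = TRUE))))
  # independent columns at large n: r^2 ~ 1/n
  g1 <- sample(0:2, 1e5, replace = TRUE, prob = hwe_probs(0.25))
  g2 <- sample(0:2, 1e5, replace = TRUE, prob = hwe_probs(0.25))
  expect_lt(ld_r2(g1, g2), 0.001)
})

test_that("pairwise scan enumerates, filters and orders pairs", {
  set.seed(92)
  sp <- solved_model("epistasis", 0.4)
  cfg <- sim_config(sp, n_cases = 400, n_controls = 400, n_snps = 12,
                    seed = 8)
  d <- simulate_dataset(cfg, 1)
  res <- pairwise_scan(d$genotypes, d$pheno,
                       scan_config(ld_r2_max = Inf,
                                   per_test_level = 1e-5))
  expect_s3_class(res, "scan_result")
  expect_equal(nrow(res$pairs), choose(12, 2))
  expect_equal(nrow(res$filtered), 0)
  # deterministic (i, j) ordering
  expect_true(all(res$pairs$snp1 <= res$pairs$snp2))
  # the interacting pair is the top statistic and flagged
  top <- res$pairs[which.max(res$pairs$igmod), ]
  expect_equal(sort(c(top$snp1, top$snp2)), c("snp001", "snp002"))
  expect_true(top$significant)
  expect_false(is.na(top$hlo))
  expect_equal(top$submodel, match_submodel(hlo_matrix(top$hlo)))
  # p-values under both shapes present, conservative is larger
  expect_true(all(res$pairs$p_conservative >= res$pairs$p_liberal))

  # LD filter: duplicated column pair is excluded and logged
  g <- cbind(d$genotypes[, 1:4], d$genotypes[, 4])
  res2 <- pairwise_scan(g, d$pheno, scan_config(ld_r2_max = 0.01,
                                                per_test_level = 1e-5))
  expect_true(any(res2$filtered$reason == "ld"))
  expect_equal(nrow(res2$pairs) + nrow(res2$filtered), choose(5, 2))
})

test_that("scan statistics are invariant to SNP input order", {
  set.seed(93)
  sp <- solved_model("xor", 0.2)
  cfg <- sim_config(sp, n_cases = 300, n_controls = 300, n_snps = 6,
                    seed = 9)
  d <- simulate_dataset(cfg, 1)
  cfg_scan <- scan_config(ld_r2_max = Inf, per_test_level = 1e-5)
  res_a <- pairwise_scan(d$genotypes, d$pheno, cfg_scan)
  perm <- c(4, 1, 6, 2, 5, 3)
  res_b <- pairwise_scan(d$genotypes[, perm], d$pheno, cfg_scan,
                         snp_ids = sprintf("snp%03d", perm))
  key <- function(df) {
    k <- paste(pmin(df$snp1, df$snp2), pmax(df$snp1, df$snp2))
    df$igmod[order(k)]
  }
  expect_equal(key(res_a$pairs), key(res_b$pairs), tolerance = 1e-12)
})

test_that("PED/MAP reading recodes to minor-allele counts", {
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  writeLines(c(
    "6 rs001 0 1000 A",
    "6 rs002 0 2000 A"
  ), map)
  # rs1: alleles G (common) / T (minor); rs2: C common / G minor
  writeLines(c(
    "f1 i1 0 0 1 2  G G  C C",
    "f2 i2 0 0 1 1  G T  C G",
    "f3 i3 0 0 1 2  T T  G G",
    "f4 i4 0 0 1 1  G G  0 0",
    "f5 i5 0 0 1 -9 G G  C C"
  ), ped)
  expect_message(x <- read_ped_map(ped, map), "dropped")
  expect_equal(dim(x$genotypes), c(4, 2))
  expect_equal(x$genotypes[, 1], c(0L, 1L, 2L, 0L))
  # rs002 alleles tie 3 C : 3 G, so the lexicographic rule makes C minor
  expect_equal(x$genotypes[, 2], c(2L, 1L, 0L, NA))
  expect_equal(x$pheno, c(1L, 0L, 1L, 0L))
  expect_equal(x$snp_ids, c("rs001", "rs002"))
  expect_equal(x$positions, c(1000, 2000))

  writeLines(c("f1 i1 0 0 1 2 G G"), ped)
  expect_error(read_ped_map(ped, map), "malformed PED line 1")
  writeLines(c("f1 i1 0 0 1 0 G G C C"), ped)
  expect_error(read_ped_map(ped, map), "phenotype")
})

test_that("allele-swapped PED yields identical interaction statistics", {
  set.seed(94)
  n <- 120
  g1 <- sample(0:2, n, replace = TRUE, prob = hwe_probs(0.3))
  g2 <- sample(0:2, n, replace = TRUE, prob = hwe_probs(0.4))
  ph <- rep(c(2, 1), length.out = n)
  alleles <- function(g, a, b) {
    vapply(g, function(x) switch(x + 1,
                                 paste(a, a), paste(a, b), paste(b, b)),
           "")
  }
  write_ped <- function(a1, b1, a2, b2) {
    ped <- tempfile(fileext = ".ped")
    writeLines(sprintf("f%d i%d 0 0 1 %d %s %s", 1:n, 1:n, ph,
                       alleles(g1, a1, b1), alleles(g2, a2, b2)), ped)
    ped
  }
  map <- tempfile(fileext = ".map")
  writeLines(c("1 s1 0 1 A", "1 s2 0 2 A"), map)
  x1 <- read_ped_map(write_ped("G", "T", "C", "A"), map)
  x2 <- read_ped_map(write_ped("T", "G", "A", "C"), map)  # labels swapped
  s1 <- igmod0(count_pair(x1$genotypes[, 1], x1$genotypes[, 2], x1$pheno))
  s2 <- igmod0(count_pair(x2$genotypes[, 1], x2$genotypes[, 2], x2$pheno))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("genotype CSV reading validates and round-trips", {
  csv <- tempfile(fileext = ".csv")
  d <- data.frame(s1 = c(0, 1, 2, NA), s2 = c(2, 1, 0, 1),
                  phenotype = c(0, 1, 1, 0))
  write.csv(d, csv, row.names = FALSE)
  x <- read_genotype_csv(csv)
  expect_equal(x$genotypes[, "s1"], c(0L, 1L, 2L, NA), ignore_attr = TRUE)
  expect_equal(x$pheno, c(0L, 1L, 1L, 0L))
  d$s1[1] <- 3
  write.csv(d, csv, row.names = FALSE)
  expect_error(read_genotype_csv(csv), "0, 1, 2 or NA")
})

test_that("results TSV writes and re-reads with flags intact", {
  set.seed(95)
  sp <- solved_model("epistasis", 0.4)
  cfg <- sim_config(sp, n_cases = 400, n_controls = 400, n_snps = 6,
                    seed = 10)
  d <- simulate_dataset(cfg, 1)
  res <- pairwise_scan(d$genotypes, d$pheno,
                       scan_config(ld_r2_max = Inf, per_test_level = 1e-5))
  out <- tempfile(fileext = ".tsv")
  write_scan_results(res, out)
  back <- read.delim(out)
  expect_equal(nrow(back), nrow(res$pairs))
  expect_equal(back$significant, res$pairs$significant)
  expect_equal(back$snp1, res$pairs$snp1)
  expect_equal(as.numeric(back$p_liberal), res$pairs$p_liberal,
               tolerance = 1e-5)
})
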