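# Retrospective (case-control) simulation of two-locus interaction data,
# plus the type-I-error and power study drivers.

#' Derive a per-replicate seed from the root seed
#'
#' Affine counter scheme `(69069 * seed + replicate) mod (2^31 - 1)`, so any
#' subset of replicates can be regenerated independently of the others.
#'
#' @param seed Root integer seed.
#' @param replicate Replicate index (1-based).
#' @return Integer seed below 2^31.
#' @export
replicate_seed <- function(seed, replicate) {
  as.integer((69069 * (seed %% 2^31) + replicate) %% 2147483647)
}

#' Simulation configuration
#'
#' Defaults mirror the study design the package's power and type-I results
#' are computed under: 100 SNPs of which the first two interact, 800 cases
#' and 800 controls, 1000 replicates, null-SNP MAFs drawn uniformly from
#' (0.05, 0.5).
#'
#' @param model_spec A solved [solve_model_params()] / [no_margin_spec()]
#'   model for the interacting pair.
#' @param n_cases,n_controls Stratum sample sizes.
#' @param n_snps Total number of SNPs in each simulated dataset.
#' @param interacting_idx Indices of the two interacting SNP columns.
#' @param null_maf_range Range the null-SNP MAFs are drawn from.
#' @param n_replicates Number of replicate datasets.
#' @param seed Root seed; replicate r uses [replicate_seed()]`(seed, r)`.
#' @return A `sim_config` list.
#' @export
sim_config <- function(model_spec, n_cases = 800, n_controls = 800,
                       n_snps = 100, interacting_idx = c(1, 2),
                       null_maf_range = c(0.05, 0.5),
                       n_replicates = 1000, seed = 1) {
  stopifnot(inherits(model_spec, "model_spec"),
            n_snps >= 2, length(interacting_idx) == 2,
            interacting_idx[1] != interacting_idx[2],
            all(interacting_idx >= 1), all(interacting_idx <= n_snps))
  structure(
    list(model_spec = model_spec, n_cases = n_cases,
         n_controls = n_controls, n_snps = n_snps,
         interacting_idx = interacting_idx,
         null_maf_range = null_maf_range,
         n_replicates = n_replicates, seed = seed),
    class = "sim_config"
  )
}

#' Sample genotypes of the interacting pair, conditional on status
#'
#' Retrospective sampling: cases are drawn from the 9-cell distribution
#' `P(G_ij | D1) = P(G_ij) f_ij / K` and controls from
#' `P(G_ij | D0) = P(G_ij) (1 - f_ij) / (1 - K)`, with `P(G_ij)` the
#' Hardy-Weinberg product and `f` the model's penetrance table. This yields
#' exact case/control counts, as in retrospective generators such as
#' GAMETES.
#'
#' @param model_spec A solved model.
#' @param n_cases,n_controls Numbers of cases/controls to draw.
#' @return List with integer vectors `g1`, `g2` (cases first) and `pheno`.
#' @export
sample_interacting_pair <- function(model_spec, n_cases, n_controls) {
  w <- outer(hwe_probs(model_spec$maf), hwe_probs(model_spec$maf))
  pen <- unclass(model_spec$penetrance)
  draw <- function(mass, n) {
    if (n == 0) return(integer(0))
    if (sum(mass) <= 0) stop("conditional genotype distribution has no mass")
    sample.int(9L, n, replace = TRUE, prob = c(mass))
  }
  cells <- c(draw(w * pen, n_cases), draw(w * (1 - pen), n_controls))
  list(g1 = (cells - 1L) %% 3L,
       g2 = (cells - 1L) %/% 3L,
       pheno = rep(c(1L, 0L), c(n_cases, n_controls)))
}

#' Sample phenotype-independent null SNPs
#'
#' Each SNP receives its own MAF drawn uniformly from `maf_range`
#' (redrawn per dataset) and genotypes i.i.d. in Hardy-Weinberg
#' proportions, independent of disease status.
#'
#' @param n_individuals,n_snps Matrix dimensions.
#' @param maf_range MAF range, within (0, 0.5].
#' @return Integer genotype matrix (individuals x SNPs).
#' @export
sample_null_snps <- function(n_individuals, n_snps,
                             maf_range = c(0.05, 0.5)) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  mafs <- stats::runif(n_snps, maf_range[1], maf_range[2])
  g <- vapply(mafs, function(q) {
    sample.int(3L, n_individuals, replace = TRUE, prob = hwe_probs(q)) - 1L
  }, integer(n_individuals))
  matrix(g, nrow = n_individuals, ncol = n_snps)
}

#' Simulate one replicate dataset
#'
#' @param config A [sim_config()].
#' @param replicate Replicate index; together with the config seed it fully
#'   determines the dataset.
#' @return List with `genotypes` (n x m integer matrix), `pheno` (cases
#'   first), `snp_ids`, and the `interacting_idx`.
#' @export
simulate_dataset <- function(config, replicate = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(replicate_seed(config$seed, replicate))
  n <- config$n_cases + config$n_controls
  pair <- sample_interacting_pair(config$model_spec,
                                  config$n_cases, config$n_controls)
  g <- matrix(0L, n, config$n_snps)
  if (config$n_snps > 2) {
    g[, -config$interacting_idx] <-
      sample_null_snps(n, config$n_snps - 2L, config$null_maf_range)
  }
  g[, config$interacting_idx[1]] <- pair$g1
  g[, config$interacting_idx[2]] <- pair$g2
  list(genotypes = g, pheno = pair$pheno,
       snp_ids = sprintf("snp%03d", seq_len(config$n_snps)),
       interacting_idx = config$interacting_idx)
}

# weighted sum over strata of within-stratum pairwise MI, via
# genotype-indicator cross-products; `weight_n` is the denominator of the
# p_ijk weights (total N for stratified sums, stratum size for pooled MI)
.mi_pairs_stratum <- function(gk, weight_n) {
  nk <- nrow(gk)
  m <- ncol(gk)
  out <- matrix(0, m, m)
  ind <- lapply(0:2, function(a) matrix(as.numeric(gk == a), nk, m))
  marg <- vapply(ind, colSums, numeric(m))
  for (a in 1:3) {
    for (b in 1:3) {
      cab <- crossprod(ind[[a]], ind[[b]])
      e <- outer(marg[, a], marg[, b])
      pos <- cab > 0
      out[pos] <- out[pos] +
        (cab[pos] / weight_n) * log2(cab[pos] * nk / e[pos])
    }
  }
  out
}

#' Conditional mutual information for every SNP pair at once
#'
#' Vectorized computation of [igmod0()] over all column pairs of a complete
#' (no missing data) genotype matrix, via genotype-indicator cross-products.
#' Agrees with the per-pair scalar path to numerical precision.
#'
#' @param genotypes Integer matrix (individuals x SNPs), entries 0/1/2.
#' @param pheno Binary phenotype vector (0/1), both classes present.
#' @return Symmetric m x m matrix of statistics in bits (`NA` diagonal).
#' @export
igmod0_all_pairs <- function(genotypes, pheno) {
  if (anyNA(genotypes)) stop("fast path requires complete genotypes")
  n <- nrow(genotypes)
  if (length(pheno) != n) stop("phenotype length mismatch")
  out <- 0
  for (k in 0:1) {
    gk <- genotypes[pheno == k, , drop = FALSE]
    if (nrow(gk) == 0) stop("both phenotype classes must be present")
    out <- out + .mi_pairs_stratum(gk, n)
  }
  diag(out) <- NA
  out
}

#' Full modified information gain for every SNP pair at once
#'
#' Vectorized [igmod()] over all column pairs: the stratified conditional
#' mutual information minus the pooled genotype-genotype mutual
#' information (`igmod = igmod0 - MI(G1; G2)`), the identity behind the
#' decomposition `IG2 - IG1(locus 1) - IG1(locus 2)`. This is the
#' statistic the study drivers and the scan test against the liberal
#' shape-2 gamma null.
#'
#' @inheritParams igmod0_all_pairs
#' @return Symmetric m x m matrix of statistics in bits (`NA` diagonal).
#' @export
igmod_all_pairs <- function(genotypes, pheno) {
  if (anyNA(genotypes)) stop("fast path requires complete genotypes")
  n <- nrow(genotypes)
  igmod0_all_pairs(genotypes, pheno) - .mi_pairs_stratum(genotypes, n)
}

#' Type-I error study over non-interacting SNP pairs
#'
#' For each configuration and replicate, simulates a dataset, computes the
#' interaction statistic for every SNP pair except the interacting one (at
#' the defaults, 4949 of 4950 pairs — including pairs pairing a main-effect
#' SNP with a null SNP), converts to gamma p-values, and tallies the
#' empirical rejection proportion at each threshold.
#'
#' @param configs A [sim_config()] or list of them.
#' @param thresholds Nominal p-value thresholds to evaluate.
#' @param criterion Gamma criterion for p-values (`"liberal"` shape 2 or
#'   `"conservative"` shape 4).
#' @param statistic `"igmod"` (default; pairs with the liberal null) or
#'   `"igmod0"` (the no-LD form, whose null is the conservative shape 4).
#' @return A `type1_study` list: `thresholds`, pooled rejection proportions
#'   `prop`, total pair count `n_pairs`, and the per-replicate rejection
#'   proportions `per_replicate` (replicates x thresholds matrix) for
#'   Monte-Carlo error assessment.
#' @export
run_type1_study <- function(configs, thresholds = c(5e-2, 5e-3, 5e-4),
                            criterion = "liberal",
                            statistic = c("igmod", "igmod0")) {
  statistic <- match.arg(statistic)
  if (inherits(configs, "sim_config")) configs <- list(configs)
  stat_fun <- if (statistic == "igmod") igmod_all_pairs else
    igmod0_all_pairs
  per_rep <- list()
  n_pairs <- 0
  for (cfg in configs) {
    null <- gamma_null(cfg$n_cases + cfg$n_controls, criterion)
    keep <- upper.tri(matrix(0, cfg$n_snps, cfg$n_snps))
    keep[cfg$interacting_idx[1], cfg$interacting_idx[2]] <- FALSE
    keep[cfg$interacting_idx[2], cfg$interacting_idx[1]] <- FALSE
    for (r in seq_len(cfg$n_replicates)) {
      d <- simulate_dataset(cfg, r)
      stat <- stat_fun(d$genotypes, d$pheno)[keep]
      p <- pvalue_gamma(stat, null)
      per_rep[[length(per_rep) + 1L]] <-
        vapply(thresholds, function(t) mean(p < t), 0)
      n_pairs <- n_pairs + length(p)
    }
  }
  per_rep <- do.call(rbind, per_rep)
  colnames(per_rep) <- format(thresholds)
  structure(
    list(thresholds = thresholds, prop = colMeans(per_rep),
         n_pairs = n_pairs, per_replicate = per_rep,
         criterion = criterion),
    class = "type1_study"
  )
}

#' @export
print.type1_study <- function(x, ...) {
  cat(sprintf("type-I error over %d null pairs (%s gamma):\n",
              x$n_pairs, x$criterion))
  se <- apply(x$per_replicate, 2, stats::sd) / sqrt(nrow(x$per_replicate))
  for (i in seq_along(x$thresholds)) {
    cat(sprintf("  nominal %.0e -> empirical %.4g (MC se %.2g)\n",
                x$thresholds[i], x$prop[i], se[i]))
  }
  invisible(x)
}

#' Power study for the interacting pair
#'
#' Simulates `n_replicates` case-control draws of the interacting pair and
#' records, per replicate: the conditional-mutual-information statistic and
#' its detection at the supplied cutoff, comparator detections at `level`,
#' and the HLO classification of the pair (see [classify_hlo()]). Only the
#' interacting pair is generated — null SNPs play no role in pair-level
#' power.
#'
#' @param config A [sim_config()].
#' @param methods Subset of `c("entropy", "logreg", "lrt", "tig")`;
#'   `"entropy"` is detection by the entropy statistic at `cutoff`.
#' @param cutoff Statistic cutoff in bits; default the liberal-gamma
#'   cutoff at per-test level `level`.
#' @param level Per-test significance level for the comparator tests
#'   (default 1e-5).
#' @param n_perm Permutations for the `tig` test.
#' @param statistic Entropy statistic tested against `cutoff`: `"igmod"`
#'   (default) or `"igmod0"`.
#' @param cell_alpha,min_cell_n,adjust Passed to [classify_hlo()].
#' @return A `power_study` with a per-replicate data frame `replicates`,
#'   overall `power` per method, and `by_hlo`: frequency and conditional
#'   power of each observed HLO pattern (sorted by frequency).
#' @export
run_power_study <- function(config, methods = c("entropy", "logreg"),
                            cutoff = NULL, level = 1e-5,
                            n_perm = 1000,
                            statistic = c("igmod", "igmod0"),
                            cell_alpha = 0.1, min_cell_n = 10,
                            adjust = c("codominant", "none")) {
  stopifnot(inherits(config, "sim_config"))
  adjust <- match.arg(adjust)
  statistic <- match.arg(statistic)
  methods <- match.arg(methods, c("entropy", "logreg", "lrt", "tig"),
                       several.ok = TRUE)
  stat_fun <- if (statistic == "igmod") igmod else igmod0
  n <- config$n_cases + config$n_controls
  if (is.null(cutoff)) {
    cutoff <- cutoff_gamma(gamma_null(n, "liberal"), level = level)
  }
  rows <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    set.seed(replicate_seed(config$seed, r))
    pair <- sample_interacting_pair(config$model_spec,
                                    config$n_cases, config$n_controls)
    cnt <- count_pair(pair$g1, pair$g2, pair$pheno)
    hlo <- classify_hlo(cnt, cell_alpha = cell_alpha,
                        min_cell_n = min_cell_n, adjust = adjust)
    row <- list(replicate = r, stat = stat_fun(cnt),
                hlo = hlo_string(hlo), submodel = match_submodel(hlo))
    if ("entropy" %in% methods) row$entropy <- row$stat > cutoff
    if ("logreg" %in% methods) {
      p <- logreg_interaction(pair$g1, pair$g2, pair$pheno)$p
      row$logreg <- !is.na(p) && p < level
    }
    if ("lrt" %in% methods) {
      p <- lrt_interaction(pair$g1, pair$g2, pair$pheno)$p
      row$lrt <- !is.na(p) && p < level
    }
    if ("tig" %in% methods) {
      row$tig <- tig_test(cnt, n_perm = n_perm)$p < level
    }
    rows[[r]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  reps <- do.call(rbind, rows)
  method_cols <- intersect(c("entropy", "logreg", "lrt", "tig"),
                           names(reps))
  power <- vapply(method_cols, function(mth) mean(reps[[mth]]), 0)
  by_hlo <- do.call(rbind, lapply(split(reps, reps$hlo), function(d) {
    out <- data.frame(hlo = d$hlo[1], freq = nrow(d) / nrow(reps))
    for (mth in method_cols) out[[mth]] <- mean(d[[mth]])
    out
  }))
  by_hlo <- by_hlo[order(-by_hlo$freq), , drop = FALSE]
  rownames(by_hlo) <- NULL
  structure(
    list(replicates = reps, power = power, by_hlo = by_hlo,
         statistic = statistic, cutoff = cutoff, level = level),
    class = "power_study"
  )
}

#' @export
print.power_study <- function(x, ...) {
  cat(sprintf("power over %d replicates (%s cutoff %.6f, level %.0e):\n",
              nrow(x$replicates), x$statistic, x$cutoff, x$level))
  print(round(x$power, 3))
  cat("most frequent HLO patterns:\n")
  print(utils::head(x$by_hlo, 8), digits = 3)
  invisible(x)
}
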