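# Exhaustive pairwise scan with LD filtering, plus file I/O.

#' Pairwise linkage disequilibrium as squared genotype correlation
#'
#' Composite LD: the squared Pearson correlation of the additive-coded
#' genotype vectors, computed on individuals non-missing at both loci.
#'
#' @param g1,g2 Genotype vectors coded 0/1/2 (NA allowed).
#' @return r-squared in `[0, 1]`, or `NA` if either column is constant or
#'   fewer than 2 complete individuals remain.
#' @export
ld_r2 <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(g1) < 2) return(NA_real_)
  if (stats::sd(g1) == 0 || stats::sd(g2) == 0) return(NA_real_)
  stats::cor(g1, g2)^2
}

#' Scan configuration
#'
#' @param criterion Gamma criterion deciding significance: `"liberal"`
#'   (shape 2) or `"conservative"` (shape 4).
#' @param alpha_global Global significance level, Bonferroni-corrected by
#'   the number of tested pairs, unless `per_test_level` overrides it.
#' @param per_test_level Optional direct per-test level.
#' @param ld_r2_max Pairs with higher LD are excluded (default 0.01); `Inf`
#'   disables the filter.
#' @param comparators Also compute comparator tests per pair (logical).
#' @return A `scan_config` list.
#' @export
scan_config <- function(criterion = "liberal", alpha_global = 0.05,
                        per_test_level = NULL, ld_r2_max = 0.01,
                        comparators = FALSE) {
  structure(
    list(criterion = match.arg(criterion, c("liberal", "conservative")),
         alpha_global = alpha_global, per_test_level = per_test_level,
         ld_r2_max = ld_r2_max, comparators = comparators),
    class = "scan_config"
  )
}

#' Exhaustive pairwise interaction scan
#'
#' Enumerates all unordered SNP pairs (i < j), applies the LD filter,
#' computes the modified information-gain statistic ([igmod()], plus the
#' no-LD form [igmod0()] for reference) with p-values under both gamma
#' shapes, flags pairs exceeding the configured cutoff,
#' and attaches the HLO classification and submodel label for flagged
#' pairs. Output rows are ordered by (i, j).
#'
#' @param genotypes Integer matrix (individuals x SNPs), 0/1/2 with `NA`
#'   for missing; or a list as returned by [read_ped_map()] /
#'   [read_genotype_csv()] (its `pheno` is then used).
#' @param pheno Binary phenotype vector; ignored when `genotypes` carries
#'   one.
#' @param config A [scan_config()].
#' @param snp_ids Optional SNP identifiers.
#' @return A `scan_result`: list with `pairs` (data frame of tested pairs),
#'   `filtered` (pairs removed and why), `cutoff`, `per_test_level`,
#'   `config`.
#' @export
pairwise_scan <- function(genotypes, pheno = NULL, config = scan_config(),
                          snp_ids = NULL) {
  if (is.list(genotypes) && !is.null(genotypes$genotypes)) {
    if (is.null(pheno)) pheno <- genotypes$pheno
    if (is.null(snp_ids)) snp_ids <- genotypes$snp_ids
    genotypes <- genotypes$genotypes
  }
  m <- ncol(genotypes)
  if (m < 2) stop("need at least 2 SNPs to scan")
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%03d", seq_len(m))

  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n_tests <- nrow(idx)
  per_test <- if (!is.null(config$per_test_level)) config$per_test_level
              else config$alpha_global / n_tests

  rows <- vector("list", n_tests)
  filtered <- list()
  for (q in seq_len(n_tests)) {
    i <- idx[q, 1]; j <- idx[q, 2]
    r2 <- ld_r2(genotypes[, i], genotypes[, j])
    if (is.na(r2)) {
      filtered[[length(filtered) + 1L]] <-
        data.frame(snp1 = snp_ids[i], snp2 = snp_ids[j],
                   r2 = NA_real_, reason = "constant column")
      next
    }
    if (r2 > config$ld_r2_max) {
      filtered[[length(filtered) + 1L]] <-
        data.frame(snp1 = snp_ids[i], snp2 = snp_ids[j],
                   r2 = r2, reason = "ld")
      next
    }
    cnt <- count_pair(genotypes[, i], genotypes[, j], pheno)
    n_pair <- attr(cnt, "N")
    stat <- igmod(cnt)
    p2 <- pvalue_gamma(stat, gamma_null(n_pair, "liberal"))
    p4 <- pvalue_gamma(stat, gamma_null(n_pair, "conservative"))
    p_used <- if (config$criterion == "liberal") p2 else p4
    sig <- p_used < per_test
    hlo <- sub <- NA_character_
    if (sig) {
      h <- classify_hlo(cnt)
      hlo <- hlo_string(h)
      sub <- match_submodel(h)
    }
    row <- data.frame(
      snp1 = snp_ids[i], snp2 = snp_ids[j], n = n_pair, r2 = r2,
      igmod = stat, igmod0 = igmod0(cnt),
      p_liberal = p2, p_conservative = p4,
      significant = sig, hlo = hlo, submodel = sub,
      stringsAsFactors = FALSE
    )
    if (isTRUE(config$comparators)) {
      row$p_logreg <- logreg_interaction(genotypes[, i], genotypes[, j],
                                         pheno)$p
      row$p_lrt <- lrt_interaction(genotypes[, i], genotypes[, j],
                                   pheno)$p
    }
    rows[[q]] <- row
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs)) {
    warning("no SNP pairs survive the LD filter")
    pairs <- data.frame(
      snp1 = character(), snp2 = character(), n = integer(),
      r2 = numeric(), igmod = numeric(), igmod0 = numeric(),
      p_liberal = numeric(), p_conservative = numeric(),
      significant = logical(), hlo = character(),
      submodel = character(), stringsAsFactors = FALSE
    )
  }
  structure(
    list(pairs = pairs,
         filtered = if (length(filtered)) do.call(rbind, filtered)
                    else data.frame(),
         per_test_level = per_test,
         cutoff = cutoff_gamma(
           gamma_null(length(pheno), config$criterion), level = per_test),
         config = config),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("pairwise scan: %d pairs tested, %d filtered, %d significant (per-test level %.3g)\n",
              nrow(x$pairs), nrow(x$filtered),
              sum(x$pairs$significant %in% TRUE), x$per_test_level))
  sig <- x$pairs[x$pairs$significant %in% TRUE, , drop = FALSE]
  if (nrow(sig)) print(utils::head(sig, 10), digits = 4)
  invisible(x)
}

#' Read PLINK text PED/MAP files
#'
#' Recodes alleles additively per SNP: 0/1/2 copies of the minor allele
#' (minor determined from the sample allele frequency; ties broken
#' lexicographically by allele character). Genotypes with a `0` allele are
#' missing. Phenotype column must be 1 (unaffected) / 2 (affected);
#' individuals with phenotype 0 or -9 are dropped.
#'
#' @param ped,map Paths to the PED and MAP files.
#' @return List: `genotypes` (matrix, NA = missing), `pheno` (0/1),
#'   `snp_ids`, `positions`, `individual_ids`.
#' @export
read_ped_map <- function(ped, map) {
  map_df <- utils::read.table(map, header = FALSE,
                              stringsAsFactors = FALSE)
  if (ncol(map_df) < 4) stop("MAP file must have >= 4 columns")
  snp_ids <- as.character(map_df[[2]])
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids in MAP file")
  m <- length(snp_ids)

  lines <- readLines(ped)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6 + 2 * m
  bad <- which(lengths(fields) != want)
  if (length(bad)) {
    stop(sprintf("malformed PED line %d: expected %d fields, found %d",
                 bad[1], want, lengths(fields)[bad[1]]))
  }
  ped_mat <- do.call(rbind, fields)
  pheno_raw <- ped_mat[, 6]
  keep <- pheno_raw %in% c("1", "2")
  if (!any(keep)) stop("no individuals with non-missing phenotype")
  if (any(!keep)) {
    message(sum(!keep), " individual(s) dropped for missing phenotype")
  }
  ped_mat <- ped_mat[keep, , drop = FALSE]
  pheno <- as.integer(ped_mat[, 6] == "2")

  a1 <- ped_mat[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- ped_mat[, 6 + 2 * seq_len(m), drop = FALSE]
  g <- matrix(NA_integer_, nrow(ped_mat), m)
  for (s in seq_len(m)) {
    al <- c(a1[, s], a2[, s])
    obs <- al[al != "0"]
    if (!length(obs)) next
    tab <- sort(table(obs))
    minor <- names(tab)[1]  # sorted ascending by count, ties lexicographic
    if (length(tab) > 1 && tab[1] == tab[2]) {
      minor <- min(names(tab)[tab == tab[1]])
    }
    miss <- a1[, s] == "0" | a2[, s] == "0"
    g[, s] <- (a1[, s] == minor) + (a2[, s] == minor)
    g[miss, s] <- NA_integer_
  }
  list(genotypes = g, pheno = pheno, snp_ids = snp_ids,
       positions = as.numeric(map_df[[4]]),
       individual_ids = ped_mat[, 2])
}

#' Read an additive-coded genotype CSV
#'
#' Expects a header of SNP ids plus a `phenotype` column; genotype cells
#' must be 0/1/2 or NA, phenotype 0/1.
#'
#' @param path CSV path.
#' @param pheno_col Name of the phenotype column (default "phenotype").
#' @return List: `genotypes`, `pheno`, `snp_ids`.
#' @export
read_genotype_csv <- function(path, pheno_col = "phenotype") {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!pheno_col %in% names(d)) {
    stop("phenotype column '", pheno_col, "' not found")
  }
  pheno <- d[[pheno_col]]
  if (!all(pheno[!is.na(pheno)] %in% c(0, 1))) {
    stop("phenotype must be 0/1")
  }
  g <- as.matrix(d[, setdiff(names(d), pheno_col), drop = FALSE])
  bad <- !(g %in% c(0, 1, 2) | is.na(g))
  if (any(bad)) stop("genotype cells must be 0, 1, 2 or NA")
  storage.mode(g) <- "integer"
  keep <- !is.na(pheno)
  list(genotypes = g[keep, , drop = FALSE], pheno = as.integer(pheno[keep]),
       snp_ids = colnames(g))
}

#' Write scan results as TSV
#'
#' One row per tested pair, stable column order, p-values in scientific
#' notation with 6 significant digits; round-trippable with
#' [utils::read.delim()].
#'
#' @param result A `scan_result` from [pairwise_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_results <- function(result, path) {
  stopifnot(inherits(result, "scan_result"))
  d <- result$pairs
  for (col in intersect(c("p_liberal", "p_conservative", "p_logreg",
                          "p_lrt"), names(d))) {
    d[[col]] <- format(d[[col]], digits = 6, scientific = TRUE,
                       trim = TRUE)
  }
  for (col in intersect(c("igmod", "igmod0"), names(d))) {
    d[[col]] <- format(d[[col]], digits = 6, trim = TRUE)
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
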