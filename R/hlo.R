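# MB-MDR-style classification of the 9 two-locus genotype cells into
# High risk / Low risk / O (no evidence or insufficient information).

#' Construct an HLO matrix
#'
#' @param labels 3 x 3 character matrix over `{"H", "L", "O"}`, or a
#'   row-wise string such as `"HLL/LHH/LHH"`.
#' @return An `hlo_matrix` object.
#' @export
hlo_matrix <- function(labels) {
  if (is.character(labels) && length(labels) == 1) {
    rows <- strsplit(labels, "/", fixed = TRUE)[[1]]
    if (length(rows) != 3 || any(nchar(rows) != 3)) {
      stop("HLO string must have form 'XXX/XXX/XXX'")
    }
    labels <- do.call(rbind, strsplit(rows, ""))
  }
  labels <- as.matrix(labels)
  if (!all(dim(labels) == c(3, 3)) || !all(labels %in% c("H", "L", "O"))) {
    stop("HLO matrix must be 3 x 3 over {H, L, O}")
  }
  dimnames(labels) <- list(c("aa", "aA", "AA"), c("bb", "bB", "BB"))
  structure(labels, class = c("hlo_matrix", "matrix"))
}

#' Serialize an HLO matrix to its row-wise string form
#'
#' @param hlo An `hlo_matrix`.
#' @return String like `"HLL/LHH/LHH"`.
#' @export
hlo_string <- function(hlo) {
  paste(apply(unclass(hlo), 1, paste, collapse = ""), collapse = "/")
}

#' @export
print.hlo_matrix <- function(x, ...) {
  cat("HLO matrix:", hlo_string(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' Classify genotype-combination cells as High/Low/O risk
#'
#' For each of the 9 two-locus genotype cells, tests whether the cell's
#' case proportion deviates from a reference, labelling the cell `H`
#' (significantly higher risk), `L` (significantly lower), or `O`
#' (no evidence, or fewer than `min_cell_n` individuals).
#'
#' With `adjust = "codominant"` (default) the reference is the cell's
#' expected case proportion under a logistic main-effects model with
#' codominant (factor) coding of both loci, and the test statistic is the
#' leverage-corrected standardized Pearson residual of the cell,
#' `z = (observed - expected cases) / sqrt(n p (1-p) (1-h))`; cells then
#' flag *interaction-driven* departures, so a model whose risk surface is
#' fully explained by main effects yields all `O`. With `adjust = "none"` the
#' reference is the case proportion among all other individuals
#' (two-proportion z test, equivalent to the 2 x 2 chi-square), so marginal
#' effects also show up as H/L.
#'
#' @param counts A `pair_counts` tensor (see [count_pair()]).
#' @param cell_alpha Two-sided significance level of the per-cell test
#'   (default 0.1).
#' @param min_cell_n Cells with fewer individuals are labelled `O`
#'   regardless of the test (default 10).
#' @param adjust `"codominant"` or `"none"`.
#' @return An `hlo_matrix`.
#' @export
classify_hlo <- function(counts, cell_alpha = 0.1, min_cell_n = 10,
                         adjust = c("codominant", "none")) {
  adjust <- match.arg(adjust)
  if (!inherits(counts, "pair_counts")) counts <- pair_counts(counts)
  x <- unclass(counts)
  cases <- x[, , 2]
  tot <- x[, , 1] + x[, , 2]
  zcrit <- stats::qnorm(1 - cell_alpha / 2)
  z <- matrix(0, 3, 3)

  if (adjust == "codominant") {
    d <- data.frame(
      cases = c(cases), tot = c(tot),
      i = factor(rep(0:2, 3)), j = factor(rep(0:2, each = 3))
    )
    d <- d[d$tot > 0, , drop = FALSE]
    fit <- suppressWarnings(
      stats::glm(cbind(cases, tot - cases) ~ i + j,
                 family = stats::binomial(), data = d)
    )
    at <- cbind(as.integer(as.character(d$i)) + 1L,
                as.integer(as.character(d$j)) + 1L)
    p_hat <- h <- matrix(NA_real_, 3, 3)
    p_hat[at] <- stats::fitted(fit)
    h[at] <- stats::hatvalues(fit)
    v <- tot * p_hat * (1 - p_hat) * (1 - pmin(h, 1 - 1e-8))
    ok <- !is.na(p_hat) & v > 0
    z[ok] <- (cases[ok] - tot[ok] * p_hat[ok]) / sqrt(v[ok])
  } else {
    n1 <- sum(cases); n <- sum(tot)
    for (i in 1:3) for (j in 1:3) {
      nc <- tot[i, j]
      if (nc == 0 || nc == n) next
      p_cell <- cases[i, j] / nc
      p_rest <- (n1 - cases[i, j]) / (n - nc)
      p_pool <- n1 / n
      se <- sqrt(p_pool * (1 - p_pool) * (1 / nc + 1 / (n - nc)))
      if (se > 0) z[i, j] <- (p_cell - p_rest) / se
    }
  }

  lab <- matrix("O", 3, 3)
  lab[z > zcrit] <- "H"
  lab[z < -zcrit] <- "L"
  lab[tot < min_cell_n] <- "O"
  hlo_matrix(lab)
}

#' Submodel catalogue of detected interaction patterns
#'
#' Named wildcard patterns for binning observed HLO matrices into submodel
#' categories. Each cell of a pattern lists its admissible labels:
#' `"H"`, `"L"`, `"O"`, `"HO"` (H or O), or `"LO"` (L or O). Matching is
#' first-match in the catalogue's order (Multi, Epi, XOR, Multi incompl,
#' Other); anything unmatched falls through to `"Other"`.
#'
#' @return Named list of 3 x 3 character pattern matrices.
#' @export
submodel_catalog <- function() {
  pat <- function(...) matrix(c(...), 3, 3, byrow = TRUE,
                              dimnames = list(c("aa", "aA", "AA"),
                                              c("bb", "bB", "BB")))
  list(
    "Multi" = pat("H", "L", "LO",
                  "L", "H", "H",
                  "L", "HO", "HO"),
    "Epi" = pat("L", "H", "HO",
                "HO", "LO", "O",
                "HO", "LO", "LO"),
    "XOR" = pat("O", "O", "L",
                "O", "O", "H",
                "L", "H", "O"),
    "Multi incompl" = pat("H", "LO", "LO",
                          "LO", "O", "HO",
                          "LO", "HO", "HO"),
    "Other" = pat("LO", "O", "HO",
                  "O", "O", "HO",
                  "H", "H", "L")
  )
}

#' Match an HLO matrix to a submodel category
#'
#' @param hlo An `hlo_matrix` (or its string form).
#' @param catalog A catalogue from [submodel_catalog()].
#' @return The first matching category name, or `"Other"`.
#' @examples
#' match_submodel(hlo_matrix("HLL/LHH/LHH")) # "Multi"
#' @export
match_submodel <- function(hlo, catalog = submodel_catalog()) {
  hlo <- if (inherits(hlo, "hlo_matrix")) unclass(hlo) else
    unclass(hlo_matrix(hlo))
  for (name in names(catalog)) {
    pattern <- catalog[[name]]
    ok <- vapply(seq_along(pattern), function(c_) {
      grepl(hlo[[c_]], pattern[[c_]], fixed = TRUE)
    }, TRUE)
    if (all(ok)) return(name)
  }
  "Other"
}
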