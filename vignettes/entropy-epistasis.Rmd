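---
title: "Entropy-based detection of gene-gene interactions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based detection of gene-gene interactions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igmod)
```

## The problem

In a case-control study with diallelic markers (SNPs coded 0/1/2 copies of
the minor allele), epistasis means that the penetrance surface over the
nine two-locus genotype combinations is not explained by the two marginal
effects. Regression tests for interaction commit to a scale and a coding;
entropy-based statistics are model-free and react to *any* departure from
independence, which makes them attractive for unconventional risk patterns
(XOR-like surfaces, interactions without marginal effects) that additive
regression handles poorly.

The catch is that the plain second-order information gain

$$IG(D \mid G) \;=\; H(D) - H(D \mid G_1, G_2)$$

reacts to main effects too: a single associated locus drives it away from
zero, so used as an interaction test it has an inflated type-I error.
`igmod` implements the modification that removes both first-order terms,

$$IGmod(D \mid G) \;=\; IG(D\mid G) - IG(D\mid G_1) - IG(D\mid G_2),$$

estimated by plug-in relative frequencies from the 3×3×2 contingency
tensor of one SNP pair against disease status (`count_pair()`,
`igmod()`).

## The statistic, its no-LD form, and two gamma criteria

An algebraic identity connects the difference form to conditional mutual
information: writing $MI(G_1; G_2)$ for the pooled genotype-genotype
mutual information of the pair,

$$IGmod \;=\; CMI(G_1; G_2 \mid D) \;-\; MI(G_1;G_2).$$

Under linkage equilibrium the second term vanishes in expectation and one
obtains the simplified estimator

$$IGmod_0 \;=\; \sum_k \sum_{i,j} \hat P_{ijk}
\log_2 \frac{\hat P^k_{ij}}{\hat P^k_{i\cdot}\,\hat P^k_{\cdot j}}
\;=\; \widehat{CMI},$$

the case- and control-stratum mutual informations weighted by stratum
frequency (`igmod0()`; in natural-log units this is the GenoCMI statistic,
`geno_cmi()`). Both are exposed; they differ in a way that matters:

* $2N\ln 2 \cdot IGmod_0$ is asymptotically $\chi^2$ with
  $2(3-1)(3-1) = 8$ degrees of freedom under conditional independence,
  i.e. a **gamma with shape 4** and scale $1/(N\ln 2)$ on the bits scale.
  This is the *conservative* criterion (`gamma_null(n, "conservative")`).
* the difference form additionally subtracts the *sample* pooled
  association, which removes the 4-df "pooled" subspace of those
  fluctuations; its null law is $\chi^2(4)$-type, i.e. a **gamma with
  shape 2** — the *liberal* criterion (`gamma_null(n, "liberal")`,
  the default). The package's scan and study drivers therefore pair
  `igmod()` with the shape-2 null; the test-suite verifies on simulated
  null genome scans that this combination holds its nominal levels over
  four orders of magnitude, while `igmod0()` p-values are calibrated
  against the shape-4 null.

The subtraction matters beyond calibration. In a case-control *sample*
drawn from an interaction model, the two loci are marginally associated
even at linkage equilibrium in the population (selection on disease status
induces dependence), and when main effects are strong this pooled
association is substantial. `igmod()` discounts it; `igmod0()` does not,
and accordingly detects main-effect-rich surfaces more often. On
LD-filtered pairs (the intended use; see the scan section) the two nearly
coincide.

Decision thresholds come from inverting the gamma survival function at a
Bonferroni-corrected per-test level (`cutoff_gamma()`). Two reference
settings recur throughout the package: shape 2, $N = 1600$, per-test level
$10^{-5}$ (cutoff ≈ 0.012836 bits, the simulated-study setting) and shape
4, $N = 2062$, level $5\times10^{-8}$ (cutoff ≈ 0.017331 bits, the
real-data-style setting). We use `stats::qgamma`/`pgamma`; the round-trip
is exact to $10^{-10}$ relative.

Numerical conventions: $0\log 0 := 0$ everywhere; terms with zero
numerator contribute nothing (the plug-in estimator restricted to observed
support); no pseudocounts or shrinkage, because the gamma calibration is
for the raw plug-in statistic. A negative `igmod()` value (possible when
the sample LD term exceeds the conditional dependence) carries no evidence
and maps to $p = 1$.

## The five interaction models and the constraint solver

The simulator covers five two-locus disease models written as 3×3 tables
of odds, rows/columns indexed aa/aA/AA and bb/bB/BB (capital = minor
allele). Four are parameterized by a baseline odds $\alpha$ and a
multiplicative interaction factor $(1+\theta)$ placed on different cells
(`odds_table()`): *multiplicative* (exponent $i \times j$), *epistasis*,
*two-allele*, and *XOR*. The fifth, *no-margin*, is a fixed table
(`no_margin_spec()`) whose marginal odds are all equal at MAF 0.25 — pure
interaction with no main effects. Because its source is ambiguous about
whether the printed values are odds or penetrances, both readings are
available (`as_penetrance`); the default follows the table's own header
(odds). Odds convert to penetrances cell-wise by $f = o/(1+o)$.

Given a model, a shared MAF for both loci, a target prevalence

$$K = \sum_{ij} P(G_{ij})\, f_{ij}, \qquad
P(G_{ij}) = \mathrm{HWE}(q)_i \,\mathrm{HWE}(q)_j,$$

and a target broad-sense heritability

$$h^2 = \sum_{ij} P(G_{ij}) \frac{(f_{ij} - K)^2}{K(1-K)},$$

`solve_model_params()` finds $(\alpha, \theta)$ by nested root-finding:
the inner solve matches the prevalence in $\alpha$ (strictly increasing),
the outer matches the heritability in $\theta$ (increasing after
re-solving $\alpha$), with `uniroot` at tolerance $10^{-13}$ and a
doubling upper bracket for $\theta$. Both constraints are re-verified to
$10^{-8}$ on exit and the solver errors rather than returning an
unverified table. The twelve study designs (four parameterized models ×
MAF 0.1/0.2/0.4, prevalence 0.1, $h^2$ 0.03 for multiplicative and 0.02
otherwise) all solve; $h^2 = 0$ short-circuits to the analytic
$\theta = 0$, $\alpha = K/(1-K)$.

## Data generation

Sampling is retrospective, as in penetrance-table generators such as
GAMETES: cases are drawn from the nine-cell distribution
$P(G_{ij} \mid D_1) \propto P(G_{ij}) f_{ij}$ and controls from
$P(G_{ij} \mid D_0) \propto P(G_{ij})(1 - f_{ij})$
(`sample_interacting_pair()`), which yields exact case/control counts —
the study default is 800 + 800. Non-interacting SNPs get an independent
MAF drawn uniformly from (0.05, 0.5), redrawn per dataset, with genotypes
i.i.d. Hardy-Weinberg and independent of status
(`sample_null_snps()`); a default dataset has 100 SNPs with the
interacting pair in columns 1-2 (`simulate_dataset()`).

Reproducibility: one root seed; replicate $r$ uses the derived seed
$(69069\,s + r) \bmod (2^{31}-1)$ (`replicate_seed()`), so any subset of
replicates can be regenerated independently and studies could be
parallelized by replicate without changing results.

What the generator does *not* emulate: LD between markers (all SNPs are
independent, matching the method's assumption after LD filtering),
genotyping error and missingness, covariates or population structure, and
quantitative phenotypes. Passing tests therefore demonstrate correctness
of the statistic and its calibration under the stated design, not
robustness to those real-data complications.

## Study drivers and their problem sizes

`run_type1_study()` scores every non-interacting pair of each replicate —
4949 of the 4950 pairs at defaults, deliberately *including* the pairs
that couple one main-effect (interacting) SNP with a null SNP, so that
robustness of the statistic to marginal effects is exercised. The
acceptance runs use 12 designs × 100 replicates (≈ 5.9 million null
pairs), a size chosen to estimate tail frequencies at $5\times10^{-2}$
and $5\times10^{-3}$ with Monte-Carlo standard errors well below the
quantities themselves; deeper tails ($5\times10^{-5}$ and below) are only
bounded coarsely at this size.

`run_power_study()` generates only the interacting pair per replicate
(null SNPs are irrelevant to pair-level power), records detection by the
entropy statistic at a fixed cutoff, by the 1-df additive logistic Wald
test, optionally the 4-df LRT and the case/control mutual-information
difference $T_{IG}$, and attaches the HLO classification of each
replicate; 1000 replicates is the study default.

## Comparator tests

* `logreg_interaction()`: logit $P(D{=}1) = \beta_0 + \beta_1 g_1 +
  \beta_2 g_2 + \beta_3 g_1 g_2$ with additive coding; Wald test on
  $\beta_3$ (the PLINK epistasis-module convention; a 1-df LRT would
  differ slightly, which is why the choice is documented). Non-converged
  or separated fits are flagged and count as non-detections.
* `lrt_interaction()`: null model with additive + dominance
  (heterozygote-indicator) terms per locus, full model adding the four
  products; likelihood-ratio statistic on 4 df, with reduced df reported
  when empty cells make products collinear.
* `tig_test()`: $T_{IG} = MI(G_1;G_2 \mid \text{cases}) -
  MI(G_1;G_2 \mid \text{controls})$, a signed statistic whose null is
  taken by label permutation with stratum sizes fixed,
  $p = (1 + \#\{|T^*| \ge |T|\})/(1 + B)$ — the method's source does not
  specify a usable asymptotic null, so permutation is the package's
  choice.

## HLO classification and the submodel catalogue

One step of the MB-MDR algorithm summarizes a pair's risk surface: each
of the nine cells is labelled **H** (significantly elevated case
proportion), **L** (significantly depressed), or **O** (no evidence, or
fewer than `min_cell_n = 10` individuals), at a two-sided per-cell level
`cell_alpha = 0.1` (`classify_hlo()`).

The reference the cell is compared against is the one genuinely open
design choice, and the package ships two conventions:

* `adjust = "codominant"` (default): the cell's expected case count under
  a codominant (factor-coded) logistic main-effects fit, tested with the
  leverage-corrected standardized Pearson residual
  $z = (O - E)/\sqrt{n\hat p(1-\hat p)(1 - h)}$. Cells then flag
  departures *net of main effects*: a surface fully explained by margins
  is all-O. This is the convention under which the multiplicative model's
  ideal pattern (HLL/LHH/LHH — note the **H** in the common aa/bb corner,
  which is above its main-effects expectation while below the sample
  average) is recovered, and it is the convention the power studies
  report.
* `adjust = "none"`: the classical two-proportion z test of the cell
  against all remaining individuals. Margins then show up in the labels;
  this matches the tabulated ideal patterns of the low-main-effect models
  (epistasis, two-allele, XOR, no-margin).

No single convention reproduces every tabulated ideal pattern — the
multiplicative ideal is only obtainable net of main effects, the
two-allele ideal only raw — so the large-sample convergence test checks
each model under its generating convention. One further corner case: the
no-margin model's zero-penetrance cell (AA/BB, odds 0.00) is tabulated O,
but a cell that cannot contain cases is, at large n, indistinguishable
from minimal risk; the package labels it L once it is big enough to test,
and the tests accept either label there.

`match_submodel()` bins an observed HLO matrix into the categories
Multi, Epi, XOR, Multi incompl, Other, using wildcard patterns ("H or
O", "L or O") matched in that fixed order; anything unmatched is Other.

## The pairwise scan

`pairwise_scan()` enumerates unordered pairs in deterministic (i, j)
order, removes pairs with squared genotype correlation
$r^2 > 0.01$ by default (`ld_r2()`, computed on pooled cases+controls;
configurable or disabled), computes `igmod()` and `igmod0()` with
p-values under both gamma shapes, flags pairs by the configured criterion
(liberal by default; exactly one of a per-test level or a global alpha
with Bonferroni-by-pair-count determines the cutoff), and attaches
HLO/submodel labels to flagged pairs. Input comes from PLINK text
PED/MAP (`read_ped_map()`: per-SNP minor allele from sample frequency,
lexicographic tie-break, `0` alleles missing, pairwise-complete deletion
per pair) or an additive-coded CSV (`read_genotype_csv()`); output is a
round-trippable TSV (`write_scan_results()`). Missing genotypes are never
imputed — pairwise deletion is the package's documented choice, and the
per-pair sample size N (hence the gamma scale) adjusts accordingly.

## Known limitations

* The entropy statistics are second-order only; higher-order interactions
  are out of scope.
* The gamma null is asymptotic and approximate; with very rare genotype
  classes the effective degrees of freedom drop and both criteria become
  conservative at the same nominal shape.
* Conditional (per-HLO-pattern) power is sensitive to the cell-test
  convention, its alpha, and `min_cell_n`; the shipped defaults were
  fixed from the classification behaviour of the adjusted test at the
  study's sample size, and tabulated conditional powers from other
  implementations of the same design may differ beyond Monte-Carlo error.
* Real genotype data (e.g. consortium GWAS data) are not distributable
  with the package; all packaged data are synthetic, and the real-data
  setting appears only through its sample size and threshold
  conventions.
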