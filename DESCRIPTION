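Package: igmod
Title: Entropy-Based Detection of Gene-Gene Interactions in Case-Control Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects pairwise gene-gene interactions (epistasis) in
    case-control SNP data with a modified entropy-based estimator: the
    second-order information gain minus both first-order (main-effect)
    information gains, which under linkage equilibrium equals the
    conditional mutual information of the two genotypes given disease
    status. Provides gamma-distribution null calibration with liberal
    (shape 2) and conservative (shape 4) criteria, a two-locus penetrance
    model simulator covering five interaction models with exact prevalence
    and heritability constraints, comparator tests (1-df additive logistic
    interaction, 4-df likelihood-ratio test, case/control mutual-information
    difference with permutation p-values), an MB-MDR-style High/Low/O risk
    cell classifier with a submodel catalogue, and an exhaustive pairwise
    scan with LD filtering over PLINK PED/MAP or genotype CSV input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
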