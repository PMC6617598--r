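Package: gwasrank
Title: Multi-Approach Univariate GWAS Association and Ranked-List Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Runs a diverse suite of per-SNP association approaches
    (logistic regression under additive, dominant, recessive and codominant
    encodings; contingency-table tests; permutation-based model selection;
    MDR balanced accuracy; entropy gain; per-SNP decision trees) on
    case-control genotype data in PLINK PED/MAP format, compares the
    resulting ranked SNP lists with Canberra-based top-k distances, derives
    consensus clusterings of the approaches, selects cluster
    representatives, and reports haplotype-block-pruned top-k union tables
    with extraction numbers and average positions. Includes quality-control
    filters (missingness, MAF, Hardy-Weinberg exact test, differential
    call rate), LD pruning, PCA covariates, and a seeded synthetic
    case-control generator with planted genetic effects for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
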