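Package: mrlite
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and validating per-SNP association tables, effect-allele
    harmonization with palindromic-SNP policies, instrument filtering and
    distance-based pruning, instrument-strength (F statistic) diagnostics,
    causal-effect estimation by inverse-variance weighting (fixed and
    multiplicative random effects), MR-Egger regression and the weighted median
    with parametric-bootstrap standard errors, and a sensitivity suite (Cochran
    Q, MR-Egger intercept, MR-PRESSO global and outlier tests, leave-one-out,
    funnel-plot coordinates). Includes a generator for synthetic two-sample
    summary statistics with known causal effect and configurable pleiotropy,
    a scenario simulation grid, and a one-command pipeline that reproduces a
    complete analysis report from delimited text inputs. Ships the published
    15-SNP leukocyte-telomere-length instrument table for constipation as a
    worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
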