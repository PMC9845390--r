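Package: ebdiet
Title: Empirical Bayes Dietary Phenotypes Benchmarked by SNP Heritability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives crude and Empirical Bayes (beta-binomial and
    Dirichlet-multinomial posterior mean) dietary phenotypes from repeated
    24-hour recall questionnaires and benchmarks the two derivations against
    each other using SNP heritability as a relative-validity metric. Includes
    a synthetic-data generator for genotypes with linkage disequilibrium and
    heritable dietary traits with controllable questionnaire-to-questionnaire
    reliability, per-questionnaire quality-control filters, one-way intraclass
    correlation, covariate-adjusted per-SNP association scans, LD score
    regression and Haseman-Elston heritability estimators, effective-number-
    of-tests multiple-testing correction, greedy locus clumping, and
    crude-versus-EB comparison summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
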