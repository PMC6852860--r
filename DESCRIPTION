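Package: fattenassoc
Title: Candidate-Gene Association Analysis of Cattle Fattening Performance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for candidate-gene association studies of fattening
    performance in cattle. Derives growth and feed-efficiency phenotypes
    (days to reach target body weights, fattening periods, dry matter
    intake, feed conversion rate, average daily weight gain) from raw
    weigh and feed records by linear interpolation; characterises biallelic
    SNP markers (allele and genotype frequencies, Hardy-Weinberg chi-square
    tests, expected homozygosity and heterozygosity, effective allele
    number, polymorphism information content); fits fixed-effects linear
    models with an age covariate, season, genotype and genotype-by-genotype
    interaction terms, reporting least-square means with standard errors,
    partial F tests and Tukey-adjusted groupings; and estimates single-locus
    additive and dominance effects from genotype means. A seeded synthetic
    herd generator with planted genotype effects makes every stage of the
    pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    emmeans,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
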