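Package: gwastrans
Title: Translational Prioritisation of GWAS Signals into Candidate Causal Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested re-implementation of a translational pipeline that takes
    genome-wide association signals for moderate-to-severe asthma through
    multi-source functional-genomics evidence to scored candidate causal
    genes. Covers linkage-disequilibrium proxy selection, weighted
    evidence scoring with threshold and fallback selection rules,
    Bonferroni-corrected phenome-wide trait screening, differential
    expression testing with a Shapiro-Wilk normality gate dispatching to
    Kruskal-Wallis or Welch's heteroscedastic ANOVA under two-stage
    Benjamini-Krieger-Yekutieli false-discovery-rate control, gene-set
    fold-enrichment statistics, tissue and colocalization classification,
    and drug-interaction triage. Ships curated study tables as plain-text
    fixtures and a seeded synthetic-data generator so the whole pipeline
    runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
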