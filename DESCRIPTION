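Package: psmvar
Title: Count-Dependent Variance Moderation for Quantitative Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential protein expression analysis for quantitative
    mass-spectrometry proteomics in which the empirical-Bayes prior variance
    of each protein depends on the number of peptide-spectrum matches (PSMs)
    or peptides used for its quantification.  Provides PSM-to-protein
    summarization by median sweeping and by reference-channel ratios,
    per-protein linear models with ordinary t and ANOVA F tests, moderated t
    and F tests with a count-dependent variance prior fitted by local
    regression, Benjamini-Hochberg correction, diagnostics for the
    variance-count relationship (including residual-sum-of-squares
    comparison of count metrics across TMT batches and partial-AUC
    benchmarking), and synthetic-data generators for null and spike-in
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
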