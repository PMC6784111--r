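Package: abframe
Title: Germline-Guided Antibody Framework Optimization and Developability Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for germline-guided optimization of antibody variable-domain
    frameworks and the downstream developability analytics used to evaluate the
    resulting variant panels. Provides Kabat numbering and framework/CDR
    delineation for VL and VH amino-acid sequences, closest-germline assignment
    with per-position framework mismatch reports and positional residue
    frequencies, combinatorial enumeration of germlining variants with
    signature-based names, global 1:1 Langmuir fitting of surface plasmon
    resonance sensorgrams, melting-point extraction from differential scanning
    fluorimetry curves, size-exclusion chromatogram species quantification and
    stability time-course summaries, mono/bi-exponential pharmacokinetic fitting
    with extra-sum-of-squares model selection and non-compartmental analysis
    (AUC, CL, MRT, V_D,ss), cross-variant statistics (ANOVA/Tukey, exact
    Spearman rank correlation, fold-change screens), seeded synthetic-data
    generators for every assay, and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    pracma,
    signal,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
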