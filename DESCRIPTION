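Package: mosaicqtl
Title: Haplotype Reconstruction and QTL Mapping for Multiparent Outbred Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for genetic mapping in multiparent outbred populations such
    as Diversity Outbred (DO) mice. Provides a 36-state hidden Markov model for
    probabilistic reconstruction of founder diplotypes from genotyping-array
    calls or two-channel intensities (EM-fitted emission models), founder
    allelic dosages and genome-wide SNP imputation, kinship matrices from
    expected allele sharing with leave-one-chromosome-out variants,
    kinship-corrected genome scans under full, additive-haplotype and
    additive-SNP regression models, permutation and Bonferroni genome-wide
    significance thresholds, Bayesian credible support intervals, and power and
    type-I-error simulation studies. A bundled breeding simulator generates
    synthetic DO genomes, array observations and phenotypes so the whole
    pipeline runs without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
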