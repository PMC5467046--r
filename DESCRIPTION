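Package: mhcbinder
Title: Position-Specific Scoring Matrix Prediction of Peptide-HLA Class I
    Binding with Pan-Allele Extension
Version: 0.1.0
Authors@R:
    person("mhcbinder", "developers", email = "mhcbinder@example.org",
           role = c("aut", "cre"))
Description: Trains position-specific scoring matrices (PSSMs) from sets of
    experimentally verified HLA class I binder peptides, scores peptides by
    length-normalized log-odds against amino-acid background frequencies,
    converts binding scores to IC50 (nM) with the 500/50 nM binder and
    strong-binder cutoffs, and extends predictions to HLA alleles without
    training data by a similarity-weighted mean over sequence-similar
    characterized alleles (BLOSUM62 local alignment weights). Includes the
    training-data cleaning and grouping rules, ten-fold cross-validation
    with generated nonbinders and AUC/ACC metrics, mutant peptide window
    enumeration from protein-level somatic mutations with neoantigen filter
    rules, a seeded synthetic-data generator with planted binding motifs,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
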