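Package: combipep
Title: Combinatorial Saturation Mutagenesis Analysis for Chemokine-Binding Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for optimising chemokine-binding peptides
    by phage-display saturation mutagenesis. Parses paired-end amplicon reads
    with scaffold and insert-size filters into variant count tables, computes
    log2 enrichment (log2E) and parental deltas with two imputation dialects
    and control-binder exclusion, selects improving point mutations by mean
    and peak delta-log2E, enumerates combinatorial peptide libraries and
    reverse-translates them into clonable oligonucleotides, fits 3-parameter
    log-logistic dose-response curves with desensitisation exclusion and
    potency (pEC50/pEC80/pIC50) transforms, designs expression-proportional
    chemokine pools, runs many-to-one Dunnett comparisons, classifies
    inter-chain contacts in complex models and quantifies binding-site
    occlusion. Seeded simulators generate every input class with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    bio3d,
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    mvtnorm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    multcomp,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
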