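Package: ssbdnds
Title: Substitution-Bias-Corrected dN/dS for Somatic Selection in Cancer Exomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects positive and negative selection on somatic point
    mutations with a somatic-substitution-bias (SSB) corrected dN/dS.
    Synonymous and non-synonymous sites are counted per substitution class
    (seven collapsed classes including CpG>N, or 192 trinucleotide-context
    and strand classes), reweighted by the fold change of observed versus
    expected class frequencies, and tested per gene against neutrality with
    an exact binomial test under the passenger-synonymous assumption, with
    Benjamini-Hochberg FDR classification. Also provides quality and
    gene-level mutation filters for MAF-style tables, a super-epitope
    permutation test for immunopeptidome regions, and a neutral/selection
    simulator with precision-recall benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
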