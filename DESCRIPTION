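Package: sigscar
Title: Mutational Signature Refitting and Homologous-Recombination-Deficiency Scars
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for somatic mutational-signature analysis in cancer genomes:
    filtering of somatic variant lists, construction of 96-channel
    trinucleotide-context mutational catalogues, de novo signature extraction by
    bootstrapped non-negative matrix factorization with consensus clustering,
    constrained least-squares refitting of known signature exposures,
    classification of deletions with breakpoint microhomology (a genomic scar of
    failed homologous-recombination repair), and the exact association
    statistics used to link signature-3 status to histology and indel burden.
    Includes a synthetic-data generator that emulates cohorts drawn from known
    signature mixtures so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    cluster,
    data.table,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
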