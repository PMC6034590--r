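Package: geneharvest
Title: Extract Annotated Subsequences from GenBank Flat Files
Version: 0.1.0
Authors@R:
    person("geneharvest", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Offline extraction of gene subsequences from GenBank flat-file
    records. Parses feature tables and the INSDC location grammar (join,
    complement, order, partial coordinates, trans-spliced mixed-strand
    features), matches annotated features against user-supplied or bundled
    gene-name synonym dictionaries (animal and plant mitochondrial,
    chloroplast, and ribosomal DNA terms), resolves and optionally translates
    the matched subsequences under NCBI genetic codes, and writes per-locus
    FASTA files plus a species-by-locus accession table for supermatrix
    assembly. Includes a deterministic synthetic-record generator with a
    ground-truth manifest for end-to-end validation, term-table merging, and
    longest-sequence-per-species selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
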