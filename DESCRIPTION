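Package: CleaveScan
Title: Protease Cleavage-Motif Discovery, Refinement and Proteome Scanning
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deriving protease substrate-recognition motifs from
    panels of labeled cleavage peptides and for predicting substrates
    proteome-wide. Implements a PROSITE-dialect pattern engine (residue
    classes, exclusion classes, bounded wildcard gaps) with
    ScanProsite-compatible matching semantics, TEIRESIAS-style <L,W,K>
    pattern discovery over a chemical-equivalence alphabet, refinement of a
    motif from cleaved and uncleaved peptides (position-wise residue unions,
    negative-only exclusion classes, jackknife contribution statistics), and
    characterization of predicted substrate sets by hypergeometric
    information-content enrichment over a Gene Ontology style DAG. A
    synthetic-data module generates proteomes with planted motif instances,
    labeled peptide panels and toy ontologies with known ground truth for
    benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
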