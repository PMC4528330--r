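Package: GeneModelAudit
Title: Auditing Exceptional Gene Models in Genome Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects, classifies and flags exceptional gene models in a genome annotation: polycistronic transcripts, shared and
    multiphasic/bidirectional coding overlaps, noncanonical and
    endonuclease-processed splice sites, U12-type introns, trans-spliced
    transcripts, and the full set of translation exceptions (non-AUG starts,
    selenocysteine recoding, stop-codon readthrough, programmed +1
    frameshifting, mitochondrial code and incomplete stop codons). Derives
    correct polypeptide sequences under every declared exception, binds
    classifications to Sequence Ontology terms and standardized transcript
    flags, audits RNA-seq junction calls against annotated introns, and ships
    a deterministic synthetic-fixture generator with ground-truth manifests
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
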