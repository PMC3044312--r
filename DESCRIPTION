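Package: pdthread
Title: Protein Threading with Partial-Decoy Distance-Dependent Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-to-structure threading that scores query-template
    alignments with a profile-based local term plus a distance-dependent
    pairwise statistical potential evaluated on a "partial decoy" (the matched
    residues with coordinates copied from the template). Alignments are
    represented as non-decreasing mappings from template to query, optimized
    by an affine-gap dynamic program that also emits suboptimal candidate
    alignments, followed by a k-neighborhood local search with a
    multiplicative acceptance criterion. Includes DFIRE-style potential
    estimation from structure sets, a contact-preference baseline score,
    TM-score-style alignment quality, weight/threshold training utilities,
    and generators for synthetic toy structures and threading pairs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
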