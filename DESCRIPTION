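Package: phagenet
Title: Phage Genome Triage, Clustering, Marker Phylogenies and
    CRISPR-Spacer Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for curating phage genome collections
    and inferring their ecology. Implements multi-evidence viral triage of
    annotated contigs (protein-family signatures, strand layout, hallmark
    keywords, BUSCO/VPF false-positive filtering, lifestyle calls),
    exact dereplication and greedy centroid species-level clustering by
    average nucleotide identity, detection of alternative genetic codes by
    coding-density contrasts under reassigned stop-codon sets, an iterative
    core-marker phylogeny driver with neighbor-joining trees and patristic
    distances, genus-level clustering by amino-acid identity with Markov
    clustering and a habitat-divergence rank test, and CRISPR array
    detection with mismatch-bounded spacer matching for phage-host and
    phage-phage interaction networks. A seeded synthetic community
    generator with planted ground truth provides a self-contained test
    surface for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
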