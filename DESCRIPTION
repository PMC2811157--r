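Package: phosphocons
Title: Cross-Species Conservation Scoring and Kinase-Motif Annotation of
    Phosphorylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores the evolutionary conservation of mapped human
    phosphorylation sites across aligned vertebrate ortholog families
    using a -5/+5 residue window with interchangeable S/T phospho-acceptor
    centers, annotates sites with kinase consensus motifs and Polo-box
    domain docking motifs, filters recurrent conserved kinase-consensus
    sites, and assembles the annotated signaling network with GraphML and
    JSON export.  Includes a seeded ortholog-family simulator (star
    phylogeny with site-specific purifying constraint) so the whole
    pipeline is testable without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
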