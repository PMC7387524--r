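Package: aarsfp
Title: Interaction Fingerprints of Amino Acid Recognition in
    Aminoacyl-tRNA Synthetases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Characterizes how aminoacyl-tRNA synthetases (aaRSs) recognize
    their amino acid ligands from annotated non-covalent protein-ligand
    interactions. Maps interactions onto the amino-acid substructure of the
    ligand by subgraph isomorphism against built-in scaffold graphs, computes
    per-atom interaction occupancy profiles and class-level frequency tables,
    encodes complexes as segmented binary interaction fingerprints (binding
    site composition, hashed interaction features, editing mechanisms, and
    binding cavity volume), quantifies recognition-space structure through
    Jaccard distances, low-dimensional embedding and silhouette analysis, and
    ships a synthetic-complex generator emulating the statistical structure
    of crystallographic aaRS datasets so that every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml,
    Biostrings
Suggests:
    bio3d,
    cluster,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
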