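Package: buscosynteny
Title: BUSCO Single-Copy Ortholog Synteny and Assembly Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for ortholog-anchored macrosynteny
    between chromosome-level genome assemblies. Parses BUSCO full-table
    outputs (v2-v5 dialects), merges forward and reverse-complement runs with
    coordinate remapping, intersects single-copy ortholog placements of two
    genomes into synteny links, filters single relocations, and classifies
    chromosome fusion and fission events from the chromosome-pair bipartite
    graph. Also computes Assemblathon-style assembly contiguity statistics
    (Nx/Lx, scaffold-to-contig decomposition at N-gap runs, composition),
    writes Circos karyotype and links files, and ships a seeded simulator of
    paired genomes with planted fusion/fission/relocation events for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    igraph,
    jsonlite,
    optparse,
    rlang,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
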