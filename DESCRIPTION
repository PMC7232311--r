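Package: otuflock
Title: Species Flock Detection and Endemism Typing for OTU Metabarcoding
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-clustering analysis of amplicon (18S rDNA V4) OTU data
    from confined habitats such as ancient lakes: classification of OTUs
    into divergence bands against a reference set, detection of putative
    species flocks on bootstrap-supported phylogenies, screening of
    intragenomic rRNA-variant clouds by their dominant-plus-satellite
    abundance signature, a three-way endemism typology, and the supporting
    community statistics (rarefaction, Bray-Curtis dissimilarity, richness,
    shared-OTU partitions). Includes a synthetic-community generator with
    planted ground truth so every stage of the pipeline is testable without
    access to raw sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
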