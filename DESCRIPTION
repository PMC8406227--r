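Package: asvorigin
Title: Origin Classification and Decontamination for Low-Biomass Subsurface Microbiome Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contamination screening of low-biomass 16S rRNA gene
    amplicon surveys and partial-genome collections from subsurface
    environments. Implements a four-category amplicon sequence variant (ASV)
    origin classifier (subsurface, possibly subsurface, likely contaminant,
    contaminant) driven by global sequence identity against no-template,
    drilling-fluid and seawater control collections, a "likely indigenous"
    whitelist, and environment-of-closest-match evidence; decontaminated
    community summaries and drilling-tracer comparisons; screening-success
    accounting; KEGG Orthology (KO) based pathway-completeness and marker-gene
    profiling of metagenome-assembled and single-cell amplified genomes; and a
    fully seeded synthetic-community generator with recorded ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
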