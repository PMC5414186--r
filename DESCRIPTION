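Package: asmcurator
Title: Assembly Curation, Map Anchoring and Pooled Sex-Region Scanning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating long-read genome assemblies of the kind used
    for fish genomics projects. Detects chimeric (inter-chromosomal)
    misassemblies from the joint signature of elevated variant density and
    dips in large-insert mate-pair physical coverage, adjudicates candidates
    against radiation-hybrid and RAD genetic maps, and breaks contigs at
    annotation-safe positions. Anchors contigs into linkage-group
    pseudomolecules with a two-marker rule and fixed join gaps, emitting AGP.
    Ranks candidate assemblies by averaged likelihood-score ranks and
    standardized principal component analysis, and classifies BAC-end pairs.
    Scans pooled male/female resequencing data for FST and sex-patterned
    variants to delimit sex-determination regions. A synthetic-data module
    generates genomes with known chimeric joins, maps, mate pairs, BAC ends
    and pooled allele counts so every stage can be validated against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
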