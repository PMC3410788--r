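Package: srnaevo
Title: Small RNA Evolution Toolkit: miRNA Profiling, Homolog Mapping and
    Cross-Species Expression Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for evolutionary analysis of microRNAs from
    small RNA sequencing data. Preprocesses small-RNA libraries (3' adapter
    trimming, read collapsing), aligns reads with a mismatch-bounded
    best-stratum short-read aligner, filters against an ncRNA annotation
    database and profiles expression over known hairpin precursors with per-arm
    (5p/3p) assignment. Identifies miRNA homologs by slicing multiple-species
    whole-genome alignments (UCSC MAF) at precursor loci and stitching
    per-species homolog sequences; computes region-wise Kimura two-parameter
    evolutionary distances for precursor, mature and seed regions; folds
    hairpins with a weighted base-pair maximization dynamic program; and tests
    cross-species expression divergence of orthologous miRNAs with a Poisson
    likelihood-ratio test with Benjamini-Hochberg correction. Includes a
    deterministic synthetic-data generator (toy genomes, mutated orthologs with
    known substitution rates, MAF alignments, Poisson-sampled read libraries)
    and a reproducible multi-stage pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
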