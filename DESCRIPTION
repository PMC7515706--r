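Package: guideforge
Title: Tiered CRISPR/Cas9 Guide Library Design with Deletion-Based
    Protein Conservation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds genome-wide SpCas9 sgRNA feature databases and designs
    tiered knockout guide libraries. Enumerates all NGG guides in a genome,
    annotates intrinsic guide features (homopolymers, Esp3I restriction
    sites, nearest-neighbor melting temperature, pluggable cleavage
    efficacy), Hsu-style off-target specificity from a seeded mismatch
    search, and target features (position in the coding sequence,
    nonsense-mediated-decay competence under the 50-nt rule, exon symmetry,
    splice-site proximity, splicing-enhancer motifs, domain and
    secondary-structure overlap, common polymorphisms). Computes a
    per-residue deletion-based protein conservation score from semi-global
    alignment deltas against ortholog sets, assigns guides to design tiers
    with iterative constraint relaxation, and picks spaced guide sets per
    gene. Includes the training-analysis machinery used to weigh features
    (per-experiment/per-gene z-scoring, linear modelling with LMG relative
    importance, screen dropout metrics) and a deterministic synthetic-data
    generator so the whole pipeline is testable on toy genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
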