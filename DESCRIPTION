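Package: PapaverSSR
Title: EST-SSR Marker Development and Cultivar Genotyping for Opium Poppy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for developing and evaluating trinucleotide EST-SSR
    (microsatellite) markers in opium poppy (Papaver somniferum) and related
    species: perfect tandem-repeat mining from FASTA sequences with
    flank-based deduplication, fragment-size binning against allelic
    ladders, S4 containers for codominant diploid genotype matrices,
    per-locus diversity statistics (allele counts, observed and expected
    heterozygosity, polymorphic information content), mismatch-tolerant
    multilocus identity analysis with probability-of-identity estimators,
    between-laboratory genotyping error rates per allele and per locus,
    two-laboratory cross-species transferability summaries, Dice-distance
    hierarchical clustering with locus-bootstrap supports and
    cophenetic-correlation linkage selection, principal component analysis
    of trinary allele encodings, and a seeded synthetic-genotype generator
    emulating highly homozygous autogamous cultivar panels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
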