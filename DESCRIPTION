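Package: dfpmaa
Title: Carbohydrate-Active Domain Abundance Scoring for Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the carbohydrate-processing potential of bacterial genomes
    and fecal shotgun metagenomes by integrating profile-HMM hits against a
    CAZyme domain collection into normalized per-domain abundances
    ("domain fractions per million amino acids", calibrated at 250-nt reads).
    Provides a HMMER3 per-domain table reader, dbCAN-style hit filtering
    (E-value tiers, overlap resolution, minimum HMM coverage of 0.3),
    per-sample score tables and CAZy-class summaries, Hill-number diversity
    profiles with rarefaction, the comparison statistics used for
    between-group contrasts (Welch and one-sample t from summary statistics,
    Pearson correlation, paired bootstrap, Hellinger transform, PCA,
    rarefaction-consensus feature selection), a synthetic-community generator
    with planted domain segments and ground-truth hit tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
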