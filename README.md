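# dfpmaa

Quantifying the carbohydrate-processing potential of bacterial genomes and
fecal shotgun metagenomes by integrating profile-HMM hits against a CAZyme
domain collection into a single normalized readout.

## What it computes

Taxonomic profiles tell you *who* is in a gut community; this package
scores *what the community can do* with carbohydrates. Merged shotgun reads
are translated into protein fragments, scanned against a dbCAN-style
collection of carbohydrate-active domain HMMs (glycoside hydrolases,
glycosyltransferases, polysaccharide lyases, carbohydrate esterases,
carbohydrate-binding modules, auxiliary activities), and the accepted hits
are integrated per HMM:

    DFPMAA_250(h) = 1e6 * sum_i cov(i) / N_aa,   cov(i) = (hmm_to - hmm_from + 1) / hmm_len

where the sum runs over accepted hits of HMM `h` and `N_aa` is the total
number of amino acids submitted to scanning ("domain fractions per million
amino acids", calibrated at 250-nt reads). The sample-level readout is the
sum over all HMMs, `sum(DFPMAA_250)`.

Hits are accepted with dbCAN-style rules (all configurable via
`filter_config()`): same-fragment overlap resolution (>50% of the shorter
alignment conflicts; the better i-Evalue wins), two-tier i-Evalue cutoffs
(1e-5 above 80 aa, else 1e-3), and minimum HMM coverage 0.3. Because of the
coverage rule, samples with mean merged-read length below 187.6 bp are
flagged non-comparable (`length_gate()`).

Around the score the package provides Hill-number diversity profiles and
exact hypergeometric rarefaction, the comparison statistics used for group
contrasts (Welch and one-sample t from summary statistics, Pearson
correlation, paired bootstrap, Hellinger transform, PCA, two-model
rarefaction-consensus feature selection), a fully seeded synthetic-community
generator with planted domain segments plus a naive exact-match scanner
standing in for HMMER at desk scale, and a command-line interface.

## Worked example

Build a toy registry and genome, simulate reads, and run the full pipeline:

```r
library(dfpmaa)

registry <- make_registry(8, c(GH = 0.5, CBM = 0.25, GT = 0.25),
                          seed = 1, len_range = c(60L, 160L))
genome <- make_toy_genome(registry, n_segments_per_hmm = 2,
                          spacer_len = 400, seed = 2)
reads <- simulate_reads(genome, 10000, 250, seed = 3)

tab <- dfpmaa_pipeline(reads, registry, sample_id = "toy")
tab
#> DFPMAA_250 score table: sample 'toy'
#>   8 scored HMMs, sum DFPMAA_250 = 963.8746
#>   total_aa = 3145572, mean read length = 250 nt, n_reads = 10000

round(class_proportions(tab), 3)
#>   CBM    GH    GT
#> 0.241 0.499 0.260

diversity_profile(tab$scores, c(0, 1, 2))
#>   q        d
#> 1 0 8.000000
#> 2 1 7.983421
#> 3 2 7.967156
```

All 8 planted domains are recovered (`d = 8` at `q = 0`), the near-flat
profile shows their scores are nearly even, and the class proportions
reflect the registry mix. Each score is an abundance ratio, so doubling the
reads (or the sequencing depth generally) leaves it unchanged — that
invariance, the 1:2:4 planted-density linearity, and the read-length
degradation below ~190 nt are all checked by the test suite.

For real data, run `hmmsearch --domtblout` (with `-Z` set to the number of
models in the collection) on FragGeneScan-predicted proteins from merged
reads, then:

```r
hits <- read_domtblout("sample.domtblout", orientation = "search")
accepted <- apply_dbcan_filter(hits, filter_config())
scores <- dfpmaa_per_hmm(accepted, total_aa = 3145572)
sum_dfpmaa(scores)
```

## Command line

A thin launcher is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dfpmaa.R", package = "dfpmaa"))')" \
    score --domtblout sample.domtblout --proteins proteins.fasta --out scores.tsv
```

Subcommands: `score`, `sum`, `classes`, `diversity`, `rarefy`, `trim`,
`compare`, `select`, `simulate`, `selftest`. Every run that writes output
also writes a `.provenance.json` record (inputs, thresholds, seed,
version), and all stochastic subcommands are bit-reproducible given a seed.

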