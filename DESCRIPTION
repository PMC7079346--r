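Package: paralogr
Title: Paralog Conservation Scoring and Gene-Family De Novo Mutation Burden
Version: 0.1.0
Authors@R:
    person("paralogr", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to score per-residue conservation across human paralogs and
    to test gene families for de novo mutation burden. Gene families are
    assembled from paralog pairs and split into sub-families by connected
    components of a pairwise-alignment similarity graph. Alignment columns are
    scored with a physico-chemical (AMAS-style) conservation index, normalized
    per gene into paralog conservation z-scores (para_zscore), and compared
    against ortholog conservation with Rand indices and Pearson correlation.
    Expected de novo mutation counts per gene and consequence class are derived
    from trinucleotide-context mutation rates, with missense expectations
    partitioned into paralog-conserved and non-conserved sites, and observed
    counts are tested family-wise with log-space Poisson upper-tail tests under
    Bonferroni correction. Includes variant normalization, per-protein track
    export with variant overlays, and a seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
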