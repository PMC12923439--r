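Package: dyadalign
Title: Lexical Alignment Metrics for Dyadic Conversation Transcripts
Version: 0.1.0
Authors@R: person("dyadalign", "maintainers", email = "dyadalign@example.org",
    role = c("aut", "cre"))
Description: Transforms raw two-person conversation transcripts into per-turn
    psycholinguistic time series and computes complementary indices of
    linguistic alignment: area under the absolute-difference curve (dAUC; a
    proximity measure, raw, standardized to a 50-turn length, and under a
    lag-1 re-pairing of exchanges) and lead/lag Spearman or Pearson
    correlations (a synchrony measure). Includes deterministic text cleaning
    (contraction expansion, tiered stopword removal, dictionary
    lemmatization), pluggable word-norm lexicons, permutation ("sham") dyads
    as null controls, corpus descriptive analytics, a coupled-AR(1) synthetic
    dyad generator, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
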