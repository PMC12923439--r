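mini_corpus <- function(texts_by_event) {
  rows <- do.call(rbind, lapply(names(texts_by_event), function(ev) {
    tx <- texts_by_event[[ev]]
    data.frame(event_id = ev, participant_id = rep_len(c("A", "B"),
                                                       length(tx)),
               text = tx, row_order = seq_along(tx),
               stringsAsFactors = FALSE)
  }))
  mark_turns(rows)
}

analytics_cell <- function(an, measure, stat) {
  an[[stat]][an$measure == measure]
}

test_that("raw TTR and retention match hand counts", {
  tab <- mini_corpus(list(e = c("the cat and the dog", "happy sad")))
  tok <- join_norms(tokenize(tab, cleaning_config("valence")),
                    build_fixture_lexicon(), "valence")
  an <- describe_corpus(tab, tok, build_fixture_lexicon())
  # utterance 1 alone: 5 tokens, 4 types -> 0.8; with utt 2: 7 tok, 6 types
  expect_equal(analytics_cell(an, "Type-token ratio raw (by conversation)",
                              "mean"), 6 / 7)
  # clean tokens: cat, dog, happy, sad of raw 7
  expect_equal(analytics_cell(
    an, "Cleaning retention rate (by conversation)", "mean"), 4 / 7)
  expect_equal(analytics_cell(
    an, "Token count all conversations (raw)", "mean"), 7)
  expect_equal(analytics_cell(
    an, "Word count clean (by conversation)", "mean"), 4)
  # 2 turns -> words-per-turn raw 3.5, clean 2
  expect_equal(analytics_cell(
    an, "Words-per-turn raw (by conversation)", "mean"), 3.5)
  expect_equal(analytics_cell(
    an, "Words-per-turn clean (by conversation)", "mean"), 2)
})

test_that("a 50% retention corpus reports 0.50", {
  # exactly half the tokens are stopwords
  tab <- mini_corpus(list(e = c("the happy", "a sad", "an dog", "oh storm")))
  tok <- join_norms(tokenize(tab, cleaning_config("valence")),
                    build_fixture_lexicon(), "valence")
  an <- describe_corpus(tab, tok, build_fixture_lexicon())
  expect_equal(analytics_cell(
    an, "Cleaning retention rate (by conversation)", "mean"), 0.50)
})

test_that("two identical conversations give zero sd on every measure", {
  tab <- mini_corpus(list(e1 = c("happy dog sleeps", "sad storm"),
                          e2 = c("happy dog sleeps", "sad storm")))
  tok <- join_norms(tokenize(tab, cleaning_config("valence")),
                    build_fixture_lexicon(), "valence")
  an <- describe_corpus(tab, tok, build_fixture_lexicon())
  per_conv <- grepl("by conversation", an$measure)
  expect_true(all(an$sd[per_conv] == 0))
  expect_true(all(an$min[per_conv] == an$max[per_conv]))
})

test_that("min <= mean <= max row-wise", {
  dir <- withr::local_tempdir()
  simulate_corpus(dir, n_dyads = 3, n_slots = 20, seed = 2)
  tab <- suppressWarnings(read_dyads(dir))
  tok <- join_norms(tokenize(tab, cleaning_config("valence")),
                    build_fixture_lexicon(), "valence")
  an <- describe_corpus(tab, tok, build_fixture_lexicon())
  ok <- !is.na(an$sd)
  expect_true(all(an$min[ok] <= an$mean[ok] + 1e-12))
  expect_true(all(an$mean[ok] <= an$max[ok] + 1e-12))
  ret <- analytics_cell(an, "Cleaning retention rate (by conversation)",
                        "mean")
  expect_true(ret > 0 && ret <= 1)
})

test_that("every cell agrees with an independent aggregation", {
  tab <- mini_corpus(list(e1 = c("the happy dog", "a sad storm", "dogs"),
                          e2 = c("uh huh happy", "storm storm storm")))
  lex <- build_fixture_lexicon()
  tok <- join_norms(tokenize(tab, cleaning_config("valence")), lex,
                    "valence")
  an <- describe_corpus(tab, tok, lex)
  # oracle: direct per-event recomputation from the long tables
  evs <- unique(tab$event_id)
  raw_counts <- vapply(evs, function(ev) {
    length(unlist(strsplit(normalize_string(tab$text[tab$event_id == ev]),
                           " ")))
  }, numeric(1))
  clean_counts <- vapply(evs, function(ev)
    sum(!is.na(tok$token_clean[tok$event_id == ev])), numeric(1))
  expect_equal(analytics_cell(an, "Word count raw (by conversation)",
                              "mean"), mean(raw_counts), tolerance = 1e-12)
  expect_equal(analytics_cell(an, "Word count raw (by conversation)", "sd"),
               sd(raw_counts), tolerance = 1e-12)
  expect_equal(analytics_cell(an, "Word count clean (by conversation)",
                              "max"), max(clean_counts), tolerance = 1e-12)
  freqs <- vapply(evs, function(ev) {
    tc <- tok$token_clean[tok$event_id == ev]
    mean(lex$freq_lg10[match(tc, lex$headword)], na.rm = TRUE)
  }, numeric(1))
  expect_equal(analytics_cell(an, "Lexical frequency lg10 (by conversation)",
                              "mean"), mean(freqs), tolerance = 1e-12)
})

test_that("degenerate corpora are rejected; absent dimensions warn", {
  tab <- mini_corpus(list(e = c("happy dog", "!!!", "sad", "storm")))
  tok <- join_norms(tokenize(tab, cleaning_config("valence")),
                    build_fixture_lexicon(), "valence")
  expect_error(describe_corpus(tab, tok, build_fixture_lexicon()), "empty")

  tab2 <- mini_corpus(list(e = c("happy dog", "sad storm")))
  tok2 <- join_norms(tokenize(tab2, cleaning_config("valence")),
                     as_norm_lexicon(fixture_lexicon_df()), "valence")
  warns <- capture_warnings(
    an <- describe_corpus(tab2, tok2, as_norm_lexicon(fixture_lexicon_df())))
  expect_match(warns, "morphemes|letters|freq_lg10", all = TRUE)
  expect_length(warns, 3L)
  expect_true(is.na(analytics_cell(
    an, "Morphemes-per-word (by conversation)", "mean")))
})

test_that("markdown rendering mirrors the table", {
  tab <- mini_corpus(list(e = c("happy dog", "sad storm")))
  lex <- build_fixture_lexicon()
  tok <- join_norms(tokenize(tab, cleaning_config("valence")), lex,
                    "valence")
  md <- analytics_markdown(describe_corpus(tab, tok, lex))
  expect_match(md[1], "Measure.*Mean.*Stdev")
  expect_length(md, 2 + 14)
})
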