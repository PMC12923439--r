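prep_tokens <- function(texts, speakers = rep_len(c("A", "B"),
                                                  length(texts)),
                        event = "e", dims = "valence",
                        lexicon = as_norm_lexicon(fixture_lexicon_df())) {
  tab <- mark_turns(data.frame(event_id = event, participant_id = speakers,
                               text = texts, row_order = seq_along(texts),
                               stringsAsFactors = FALSE))
  join_norms(tokenize(tab, cleaning_config(dims, lemmatize = FALSE)),
             lexicon, dims)
}

test_that("aggregate_turns averages non-NA token values per turn", {
  # A turn 1: happy(9) sad(1) zyzzyva(NA) -> 5; B turn 2: storm(2)
  tok <- prep_tokens(c("happy sad zyzzyva", "storm", "dog", "sad"))
  set <- aggregate_turns(tok)
  expect_length(set, 1L)
  s <- set[[1]]
  expect_equal(s$values_a, c(5, 7))
  expect_equal(s$values_b, c(2, 1))
  expect_equal(s$turn_count_observed, 4L)
  expect_equal(s$speaker_a, "A")
})

test_that("a pure-stopword backchannel turn yields an NA slot", {
  tok <- prep_tokens(c("happy dog", "oh yeah", "sad storm", "dog"))
  s <- aggregate_turns(tok)[[1]]
  expect_true(is.na(s$values_b[1]))
  expect_false(s$filled)
})

test_that("odd trailing turn leaves NA in the partner's final slot", {
  tok <- prep_tokens(c("happy", "sad", "dog", "storm", "happy sad"))
  s <- aggregate_turns(tok)[[1]]
  expect_length(s$values_a, 3L)
  expect_length(s$values_b, 3L)
  expect_true(is.na(s$values_b[3]))
  expect_equal(s$values_a, c(9, 7, 5))
})

test_that("a speaker with no observed values on a dimension errors", {
  tok <- prep_tokens(c("happy dog", "zyzzyva", "sad", "oh yeah"))
  expect_error(aggregate_turns(tok), "e.*valence")
})

test_that("fill_missing applies edge fill and linear interpolation", {
  s <- make_series(c(NA, 2, NA, 4, NA), c(1, 1, 1, 1, 1))
  f <- fill_missing(s)
  expect_equal(f$values_a, c(2, 2, 3, 4, 4))
  expect_equal(f$fill_flags_a, c("edge_filled", "observed", "interpolated",
                                 "observed", "edge_filled"))
  expect_equal(f$fill_flags_b, rep("observed", 5))
  expect_true(f$filled)

  expect_equal(fill_missing(make_series(c(NA, NA, 5), 1:3))$values_a,
               c(5, 5, 5))
  s2 <- make_series(1:4, 4:1)
  expect_equal(fill_missing(s2)$values_a, 1:4)
})

test_that("fill_missing matches the approx oracle on random masked series", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(3:40, 1)
    x <- rnorm(n)
    mask <- runif(n) < 0.4
    if (all(mask)) mask[sample(n, 1)] <- FALSE
    x[mask] <- NA
    s <- make_series(x, rep(0, n))
    f <- fill_missing(s)
    expect_equal(f$values_a, oracle_fill(x), tolerance = 1e-12)
    # idempotent, flag conservation, interpolants within flanking bounds
    expect_identical(fill_missing(f)$values_a, f$values_a)
    expect_equal(sum(f$fill_flags_a != "observed"), sum(is.na(x)))
    expect_true(all(f$values_a >= min(x, na.rm = TRUE) - 1e-12 &
                      f$values_a <= max(x, na.rm = TRUE) + 1e-12))
  }
})

test_that("fill_missing refuses an all-NA vector", {
  s <- make_series(c(NA_real_, NA_real_), c(1, 2))
  expect_error(fill_missing(s), "all-NA")
})

test_that("backchannel removal merges flanking same-speaker turns", {
  # 3 turns: A("happy dog"), B("oh yeah") all-stopword, A("sad storm")
  tok <- prep_tokens(c("happy dog", "oh yeah", "sad storm", "dog"))
  tok <- tok[tok$turn_index <= 3, ]
  attr(tok, "dimensions") <- "valence"
  out <- drop_backchannel_turns(tok)
  expect_equal(unique(out$participant_id), "A")
  expect_equal(unique(out$turn_index), 1L)     # merged into a single turn
  expect_equal(out$token_raw, c("happy", "dog", "sad", "storm"))
})

test_that("backchannel removal is identity when no turn is fully NA", {
  tok <- prep_tokens(c("happy dog", "storm", "sad", "dog"))
  out <- drop_backchannel_turns(tok)
  expect_equal(out$token_raw, tok$token_raw)
  expect_equal(out$turn_index, tok$turn_index)
})

test_that("removing every turn of one speaker breaks the dyad downstream", {
  tok <- prep_tokens(c("happy", "oh yeah", "sad", "uh huh", "dog",
                       "oh yeah"))
  out <- drop_backchannel_turns(tok)
  expect_equal(unique(out$participant_id), "A")
  expect_error(aggregate_turns(out))
})

test_that("count_na_turns reports the interpolation diagnostic", {
  tok <- prep_tokens(c("happy dog", "oh yeah", "sad storm", "zyzzyva"))
  expect_equal(unname(count_na_turns(tok)), 2L)
  tok2 <- prep_tokens(c("happy dog", "storm", "sad", "dog"))
  expect_equal(unname(count_na_turns(tok2)), 0L)
})

test_that("series_to_long round-trips values and flags", {
  s <- fill_missing(make_series(c(NA, 2, 4), c(1, NA, 3)))
  long <- series_to_long(s)
  expect_equal(nrow(long), 6L)
  expect_equal(long$value[long$speaker == "A"], c(2, 2, 4))
  expect_equal(sum(long$fill_flag != "observed"), 2L)
})
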