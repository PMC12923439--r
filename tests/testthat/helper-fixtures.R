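# Shared fixtures and independent oracles. Oracles deliberately use a
# different route than the implementation (explicit loops, stats::approx,
# stats::cor) so agreement is informative.

make_series <- function(a, b, event = "ev", dim = "valence",
                        turn_count = 2L * length(a)) {
  turn_series(event_id = event, dimension = dim,
              speaker_a = "A", speaker_b = "B",
              values_a = a, values_b = b,
              turn_count_observed = turn_count)
}

# brute-force trapezoid: element-by-element loop
oracle_trapz <- function(a, b) {
  d <- abs(a - b)
  area <- 0
  for (i in seq_len(length(d) - 1L)) {
    area <- area + (d[i] + d[i + 1L]) / 2
  }
  area
}

# closed-form linear fill via stats::approx with rule = 2 (edge carry)
oracle_fill <- function(x) {
  obs <- which(!is.na(x))
  if (length(obs) == 1L) return(rep(x[obs], length(x)))
  stats::approx(obs, x[obs], xout = seq_along(x), method = "linear",
                rule = 2)$y
}

# explicit shift + stats::cor
oracle_lag_cor <- function(a, b, k, method) {
  n <- length(a)
  if (k >= 0) {
    x <- a[(1 + k):n]; y <- b[1:(n - k)]
  } else {
    x <- a[1:(n + k)]; y <- b[(1 - k):n]
  }
  if (length(x) < 3) return(NA_real_)
  suppressWarnings(stats::cor(x, y, method = method))
}

# run-length turn-count oracle
oracle_turn_count <- function(speakers) length(rle(speakers)$lengths)

# a tiny two-conversation corpus on disk: one CSV (with metadata), one TXT
write_fixture_corpus <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c("participant_id,text,timestamp",
               "mary,The dogs slept,0.5",
               "john,\"Isn't that sad\",1.5",
               "mary,They slept on the floor,2.0",
               "john,A happy dog dreams,3.1"),
             file.path(dir, "a.csv"))
  writeLines(c("Mary: I love sunshine",
               "John: Me too",
               "and warm rain",
               "Mary: The storm was terrible",
               "John: Oh yeah"),
             file.path(dir, "b.txt"))
  dir
}

fixture_lexicon_df <- function() {
  data.frame(headword = c("happy", "sad", "dog", "storm"),
             valence = c(9, 1, 7, 2),
             concreteness = c(2, 2, 5, 4),
             stringsAsFactors = FALSE)
}
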