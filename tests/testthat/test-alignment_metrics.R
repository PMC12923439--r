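test_that("dauc_raw matches closed forms and the brute-force oracle", {
  expect_equal(dauc_raw(make_series(c(1, 2, 3), c(1, 2, 3))), 0)
  # constant |diff| d over T slots integrates to d * (T - 1)
  expect_equal(dauc_raw(make_series(rep(5, 7), rep(2, 7))), 3 * 6)
  set.seed(1)
  for (i in 1:25) {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(dauc_raw(make_series(a, b)), oracle_trapz(a, b),
                 tolerance = 1e-10)
  }
  expect_error(dauc_raw(make_series(1, 2)), "insufficient turns")
  expect_error(dauc_raw(make_series(c(1, NA), c(1, 2))), "filled")
})

test_that("dauc_normalized applies the 50-turn standardization", {
  expect_equal(dauc_normalized(100, 25), 200)
  expect_equal(dauc_normalized(100, 50), 100)  # identity at 50 turns
  expect_error(dauc_normalized(100, 0), "positive")
  expect_error(dauc_normalized(100, -3), "positive")
  s <- make_series(rnorm(10), rnorm(10))
  expect_equal(dauc_normalized(dauc_raw(s), s$turn_count_observed),
               dauc_raw(s) * 50 / 20)
})

test_that("equal per-turn distance gives equal normalized dAUC up to the
           trapezoid end effect", {
  a1 <- rep(4, 10); b1 <- rep(1, 10)     # T = 20 turns
  a2 <- rep(4, 20); b2 <- rep(1, 20)     # T = 40 turns
  n1 <- dauc_normalized(dauc_raw(make_series(a1, b1)), 20)
  n2 <- dauc_normalized(dauc_raw(make_series(a2, b2)), 40)
  # exact closed forms: 3*(n-1) * 50 / (2n)
  expect_equal(n1, 3 * 9 * 50 / 20)
  expect_equal(n2, 3 * 19 * 50 / 40)
  expect_equal(n2 / n1, (19 / 20) / (9 / 10), tolerance = 1e-12)
})

test_that("lag-1 re-pairing puts the second speaker first", {
  # first speaker echoes the second one exchange later: a[i+1] == b[i]
  b <- c(3, 1, 4, 1, 5, 9)
  a <- c(0, b[-6])
  s <- make_series(a, b)
  expect_gt(dauc_raw(s), 0)
  expect_equal(dauc_lag1(s)$raw, 0)
  expect_equal(dauc_lag1(s)$first_speaker, "A")

  const <- make_series(rep(2, 5), rep(2, 5))
  expect_equal(dauc_raw(const), 0)
  expect_equal(dauc_lag1(const)$raw, 0)

  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(15); b <- rnorm(15)
    s <- make_series(a, b)
    l1 <- dauc_lag1(s)
    # oracle: explicit re-pair, second speaker's slot i vs first's slot i+1
    expect_equal(l1$raw, oracle_trapz(a[2:15], b[1:14]), tolerance = 1e-10)
    expect_equal(l1$normalized, l1$raw * 50 / 30, tolerance = 1e-10)
  }
  expect_error(dauc_lag1(make_series(1:2, 2:1)), "insufficient")
})

test_that("lagged_correlations match the shift + stats::cor oracle", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(30); b <- rnorm(30)
    s <- make_series(a, b)
    for (m in c("pearson", "spearman")) {
      got <- lagged_correlations(s, -3:3, method = m)
      want <- vapply(-3:3, oracle_lag_cor, numeric(1), a = a, b = b,
                     method = m)
      expect_equal(unname(got), want, tolerance = 1e-10)
    }
  }
})

test_that("a deterministic one-slot echo is identified at one offset", {
  set.seed(99)
  a <- rnorm(20)
  b <- c(0, a[-20])  # b follows a by one slot
  s <- make_series(a, b)
  for (m in c("pearson", "spearman")) {
    r <- lagged_correlations(s, -3:3, method = m)
    expect_equal(unname(r["lead1"]), 1.0, tolerance = 1e-12)
    expect_lt(max(r[names(r) != "lead1"]), 1.0)
  }
  expect_equal(unname(lagged_correlations(make_series(a, a), 0)["lag0"]), 1)
})

test_that("degenerate overlaps yield NA with a warning, never an error", {
  s <- make_series(rnorm(4), rnorm(4))
  expect_warning(r <- lagged_correlations(s, offsets = 3), "overlap")
  expect_true(is.na(r[["lag3"]]))
  z <- make_series(rep(1, 10), rnorm(10))
  expect_warning(rz <- lagged_correlations(z, 0), "zero-variance")
  expect_true(is.na(rz[["lag0"]]))
  expect_error(lagged_correlations(s, 0, method = "kendall"))
})

test_that("symmetry and invariance properties hold", {
  set.seed(4)
  a <- rnorm(25); b <- rnorm(25)
  s <- make_series(a, b)
  swapped <- make_series(b, a)
  # dAUC invariant to speaker swap
  expect_equal(dauc_raw(s), dauc_raw(swapped), tolerance = 1e-12)
  # corr at k (A shifted) equals corr at -k (B shifted)
  for (k in -3:3) {
    expect_equal(
      unname(lagged_correlations(s, k, "pearson")),
      unname(lagged_correlations(swapped, -k, "pearson")),
      tolerance = 1e-12)
  }
  # adding a constant to one speaker: dAUC shifts, correlations do not
  s_up <- make_series(a + 10, b)
  expect_equal(dauc_raw(make_series(rep(10, 5) + 1:5, as.numeric(1:5))),
               10 * 4)
  for (m in c("pearson", "spearman")) {
    expect_equal(lagged_correlations(s_up, -2:2, m),
                 lagged_correlations(s, -2:2, m), tolerance = 1e-12)
  }
  # Spearman invariant under strictly monotone transforms
  s_mono <- make_series(exp(a), b^3 + 5 * b)
  expect_equal(lagged_correlations(s_mono, -2:2, "spearman"),
               lagged_correlations(s, -2:2, "spearman"), tolerance = 1e-12)
})

test_that("summarize_dyads assembles one row per series with all indices", {
  set.seed(5)
  set <- structure(list(
    make_series(rnorm(20), rnorm(20), event = "e1"),
    make_series(rnorm(20), rnorm(20), event = "e1", dim = "concreteness"),
    make_series(c(NA, rnorm(19)), rnorm(20), event = "e2")),
    class = "turn_series_set")
  out <- summarize_dyads(set, corr_type = "pearson", lags = -2:2,
                         average_dauc = TRUE)
  expect_equal(nrow(out), 3L)
  expect_setequal(names(out), c(
    "event_id", "dimension", "first_speaker", "turn_count_observed",
    "dauc_raw", "dauc_normalized", "dauc_raw_lag1", "dauc_norm_lag1",
    "dauc_norm_avg", "corr_type",
    paste0("corr_", c("lead2", "lead1", "lag0", "lag1", "lag2"))))
  expect_true(all(out$dauc_raw >= 0))
  expect_equal(out$dauc_normalized,
               out$dauc_raw * 50 / out$turn_count_observed)
  expect_equal(out$dauc_norm_avg,
               (out$dauc_normalized + out$dauc_norm_lag1) / 2)
  cors <- as.matrix(out[, grepl("^corr_l", names(out))])
  expect_true(all(abs(cors) <= 1 + 1e-12, na.rm = TRUE))
})
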