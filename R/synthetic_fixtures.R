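#' Simulate a coupled dyadic turn series
#'
#' Minimal generative model with separately tunable global similarity and
#' turn-wise synchrony. The leader follows a stationary AR(1):
#' `a_t = rho * a_{t-1} + e_t`; the follower couples to the leader's value
#' `delay` exchange slots earlier: `b_t = beta * a_{t-delay} + n_t`, with
#' `e, n ~ iid Normal(0, noise_sd^2)` and the leader initialized from its
#' stationary distribution (variance `noise_sd^2 / (1 - rho^2)`). Setting
#' `beta = 0` gives two independent series (no synchrony); `beta = 1`,
#' `noise_sd -> 0` gives a perfect delayed echo.
#'
#' With `backchannel_rate > 0`, follower slots are independently replaced by
#' `NA` (a pure-backchannel turn) at that rate, exercising the interpolation
#' path.
#'
#' @param n_slots number of exchange slots.
#' @param rho leader autocorrelation, in `[0, 1)`.
#' @param beta follower coupling strength.
#' @param delay coupling delay in slots (positive integer).
#' @param noise_sd innovation standard deviation (positive).
#' @param follower_noise_sd standard deviation of the follower's own noise;
#'   defaults to `noise_sd`. The limit `follower_noise_sd -> 0` with
#'   `beta = 1` gives a perfect delayed echo (note the correlation is
#'   invariant to a shared noise scale, so the echo limit needs the
#'   follower's noise to shrink separately).
#' @param seed optional integer seed; same spec + seed gives identical
#'   output.
#' @param backchannel_rate probability a follower slot is a backchannel
#'   (`NA`), in `[0, 1)`.
#' @param event_id conversation identifier for the returned series.
#' @param dimension dimension name for the returned series.
#' @return A `turn_series` with speakers `"leader"` (first) and
#'   `"follower"`, `turn_count_observed = 2 * n_slots`.
#' @export
simulate_dyad <- function(n_slots = 200L, rho = 0.4, beta = 0.8,
                          delay = 1L, noise_sd = 0.5, seed = NULL,
                          backchannel_rate = 0,
                          follower_noise_sd = noise_sd,
                          event_id = "sim", dimension = "valence") {
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  if (follower_noise_sd < 0) {
    stop("follower_noise_sd must be non-negative", call. = FALSE)
  }
  if (delay < 0 || delay != round(delay)) {
    stop("delay must be a non-negative integer", call. = FALSE)
  }
  if (backchannel_rate < 0 || backchannel_rate >= 1) {
    stop("backchannel_rate must be in [0, 1)", call. = FALSE)
  }
  if (n_slots < 2L) stop("n_slots must be >= 2", call. = FALSE)
  run <- function() {
    burn <- delay
    m <- n_slots + burn
    eps <- stats::rnorm(m, 0, noise_sd)
    a <- numeric(m)
    a[1] <- stats::rnorm(1, 0, noise_sd / sqrt(1 - rho^2))
    for (t in seq_len(m)[-1]) a[t] <- rho * a[t - 1] + eps[t]
    lagged <- if (delay == 0) a[(burn + 1):m] else
      a[(burn + 1 - delay):(m - delay)]
    b <- beta * lagged + stats::rnorm(n_slots, 0, follower_noise_sd)
    a <- a[(burn + 1):m]
    if (backchannel_rate > 0) {
      b[stats::runif(n_slots) < backchannel_rate] <- NA_real_
    }
    list(a = a, b = b)
  }
  sim <- if (is.null(seed)) run() else with_seed(seed, run())
  turn_series(event_id = event_id, dimension = dimension,
              speaker_a = "leader", speaker_b = "follower",
              values_a = sim$a, values_b = sim$b,
              turn_count_observed = 2L * n_slots)
}

#' Realize a turn series as a word-level transcript
#'
#' Converts a simulated (or any) turn series into an utterance table by
#' sampling, for each slot, the `words_per_turn` lexicon words whose value
#' on `dimension` is nearest the slot's target value, so the full
#' text-processing pipeline — not just the numeric core — can be exercised.
#' `NA` follower slots become a pure-stopword backchannel utterance
#' ("oh yeah"). Optional filler stopwords are prepended to each utterance to
#' exercise stopword removal; they do not affect slot means.
#'
#' The achievable slot mean is quantized by the lexicon's coverage; the
#' maximum absolute deviation between each slot's target and the realized
#' word-mean is reported in the attribute `"quantization_error"`.
#'
#' @param series a `turn_series` (values on the scale of `dimension`).
#' @param lexicon a `norm_lexicon` to sample words from.
#' @param dimension lexicon dimension to match on (defaults to the series
#'   dimension).
#' @param words_per_turn content words per turn.
#' @param include_fillers prepend filler stopwords to utterances?
#' @return An utterance table (with turns marked); attribute
#'   `"quantization_error"` gives the realization error bound.
#' @export
realize_transcript <- function(series, lexicon,
                               dimension = series$dimension,
                               words_per_turn = 3L,
                               include_fillers = TRUE) {
  stopifnot(inherits(series, "turn_series"),
            inherits(lexicon, "norm_lexicon"))
  if (!dimension %in% names(lexicon)) {
    stop("dimension '", dimension, "' not in lexicon", call. = FALSE)
  }
  vals <- lexicon[[dimension]]
  ok <- !is.na(vals)
  words <- lexicon$headword[ok]
  vals <- vals[ok]
  pick <- function(target) {
    idx <- order(abs(vals - target))[seq_len(words_per_turn)]
    list(text = paste(words[idx], collapse = " "),
         err = abs(mean(vals[idx]) - target))
  }
  n <- length(series$values_a)
  spk <- character(0); txt <- character(0); err <- 0
  for (i in seq_len(n)) {
    for (side in c("a", "b")) {
      v <- if (side == "a") series$values_a[i] else series$values_b[i]
      who <- if (side == "a") series$speaker_a else series$speaker_b
      if (is.na(v)) {
        spk <- c(spk, who); txt <- c(txt, "oh yeah")
      } else {
        p <- pick(v)
        err <- max(err, p$err)
        line <- if (include_fillers) paste("well", p$text) else p$text
        spk <- c(spk, who); txt <- c(txt, line)
      }
    }
  }
  tab <- data.frame(event_id = series$event_id, participant_id = spk,
                    text = txt, row_order = seq_along(spk),
                    stringsAsFactors = FALSE)
  tab <- mark_turns(tab)
  attr(tab, "quantization_error") <- err
  attr(tab, "target_series") <- series
  tab
}

#' Simulate a corpus of transcripts on disk
#'
#' Generates `n_dyads` coupled dyads with [simulate_dyad()], realizes each
#' as a word-level transcript against the synthetic fixture lexicon, and
#' writes one CSV per conversation — a self-contained test corpus for the
#' full pipeline, no downloads required.
#'
#' @param dir_path output directory for the transcript CSVs.
#' @param n_dyads number of conversations.
#' @param n_slots exchange slots per conversation.
#' @param seed master seed; dyad `i` uses stream `seed + i`.
#' @param dimension lexicon dimension the series values live on.
#' @param ... further arguments passed to [simulate_dyad()].
#' @return Invisibly, the paths written.
#' @export
simulate_corpus <- function(dir_path, n_dyads = 3L, n_slots = 60L,
                            seed = 1L, dimension = "valence", ...) {
  lex <- build_fixture_lexicon()
  # centre/scale the series onto the dimension's observed range
  rng <- range(lex[[dimension]], na.rm = TRUE)
  mid <- mean(rng); half <- diff(rng) / 2
  paths <- character(0)
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  for (i in seq_len(n_dyads)) {
    s <- simulate_dyad(n_slots = n_slots, seed = seed + i,
                       dimension = dimension,
                       event_id = sprintf("dyad%02d", i), ...)
    scale_to <- function(x) mid + half * tanh(x / 2)
    s$values_a <- scale_to(s$values_a)
    s$values_b <- scale_to(s$values_b)
    tab <- realize_transcript(s, lex, dimension = dimension)
    paths <- c(paths, write_dyads(tab, dir_path))
  }
  invisible(paths)
}
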