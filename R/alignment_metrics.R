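# Trapezoidal area under the absolute-difference curve of two equal-length,
# NA-free vectors, with unit spacing on the slot index.
trapz_absdiff <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (anyNA(a) || anyNA(b)) {
    stop("series must be filled (NA-free) before computing dAUC",
         call. = FALSE)
  }
  n <- length(a)
  if (n < 2L) stop("insufficient turns for area (need >= 2 slots)",
                   call. = FALSE)
  d <- abs(a - b)
  sum((d[-n] + d[-1]) / 2)
}

series_vectors <- function(series) {
  stopifnot(inherits(series, "turn_series"))
  if (!series$filled) {
    stop("series must be filled (see fill_missing()) before computing ",
         "alignment metrics", call. = FALSE)
  }
  list(a = series$values_a, b = series$values_b)
}

#' Raw dAUC: area under the absolute-difference curve
#'
#' The per-slot distance `d_i = |a_i - b_i|` between the two speakers'
#' scores is integrated over exchange slots by the trapezoidal rule with
#' unit spacing: `sum_{i=1}^{n-1} (d_i + d_{i+1}) / 2`. Lower area means the
#' speakers stayed closer on the dimension (a proximity index); it carries
#' units of dimension-units x turns and grows with conversation length.
#'
#' @param series a filled `turn_series`.
#' @return Non-negative scalar area.
#' @export
dauc_raw <- function(series) {
  v <- series_vectors(series)
  trapz_absdiff(v$a, v$b)
}

#' Standardize a raw dAUC to a 50-turn conversation length
#'
#' `dauc_normalized = dauc_raw * 50 / turn_count`: the area a conversation
#' with the same average per-turn distance would accrue over the standard
#' 50-turn length, making conversations of different lengths comparable.
#' At `turn_count = 50` normalization is the identity.
#'
#' @param raw raw dAUC value.
#' @param turn_count observed turn count of the conversation (positive).
#' @return Normalized area.
#' @export
dauc_normalized <- function(raw, turn_count) {
  if (!is.numeric(turn_count) || length(turn_count) != 1L ||
      turn_count <= 0) {
    stop("turn_count must be a positive number", call. = FALSE)
  }
  raw * 50 / turn_count
}

#' dAUC under the lag-1 re-pairing of exchanges
#'
#' The original pairing always places the first speaker's turn before the
#' second's within each exchange, so raw dAUC disproportionately reflects
#' the second speaker's adjustment to the first. The lag-1 re-pairing
#' switches the order: the second speaker's exchange-`i` turn is paired with
#' the first speaker's exchange-`i + 1` turn (`d_i = |a_{i+1} - b_i|`), the
#' non-overlapping ends being trimmed. The first speaker's label is recorded
#' to track directionality.
#'
#' Normalization uses the observed turn count of the original series.
#'
#' @param series a filled `turn_series`.
#' @return List with `raw`, `normalized`, and `first_speaker`.
#' @export
dauc_lag1 <- function(series) {
  v <- series_vectors(series)
  n <- length(v$a)
  if (n < 3L) stop("insufficient turns for lag-1 area (need >= 3 slots)",
                   call. = FALSE)
  raw <- trapz_absdiff(v$a[-1], v$b[-n])
  list(raw = raw,
       normalized = dauc_normalized(raw, series$turn_count_observed),
       first_speaker = series$speaker_a)
}

# Pearson product-moment correlation, textbook form; NA when either side has
# zero variance.
pearson_r <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  if (sxx == 0 || syy == 0) return(NA_real_)
  sum((x - mx) * (y - my)) / sqrt(sxx * syy)
}

# Average ranks (ties shared), as used for the Spearman variant.
average_rank <- function(x) rank(x, ties.method = "average")

#' Lead/lag correlations between the two speakers' series
#'
#' For each offset `k`, the first speaker's vector is shifted by `k`
#' exchange slots and correlated with the second speaker's vector over the
#' overlap (non-overlapping ends dropped, no wraparound). Positive offsets
#' are lags — the first speaker's series is shifted back, pairing their
#' exchange-`(i+k)` turn with the partner's exchange-`i` turn, emphasizing
#' the first speaker's responses. Negative offsets are leads — the series is
#' shifted ahead, emphasizing the partner's responses. Spearman converts
#' both overlap windows to average ranks immediately before the
#' product-moment computation.
#'
#' A zero-variance overlap, or an overlap shorter than 3 slots, yields an
#' `NA` coefficient with a warning (never an error, never a forced ±1).
#'
#' @param series a filled `turn_series`.
#' @param offsets integer offsets in turns (default `-3:3`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Named numeric vector of coefficients in `[-1, 1]` (or `NA`),
#'   names `"lead3"` ... `"lag3"` style with `"lag0"` for the immediate
#'   pairing.
#' @export
lagged_correlations <- function(series, offsets = -3:3,
                                method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- series_vectors(series)
  n <- length(v$a)
  out <- stats::setNames(rep(NA_real_, length(offsets)),
                         offset_label(offsets))
  for (j in seq_along(offsets)) {
    k <- offsets[j]
    if (k >= 0) {
      ov <- n - k
      if (ov < 3L) { warn_overlap(series, k); next }
      x <- v$a[(1L + k):n]
      y <- v$b[1L:ov]
    } else {
      ov <- n + k
      if (ov < 3L) { warn_overlap(series, k); next }
      x <- v$a[1L:ov]
      y <- v$b[(1L - k):n]
    }
    if (method == "spearman") {
      x <- average_rank(x)
      y <- average_rank(y)
    }
    r <- pearson_r(x, y)
    if (is.na(r)) {
      warning("zero-variance overlap at offset ", k, " for event '",
              series$event_id, "'; coefficient set to NA", call. = FALSE)
    }
    out[j] <- r
  }
  out
}

warn_overlap <- function(series, k) {
  warning("overlap shorter than 3 slots at offset ", k, " for event '",
          series$event_id, "'; coefficient set to NA", call. = FALSE)
}

offset_label <- function(offsets) {
  ifelse(offsets < 0, paste0("lead", -offsets), paste0("lag", offsets))
}

#' Summarize alignment for every conversation and dimension
#'
#' Computes, per `turn_series`, the proximity indices (raw dAUC, 50-turn
#' normalized dAUC, and both under the lag-1 exchange re-pairing) and the
#' synchrony indices (lead/lag correlations at each requested offset).
#' Unfilled series are passed through [fill_missing()] first.
#'
#' @param series a `turn_series_set` (or single `turn_series`).
#' @param corr_type `"spearman"` or `"pearson"`.
#' @param lags integer offsets for the correlations (default `-3:3`).
#' @param average_dauc also report the mean of the immediate and lag-1
#'   normalized dAUC values (`dauc_norm_avg` column)?
#' @return Data frame, one row per conversation x dimension, with columns
#'   `event_id`, `dimension`, `first_speaker`, `turn_count_observed`,
#'   `dauc_raw`, `dauc_normalized`, `dauc_raw_lag1`, `dauc_norm_lag1`,
#'   optionally `dauc_norm_avg`, `corr_type`, and one `corr_*` column per
#'   offset.
#' @export
summarize_dyads <- function(series, corr_type = c("spearman", "pearson"),
                            lags = -3:3, average_dauc = FALSE) {
  corr_type <- match.arg(corr_type)
  if (inherits(series, "turn_series")) {
    series <- structure(list(series), class = "turn_series_set")
  }
  rows <- lapply(series, function(s) {
    if (!s$filled) s <- fill_missing(s)
    raw <- dauc_raw(s)
    norm <- dauc_normalized(raw, s$turn_count_observed)
    l1 <- dauc_lag1(s)
    cors <- lagged_correlations(s, offsets = lags, method = corr_type)
    row <- data.frame(
      event_id = s$event_id, dimension = s$dimension,
      first_speaker = s$speaker_a,
      turn_count_observed = s$turn_count_observed,
      dauc_raw = raw, dauc_normalized = norm,
      dauc_raw_lag1 = l1$raw, dauc_norm_lag1 = l1$normalized,
      stringsAsFactors = FALSE)
    if (average_dauc) row$dauc_norm_avg <- (norm + l1$normalized) / 2
    row$corr_type <- corr_type
    for (nm in names(cors)) row[[paste0("corr_", nm)]] <- cors[[nm]]
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
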