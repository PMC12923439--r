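#' Construct a per-turn time series for one conversation and dimension
#'
#' A `turn_series` holds one mean norm value per speaker per exchange slot.
#' Slot `i` pairs the first speaker's turn `2i - 1` with the second
#' speaker's turn `2i` (turns alternate strictly by construction); a
#' trailing unpaired turn leaves an `NA` in the partner's final slot.
#'
#' @param event_id conversation identifier.
#' @param dimension norm dimension name.
#' @param speaker_a,speaker_b speaker labels; `speaker_a` spoke first.
#' @param values_a,values_b numeric vectors of equal length (one value per
#'   exchange slot; `NA` allowed before filling).
#' @param turn_count_observed observed number of turns in the conversation.
#' @param fill_flags_a,fill_flags_b per-slot provenance, one of
#'   `"observed"`, `"edge_filled"`, `"interpolated"` (`"observed"` for all
#'   slots before filling; `NA`-valued slots keep `"observed"` until filled).
#' @return An object of class `turn_series`.
#' @export
turn_series <- function(event_id, dimension, speaker_a, speaker_b,
                        values_a, values_b, turn_count_observed,
                        fill_flags_a = rep("observed", length(values_a)),
                        fill_flags_b = rep("observed", length(values_b))) {
  stopifnot(length(values_a) == length(values_b),
            length(fill_flags_a) == length(values_a),
            length(fill_flags_b) == length(values_b))
  structure(list(event_id = event_id, dimension = dimension,
                 speaker_a = speaker_a, speaker_b = speaker_b,
                 values_a = as.numeric(values_a),
                 values_b = as.numeric(values_b),
                 fill_flags_a = fill_flags_a, fill_flags_b = fill_flags_b,
                 turn_count_observed = as.integer(turn_count_observed),
                 filled = !anyNA(values_a) && !anyNA(values_b)),
            class = "turn_series")
}

#' @export
print.turn_series <- function(x, ...) {
  cat("<turn_series> ", x$event_id, " / ", x$dimension, ": ",
      length(x$values_a), " exchange slots, ", x$turn_count_observed,
      " turns, speakers ", x$speaker_a, " (first) vs ", x$speaker_b,
      if (x$filled) ", filled" else "", "\n", sep = "")
  invisible(x)
}

#' Aggregate token norms to per-turn, per-speaker time series
#'
#' For each conversation, speaker, turn and dimension, the slot value is the
#' arithmetic mean of the turn's non-`NA` token values; a turn whose tokens
#' are all `NA` (e.g., a pure-stopword backchannel such as "oh yeah") yields
#' an `NA` slot, to be filled by [fill_missing()]. Speakers are paired
#' within exchanges to give equal-length vectors.
#'
#' @param tokens a token table after [join_norms()].
#' @param dims dimensions to aggregate; defaults to all joined dimensions.
#' @return A list of `turn_series` (class `turn_series_set`), one per
#'   conversation x dimension.
#' @export
aggregate_turns <- function(tokens, dims = attr(tokens, "dimensions")) {
  stopifnot(!is.null(dims), all(dims %in% names(tokens)))
  out <- list()
  for (ev in unique(tokens$event_id)) {
    sub <- tokens[tokens$event_id == ev, , drop = FALSE]
    sub <- sub[order(sub$row_order), , drop = FALSE]
    n_turn <- max(sub$turn_index)
    # turns alternate strictly, so odd turns belong to the first speaker —
    # recover speaker_a by parity even if turn 1 has no surviving tokens
    min_turn <- min(sub$turn_index)
    spk_min <- sub$participant_id[sub$turn_index == min_turn][1]
    other <- unique(sub$participant_id[sub$participant_id != spk_min])[1]
    first <- if (min_turn %% 2L == 1L) spk_min else other
    second <- if (identical(first, spk_min)) other else spk_min
    n_slot <- ceiling(n_turn / 2)
    for (d in dims) {
      turn_mean <- vapply(seq_len(n_turn), function(t) {
        v <- sub[[d]][sub$turn_index == t]
        v <- v[!is.na(v)]
        if (length(v) == 0L) NA_real_ else mean(v)
      }, numeric(1))
      va <- turn_mean[seq(1L, n_turn, by = 2L)]
      vb <- if (n_turn >= 2L) turn_mean[seq(2L, n_turn, by = 2L)] else
        numeric(0)
      length(va) <- n_slot
      length(vb) <- n_slot  # trailing odd turn -> NA in partner's last slot
      if (all(is.na(va)) || all(is.na(vb))) {
        empty <- if (all(is.na(va))) first else second
        stop("no observed values for speaker '", empty, "' in event '", ev,
             "' on dimension '", d, "'", call. = FALSE)
      }
      out[[length(out) + 1L]] <- turn_series(
        event_id = ev, dimension = d, speaker_a = first, speaker_b = second,
        values_a = va, values_b = vb, turn_count_observed = n_turn)
    }
  }
  structure(out, class = "turn_series_set")
}

#' @export
print.turn_series_set <- function(x, ...) {
  cat("<turn_series_set> ", length(x), " series\n", sep = "")
  for (s in x) print(s)
  invisible(x)
}

#' Count fully-missing turns per conversation
#'
#' Diagnostic reported when backchannel turns are retained: the number of
#' turns whose every token is `NA` on every joined dimension (these are the
#' turns interpolation will replace).
#'
#' @param tokens a token table after [join_norms()].
#' @param dims dimensions considered; defaults to all joined dimensions.
#' @return Named integer vector, one entry per `event_id`.
#' @export
count_na_turns <- function(tokens, dims = attr(tokens, "dimensions")) {
  stopifnot(!is.null(dims), all(dims %in% names(tokens)))
  all_na_row <- Reduce(`&`, lapply(dims, function(d) is.na(tokens[[d]])))
  vapply(split(data.frame(turn = tokens$turn_index, na = all_na_row),
               tokens$event_id),
         function(g) sum(vapply(split(g$na, g$turn), all, logical(1))),
         integer(1))
}

#' Remove backchannel turns and merge their neighbours
#'
#' A backchannel turn is one whose every token carries `NA` on every joined
#' dimension (typically a pure-stopword response such as "oh yeah"). Such
#' turns are deleted; the adjacent same-speaker turns this exposes are
#' merged into one turn, and `turn_index` / `exchange_index` are recomputed.
#'
#' @param tokens a token table after [join_norms()].
#' @param dims dimensions considered; defaults to all joined dimensions.
#' @return The token table with backchannel turns removed and turns
#'   renumbered.
#' @export
drop_backchannel_turns <- function(tokens,
                                   dims = attr(tokens, "dimensions")) {
  stopifnot(!is.null(dims), all(dims %in% names(tokens)))
  all_na_row <- Reduce(`&`, lapply(dims, function(d) is.na(tokens[[d]])))
  keep <- logical(nrow(tokens))
  for (ev in unique(tokens$event_id)) {
    sel <- tokens$event_id == ev
    turn_all_na <- vapply(split(all_na_row[sel], tokens$turn_index[sel]),
                          all, logical(1))
    bad_turns <- as.integer(names(turn_all_na)[turn_all_na])
    keep[sel] <- !(tokens$turn_index[sel] %in% bad_turns)
  }
  out <- tokens[keep, , drop = FALSE]
  # renumber turns; adjacent same-speaker turns merge automatically because
  # the run-length rule sees one uninterrupted run
  ord <- order(match(out$event_id, unique(out$event_id)), out$row_order)
  out <- out[ord, , drop = FALSE]
  turn <- unlist(lapply(split(out$participant_id, factor(
    out$event_id, levels = unique(out$event_id))), run_length_index),
    use.names = FALSE)
  out$turn_index <- turn
  out$exchange_index <- as.integer(ceiling(turn / 2))
  rownames(out) <- NULL
  attr(out, "dimensions") <- dims
  attr(out, "cleaning_config") <- attr(tokens, "cleaning_config")
  class(out) <- unique(c("token_table", class(out)))
  out
}

# Linear fill of a numeric vector: leading/trailing NAs take the nearest
# observed value; interior NA runs are linearly interpolated between the
# flanking observed values (unit spacing on the slot index).
fill_vector <- function(x, flags = rep("observed", length(x))) {
  obs <- which(!is.na(x))
  if (length(obs) == 0L) {
    stop("cannot fill an all-NA series", call. = FALSE)
  }
  if (length(obs) == length(x)) return(list(values = x, flags = flags))
  out <- x
  for (i in seq_along(x)) {
    if (!is.na(x[i])) next
    if (i < obs[1]) {
      out[i] <- x[obs[1]]
      flags[i] <- "edge_filled"
    } else if (i > obs[length(obs)]) {
      out[i] <- x[obs[length(obs)]]
      flags[i] <- "edge_filled"
    } else {
      lo <- max(obs[obs < i])
      hi <- min(obs[obs > i])
      out[i] <- x[lo] + (x[hi] - x[lo]) * (i - lo) / (hi - lo)
      flags[i] <- "interpolated"
    }
  }
  list(values = out, flags = flags)
}

#' Fill missing slots of a turn series
#'
#' Leading and trailing `NA` slots are filled with the closest observed
#' value; interior `NA` runs are filled by linear interpolation between the
#' flanking observed values. Observed values are never modified, and fill
#' provenance is recorded per slot. Idempotent.
#'
#' @param series a `turn_series` (or a `turn_series_set`, filled
#'   element-wise).
#' @return The series with no remaining `NA` and updated fill flags.
#' @export
fill_missing <- function(series) {
  if (inherits(series, "turn_series_set")) {
    return(structure(lapply(series, fill_missing),
                     class = "turn_series_set"))
  }
  stopifnot(inherits(series, "turn_series"))
  fa <- fill_vector(series$values_a, series$fill_flags_a)
  fb <- fill_vector(series$values_b, series$fill_flags_b)
  series$values_a <- fa$values
  series$values_b <- fb$values
  series$fill_flags_a <- fa$flags
  series$fill_flags_b <- fb$flags
  series$filled <- TRUE
  series
}

#' Export a turn-series set as a long data frame
#'
#' @param series a `turn_series_set` or single `turn_series`.
#' @return Data frame: `event_id`, `dimension`, `speaker`, `exchange`,
#'   `value`, `fill_flag`.
#' @export
series_to_long <- function(series) {
  if (inherits(series, "turn_series")) series <- list(series)
  do.call(rbind, lapply(series, function(s) {
    n <- length(s$values_a)
    data.frame(
      event_id = s$event_id, dimension = s$dimension,
      speaker = rep(c(s$speaker_a, s$speaker_b), each = n),
      exchange = rep(seq_len(n), 2L),
      value = c(s$values_a, s$values_b),
      fill_flag = c(s$fill_flags_a, s$fill_flags_b),
      stringsAsFactors = FALSE)
  }))
}
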