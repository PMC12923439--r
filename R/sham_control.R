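# FNV-1a hash of a string, folded into [1, 2^31 - 2]; used so every
# conversation gets its own reproducible RNG stream and adding a
# conversation never changes another's permutation.
event_seed <- function(seed, event_id, sham_id = 1L) {
  h <- 2166136261
  for (code in utf8ToInt(as.character(event_id))) {
    h <- bitwXor(as.integer(h %% 2147483647), code)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 2654435761 + sham_id * 97) %%
               2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Generate sham (permutation) dyads
#'
#' Within each conversation, each speaker's sequence of turns is
#' independently permuted uniformly at random. Speaker identity per slot,
#' turn contents, and the alternation structure are preserved, but the
#' turn-to-turn continuity of the conversation is destroyed: sham dyads
#' retain each speaker's marginal word use (global similarity) while
#' removing turn-wise contingency, so alignment metrics computed on them
#' provide a null reference.
#'
#' With a seed, output is exactly reproducible; each conversation draws its
#' permutation from an independent stream derived from the master seed and
#' the `event_id`, so adding or removing conversations never changes another
#' conversation's permutation. A conversation with fewer than 2 turns per
#' speaker is returned unshuffled with a warning.
#'
#' @param x a `turn_series`, `turn_series_set`, or token table
#'   (data frame with `turn_index` assigned).
#' @param n_shams number of sham replicates (default 1).
#' @param seed optional integer master seed.
#' @param ... unused.
#' @return Same class as `x`. For `n_shams > 1`: a list of replicates for
#'   series input; row-bound replicates with a `sham_id` column for token
#'   tables. Sham series carry `sham = TRUE` and `sham_id`.
#' @export
generate_shams <- function(x, n_shams = 1L, seed = NULL, ...) {
  UseMethod("generate_shams")
}

#' @export
generate_shams.turn_series <- function(x, n_shams = 1L, seed = NULL, ...) {
  stopifnot(n_shams >= 1L)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  reps <- lapply(seq_len(n_shams), function(i) shuffle_series(x, seed, i))
  if (n_shams == 1L) reps[[1]] else reps
}

shuffle_series <- function(s, seed, sham_id) {
  n <- length(s$values_a)
  if (n < 2L) {
    warning("event '", s$event_id, "' has fewer than 2 turns per speaker; ",
            "returned unshuffled", call. = FALSE)
    perm_a <- perm_b <- seq_len(n)
  } else {
    perm_a <- with_seed(event_seed(seed, paste0(s$event_id, "/a"), sham_id),
                        sample.int(n))
    perm_b <- with_seed(event_seed(seed, paste0(s$event_id, "/b"), sham_id),
                        sample.int(n))
  }
  s$values_a <- s$values_a[perm_a]
  s$fill_flags_a <- s$fill_flags_a[perm_a]
  s$values_b <- s$values_b[perm_b]
  s$fill_flags_b <- s$fill_flags_b[perm_b]
  s$sham <- TRUE
  s$sham_id <- sham_id
  s
}

#' @export
generate_shams.turn_series_set <- function(x, n_shams = 1L, seed = NULL,
                                           ...) {
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  if (n_shams == 1L) {
    return(structure(lapply(x, generate_shams, n_shams = 1L, seed = seed),
                     class = "turn_series_set"))
  }
  lapply(seq_len(n_shams), function(i) {
    structure(lapply(x, shuffle_series, seed = seed, sham_id = i),
              class = "turn_series_set")
  })
}

#' @export
generate_shams.data.frame <- function(x, n_shams = 1L, seed = NULL, ...) {
  stopifnot(all(c("event_id", "participant_id", "turn_index", "row_order")
                %in% names(x)))
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1L)
  reps <- lapply(seq_len(n_shams), function(i) {
    out <- shuffle_token_table(x, seed, i)
    out$sham_id <- i
    out
  })
  res <- do.call(rbind, reps)
  rownames(res) <- NULL
  attr(res, "dimensions") <- attr(x, "dimensions")
  res
}

# Permute turn contents among each speaker's turn positions within an event.
shuffle_token_table <- function(tokens, seed, sham_id) {
  pieces <- lapply(unique(tokens$event_id), function(ev) {
    sub <- tokens[tokens$event_id == ev, , drop = FALSE]
    sub <- sub[order(sub$row_order), , drop = FALSE]
    turns <- sort(unique(sub$turn_index))
    spk_of <- vapply(turns, function(t)
      sub$participant_id[sub$turn_index == t][1], character(1))
    speakers <- unique(spk_of)
    if (min(table(spk_of)) < 2L) {
      warning("event '", ev, "' has fewer than 2 turns per speaker; ",
              "returned unshuffled", call. = FALSE)
      return(sub)
    }
    # source turn for each destination slot, per speaker
    src_of <- stats::setNames(turns, turns)
    for (si in seq_along(speakers)) {
      mine <- turns[spk_of == speakers[si]]
      perm <- with_seed(
        event_seed(seed, paste0(ev, "/", si), sham_id),
        sample(mine))
      src_of[as.character(mine)] <- perm
    }
    blocks <- lapply(turns, function(t) {
      blk <- sub[sub$turn_index == src_of[[as.character(t)]], , drop = FALSE]
      blk$turn_index <- t
      blk$exchange_index <- as.integer(ceiling(t / 2))
      blk
    })
    out <- do.call(rbind, blocks)
    out$row_order <- seq_len(nrow(out))
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}
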