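#' Descriptive analytics over raw and cleaned corpora
#'
#' Builds a near publication-ready table of corpus descriptives spanning the
#' raw and cleaned samples: corpus totals (conversation count, total raw and
#' clean tokens) and per-conversation measures summarized as mean / sd /
#' min / max across conversations — exchange count, raw and clean word
#' counts, cleaning retention rate, morphemes-per-word, letters-per-word,
#' mean log10 lexical frequency, words-per-turn (raw and clean), and
#' type-token ratio (raw and clean).
#'
#' Definitions: raw tokens are whitespace tokens of the normalized utterance
#' text (before stopword/lemma steps); clean tokens are rows with non-`NA`
#' `token_clean`; retention = clean / raw per conversation; TTR = distinct
#' types / tokens (raw on normalized surface forms, clean on `token_clean`);
#' morphemes-, letters-per-word and frequency are means of the lexicon's
#' corresponding dimensions over matched clean tokens; sd is the sample
#' standard deviation (n - 1).
#'
#' @param raw an utterance table (see [read_dyads()]).
#' @param clean a token table for the same conversations (see [tokenize()]).
#' @param lexicon a `norm_lexicon` supplying `morphemes`, `letters`,
#'   `freq_lg10` dimensions; rows for absent dimensions are `NA` with a
#'   warning.
#' @param morphemes_dim,letters_dim,frequency_dim lexicon dimension names
#'   for the word-level measures.
#' @return Data frame (class `corpus_analytics`) with columns `measure`,
#'   `mean`, `sd`, `min`, `max` (the three corpus totals carry the total in
#'   `mean` and `NA` elsewhere).
#' @export
describe_corpus <- function(raw, clean, lexicon = NULL,
                            morphemes_dim = "morphemes",
                            letters_dim = "letters",
                            frequency_dim = "freq_lg10") {
  events <- unique(raw$event_id)
  if (length(events) == 0L) stop("zero conversations", call. = FALSE)
  norm_text <- normalize_string(raw$text)
  if (any(!nzchar(norm_text))) {
    bad <- unique(raw$event_id[!nzchar(norm_text)])
    stop("utterance(s) empty after normalization in event(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  raw_tok_by_row <- vapply(strsplit(norm_text, " ", fixed = TRUE), length,
                           integer(1))
  raw_types <- lapply(split(norm_text, raw$event_id), function(tx)
    unlist(strsplit(tx, " ", fixed = TRUE)))

  per <- function(f) vapply(events, f, numeric(1))
  raw_count <- per(function(ev) sum(raw_tok_by_row[raw$event_id == ev]))
  clean_tok <- split(clean$token_clean, factor(clean$event_id,
                                               levels = events))
  clean_count <- vapply(clean_tok, function(v) sum(!is.na(v)), numeric(1))
  exchanges <- per(function(ev)
    max(raw$exchange_index[raw$event_id == ev]))
  turns <- per(function(ev) max(raw$turn_index[raw$event_id == ev]))
  retention <- clean_count / raw_count
  ttr_raw <- vapply(raw_types[events], function(v)
    length(unique(v)) / length(v), numeric(1))
  ttr_clean <- vapply(clean_tok, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) / length(v)
  }, numeric(1))

  lex_mean <- function(dim_name) {
    if (is.null(lexicon) ||
        !dim_name %in% attr(lexicon, "catalog")$dimension) {
      warning("lexicon lacks dimension '", dim_name,
              "'; measure reported as NA", call. = FALSE)
      return(rep(NA_real_, length(events)))
    }
    vals <- lexicon[[dim_name]][match(clean$token_clean, lexicon$headword)]
    vapply(split(vals, factor(clean$event_id, levels = events)),
           function(v) mean(v, na.rm = TRUE), numeric(1))
  }
  morph <- lex_mean(morphemes_dim)
  lett <- lex_mean(letters_dim)
  freq <- lex_mean(frequency_dim)

  total_row <- function(measure, value)
    data.frame(measure = measure, mean = value, sd = NA_real_,
               min = NA_real_, max = NA_real_, stringsAsFactors = FALSE)
  stat_row <- function(measure, v)
    data.frame(measure = measure, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)

  out <- rbind(
    total_row("Total number of conversations", length(events)),
    total_row("Token count all conversations (raw)", sum(raw_count)),
    total_row("Token count all conversations (post-cleaning)",
              sum(clean_count)),
    stat_row("Exchange count (by conversation)", exchanges),
    stat_row("Word count raw (by conversation)", raw_count),
    stat_row("Word count clean (by conversation)", clean_count),
    stat_row("Cleaning retention rate (by conversation)", retention),
    stat_row("Morphemes-per-word (by conversation)", morph),
    stat_row("Letters-per-word (by conversation)", lett),
    stat_row("Lexical frequency lg10 (by conversation)", freq),
    stat_row("Words-per-turn raw (by conversation)", raw_count / turns),
    stat_row("Words-per-turn clean (by conversation)", clean_count / turns),
    stat_row("Type-token ratio raw (by conversation)", ttr_raw),
    stat_row("Type-token ratio clean (by conversation)", ttr_clean))
  rownames(out) <- NULL
  class(out) <- c("corpus_analytics", "data.frame")
  out
}

#' @export
print.corpus_analytics <- function(x, digits = 2, ...) {
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = digits,
                                                  format = "f"))
  tab <- data.frame(Measure = x$measure, Mean = fmt(x$mean),
                    Stdev = fmt(x$sd), Min = fmt(x$min), Max = fmt(x$max))
  print(tab, right = FALSE, row.names = FALSE)
  invisible(x)
}

#' Render a corpus analytics table as markdown
#'
#' @param x a `corpus_analytics` table.
#' @param digits decimal places.
#' @return Character vector of markdown lines.
#' @export
analytics_markdown <- function(x, digits = 2) {
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = digits,
                                                  format = "f"))
  c("| Measure | Mean | Stdev | Min | Max |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s |", x$measure, fmt(x$mean),
            fmt(x$sd), fmt(x$min), fmt(x$max)))
}
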