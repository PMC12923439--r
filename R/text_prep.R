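#' Cleaning configuration for transcript preparation
#'
#' Bundles the cleaning options applied by [tokenize()] and downstream steps.
#' Between one and three norm dimensions may be analysed at once.
#'
#' @param dimensions character vector of 1-3 lexicon dimension names.
#' @param stopword_list one of `"none"`, `"minimal"`, `"default"`,
#'   `"strict"` (tiers nested by strictness), or a character vector giving a
#'   custom stopword list.
#' @param lemmatize map inflected forms to dictionary forms via the packaged
#'   static lemma table? Unknown forms pass through unchanged.
#' @param remove_backchanneling drop turns consisting entirely of stopwords
#'   and merge the flanking same-speaker turns (see
#'   [drop_backchannel_turns()])?
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(dimensions,
                            stopword_list = "default",
                            lemmatize = TRUE,
                            remove_backchanneling = FALSE) {
  if (length(dimensions) < 1L || length(dimensions) > 3L) {
    stop("between 1 and 3 dimensions must be selected, got ",
         length(dimensions), call. = FALSE)
  }
  stopifnot(is.logical(lemmatize), length(lemmatize) == 1L,
            is.logical(remove_backchanneling),
            length(remove_backchanneling) == 1L)
  if (is.character(stopword_list) && length(stopword_list) == 1L &&
      stopword_list %in% names(STOPWORD_TIERS)) {
    tier <- stopword_list
    words <- get_stopwords(stopword_list)
  } else if (is.character(stopword_list)) {
    tier <- "custom"
    words <- tolower(stopword_list)
  } else {
    stop("stopword_list must be a tier name (",
         paste(names(STOPWORD_TIERS), collapse = ", "),
         ") or a character vector", call. = FALSE)
  }
  structure(list(dimensions = as.character(dimensions),
                 stopword_tier = tier,
                 stopwords = words,
                 lemmatize = lemmatize,
                 remove_backchanneling = remove_backchanneling),
            class = "cleaning_config")
}

#' @export
print.cleaning_config <- function(x, ...) {
  cat("<cleaning_config>\n",
      " dimensions:   ", paste(x$dimensions, collapse = ", "), "\n",
      " stopwords:    ", x$stopword_tier, " (", length(x$stopwords),
      " entries)\n",
      " lemmatize:    ", x$lemmatize, "\n",
      " backchannels: ", if (x$remove_backchanneling) "removed" else
        "kept as NA", "\n", sep = "")
  invisible(x)
}

#' Normalize a raw utterance string
#'
#' Lowercases, maps typographic apostrophes to ASCII `'`, strips hidden
#' characters (zero-width and control codes), converts hyphens to spaces
#' (so hyphenated compounds split into their parts), removes every remaining
#' symbol other than letters, digits, apostrophes and whitespace, and
#' collapses runs of whitespace. Idempotent; the empty string maps to itself.
#'
#' @param text character vector of raw utterances.
#' @return Character vector of normalized utterances.
#' @export
normalize_string <- function(text) {
  x <- tolower(as.character(text))
  x[is.na(x)] <- ""
  # typographic apostrophes -> ASCII
  x <- gsub("[\u2018\u2019\u02bc\u00b4`]", "'", x, perl = TRUE)
  # zero-width / control characters
  x <- gsub("[\u200b\u200c\u200d\ufeff\u00ad]", "", x, perl = TRUE)
  x <- gsub("[[:cntrl:]]", " ", x, perl = TRUE)
  # hyphens separate compounds
  x <- gsub("[-\u2013\u2014]+", " ", x, perl = TRUE)
  # keep letters, digits, apostrophes, whitespace
  x <- gsub("[^a-z0-9' ]+", " ", x, perl = TRUE)
  # orphan apostrophes (not word-internal)
  x <- gsub("(^|\\s)'+|'+(\\s|$)", " ", x, perl = TRUE)
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Expand contractions token-wise
#'
#' Each whitespace token matching the packaged static contraction map is
#' replaced by its multi-word expansion (`don't` -> `do not`); tokens not in
#' the map are left unchanged. The map includes common apostrophe-less
#' variants (`dont`). Possessive `'s` on tokens not in the map is stripped.
#'
#' @param text character vector of normalized utterances.
#' @return Character vector with contractions expanded.
#' @export
expand_contractions <- function(text) {
  vapply(strsplit(text, " ", fixed = TRUE), function(tok) {
    paste(expand_token_vector(tok), collapse = " ")
  }, character(1))
}

expand_token_vector <- function(tok) {
  if (length(tok) == 0L) return(character(0))
  map <- contraction_map()
  out <- character(0)
  for (t in tok) {
    hit <- map[[t]]
    if (!is.null(hit)) {
      out <- c(out, hit)
    } else {
      # possessive 's stripped after contraction handling
      out <- c(out, sub("'s$", "", t))
    }
  }
  out[nzchar(out)]
}

.prep_cache <- new.env(parent = emptyenv())

read_resource_lines <- function(fname) {
  path <- system.file("extdata", fname, package = "dyadalign")
  if (path == "") path <- file.path("inst", "extdata", fname)  # pre-install
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

contraction_map <- function() {
  if (is.null(.prep_cache$contractions)) {
    lines <- read_resource_lines("contractions.tsv")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    map <- lapply(parts, function(p) strsplit(p[2], " ", fixed = TRUE)[[1]])
    names(map) <- vapply(parts, `[[`, character(1), 1L)
    .prep_cache$contractions <- map
  }
  .prep_cache$contractions
}

STOPWORD_TIERS <- c(none = NA, minimal = "stopwords_minimal.txt",
                    default = "stopwords_default.txt",
                    strict = "stopwords_strict.txt")

#' Retrieve a packaged stopword tier
#'
#' Tiers are nested by strictness: `none` (empty), `minimal` (articles and
#' fillers), `default` (adds determiners, adpositions, pronouns, auxiliaries,
#' modals, conjunctions, numerals 0-12, greetings), `strict` (adds degree
#' adverbs, light verbs, discourse markers). Multi-word entries (idioms,
#' greetings such as `"how is it going"`) are matched as phrases on the
#' expanded token stream.
#'
#' The published lists the tiers emulate are distributed externally; these
#' lists reproduce their described coverage, not their exact membership.
#'
#' @param tier tier name.
#' @return Character vector of stopword entries (lowercase; multi-word
#'   entries contain spaces).
#' @export
get_stopwords <- function(tier = c("default", "none", "minimal", "strict")) {
  tier <- match.arg(tier)
  if (tier == "none") return(character(0))
  key <- paste0("stop_", tier)
  if (is.null(.prep_cache[[key]])) {
    words <- read_resource_lines(STOPWORD_TIERS[[tier]])
    lower <- switch(tier, minimal = character(0),
                    default = get_stopwords("minimal"),
                    strict = get_stopwords("default"))
    .prep_cache[[key]] <- sort(unique(c(lower, tolower(words))))
  }
  .prep_cache[[key]]
}

lemma_map <- function() {
  if (is.null(.prep_cache$lemmas)) {
    lines <- read_resource_lines("lemmas.tsv")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    map <- vapply(parts, `[[`, character(1), 2L)
    names(map) <- vapply(parts, `[[`, character(1), 1L)
    .prep_cache$lemmas <- map
  }
  .prep_cache$lemmas
}

lemmatize_tokens <- function(tokens) {
  map <- lemma_map()
  hit <- map[tokens]
  ifelse(is.na(hit), tokens, unname(hit))
}

#' Tokenize an utterance table into a one-word-per-row token table
#'
#' Applies [normalize_string()] and [expand_contractions()], splits on
#' whitespace, optionally lemmatizes, and flags stopwords. Stopwords are
#' flagged, not dropped: `token_clean` is set to `NA` for them so that joined
#' norm values are missing row-wise, but the row (and hence the raw token
#' count) is preserved. Multi-word stopword idioms are matched on the
#' expanded token stream before lemmatization.
#'
#' @param table an utterance table (see [read_dyads()], [mark_turns()]).
#' @param config a [cleaning_config()].
#' @return A data frame (class `token_table`) with the utterance keys plus
#'   `token_raw`, `token_clean`, `is_stopword`.
#' @export
tokenize <- function(table, config) {
  stopifnot(inherits(config, "cleaning_config"),
            all(c("event_id", "participant_id", "turn_index",
                  "exchange_index", "row_order") %in% names(table)))
  stopset <- config$stopwords
  phrases <- strsplit(stopset[grepl(" ", stopset, fixed = TRUE)], " ",
                      fixed = TRUE)
  single <- stopset[!grepl(" ", stopset, fixed = TRUE)]

  rows <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    norm <- normalize_string(table$text[i])
    tok <- if (nzchar(norm)) strsplit(norm, " ", fixed = TRUE)[[1]] else
      character(0)
    tok <- expand_token_vector(tok)
    if (length(tok) == 0L) next
    phrase_hit <- flag_phrases(tok, phrases)
    lem <- if (config$lemmatize) lemmatize_tokens(tok) else tok
    is_stop <- phrase_hit | tok %in% single | lem %in% single
    rows[[i]] <- data.frame(
      event_id = table$event_id[i],
      participant_id = table$participant_id[i],
      row_order = table$row_order[i],
      turn_index = table$turn_index[i],
      exchange_index = table$exchange_index[i],
      token_raw = tok,
      token_clean = ifelse(is_stop, NA_character_, lem),
      is_stopword = is_stop,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows[!vapply(rows, is.null, logical(1))],
                          list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(event_id = character(0), participant_id = character(0),
                      row_order = integer(0), turn_index = integer(0),
                      exchange_index = integer(0), token_raw = character(0),
                      token_clean = character(0), is_stopword = logical(0),
                      stringsAsFactors = FALSE)
  }
  attr(out, "cleaning_config") <- config
  class(out) <- unique(c("token_table", class(out)))
  out
}

# TRUE for token positions covered by any multi-word stopword phrase
flag_phrases <- function(tok, phrases) {
  hit <- logical(length(tok))
  for (ph in phrases) {
    k <- length(ph)
    if (k > length(tok)) next
    for (s in seq_len(length(tok) - k + 1L)) {
      if (all(tok[s:(s + k - 1L)] == ph)) hit[s:(s + k - 1L)] <- TRUE
    }
  }
  hit
}

#' Cleaning retention rate per conversation
#'
#' Fraction of raw tokens that survive cleaning (i.e., are not stopwords) in
#' each conversation; always in `[0, 1]`.
#'
#' @param tokens a token table.
#' @return Named numeric vector, one entry per `event_id`.
#' @export
retention_rate <- function(tokens) {
  vapply(split(!is.na(tokens$token_clean), tokens$event_id), mean, numeric(1))
}
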