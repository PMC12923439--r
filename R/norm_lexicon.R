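#' Load a psycholinguistic norm lexicon from delimited text
#'
#' A lexicon is a lookup table mapping lowercase headwords to numeric norm
#' values on one or more dimensions (e.g., valence, concreteness, log10
#' lexical frequency). The file must have a header with a `headword` column
#' (the first column is used, with a warning, when no column is literally
#' named `headword`) and at least one numeric dimension column. Duplicate
#' headwords are collapsed to their first occurrence with a warning;
#' non-numeric cells in a dimension column become `NA` with a warning.
#'
#' @param path a CSV (or TSV, by extension) file path.
#' @return An object of class `norm_lexicon`: a data frame keyed by
#'   `headword` with a `catalog` attribute describing each dimension
#'   (observed range, missingness).
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  as_norm_lexicon(raw)
}

#' Build a norm lexicon from a data frame
#'
#' @param raw data frame with a `headword` column and numeric dimensions.
#' @return A `norm_lexicon`.
#' @export
as_norm_lexicon <- function(raw) {
  if (!"headword" %in% names(raw)) {
    if (ncol(raw) < 2L) stop("lexicon needs a headword column plus at least ",
                             "one dimension column", call. = FALSE)
    warning("no 'headword' column; using first column '", names(raw)[1],
            "' as headword", call. = FALSE)
    names(raw)[1] <- "headword"
  }
  raw$headword <- tolower(as.character(raw$headword))
  if (anyDuplicated(raw$headword)) {
    n_dup <- sum(duplicated(raw$headword))
    warning(n_dup, " duplicate headword(s) collapsed to first occurrence",
            call. = FALSE)
    raw <- raw[!duplicated(raw$headword), , drop = FALSE]
  }
  dims <- setdiff(names(raw), "headword")
  if (length(dims) == 0L) {
    stop("lexicon has zero dimension columns", call. = FALSE)
  }
  for (d in dims) {
    if (!is.numeric(raw[[d]])) {
      conv <- suppressWarnings(as.numeric(raw[[d]]))
      bad <- sum(is.na(conv) & !is.na(raw[[d]]) & raw[[d]] != "")
      if (bad > 0L) {
        warning(bad, " non-numeric cell(s) in dimension '", d,
                "' set to NA", call. = FALSE)
      }
      raw[[d]] <- conv
    }
  }
  rownames(raw) <- NULL
  catalog <- data.frame(
    dimension = dims,
    min = vapply(dims, function(d) suppressWarnings(
      min(raw[[d]], na.rm = TRUE)), numeric(1)),
    max = vapply(dims, function(d) suppressWarnings(
      max(raw[[d]], na.rm = TRUE)), numeric(1)),
    frac_na = vapply(dims, function(d) mean(is.na(raw[[d]])), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(raw, catalog = catalog,
            class = c("norm_lexicon", "data.frame"))
}

#' @export
print.norm_lexicon <- function(x, ...) {
  cat("<norm_lexicon> ", nrow(x), " headwords, ",
      nrow(attr(x, "catalog")), " dimensions\n", sep = "")
  print(attr(x, "catalog"))
  invisible(x)
}

#' Dimension catalog of a lexicon
#'
#' @param lexicon a `norm_lexicon`.
#' @return Data frame of dimension names with observed ranges and
#'   missingness.
#' @export
dimension_catalog <- function(lexicon) {
  stopifnot(inherits(lexicon, "norm_lexicon"))
  attr(lexicon, "catalog")
}

#' Join norm dimensions onto a token table
#'
#' Left-join semantics on `token_clean` (exact string match, no fuzzy
#' matching): every token row is preserved; stopword rows (`token_clean` is
#' `NA`) and rows whose token has no lexicon entry receive `NA` on every
#' selected dimension. Between 1 and 3 dimensions may be joined.
#'
#' @param tokens a token table from [tokenize()].
#' @param lexicon a `norm_lexicon`.
#' @param dims character vector of 1-3 dimension names present in the
#'   lexicon.
#' @return The token table with one numeric column per dimension appended.
#' @export
join_norms <- function(tokens, lexicon, dims) {
  stopifnot(inherits(lexicon, "norm_lexicon"))
  if (length(dims) < 1L || length(dims) > 3L) {
    stop("between 1 and 3 dimensions must be selected, got ", length(dims),
         call. = FALSE)
  }
  avail <- attr(lexicon, "catalog")$dimension
  unknown <- setdiff(dims, avail)
  if (length(unknown)) {
    stop("unknown dimension(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(avail, collapse = ", "), call. = FALSE)
  }
  idx <- match(tokens$token_clean, lexicon$headword)
  for (d in dims) {
    tokens[[d]] <- lexicon[[d]][idx]
  }
  attr(tokens, "dimensions") <- dims
  tokens
}

#' Per-conversation missingness report
#'
#' Fraction of token rows with a missing value on each joined dimension, per
#' conversation. Missingness comes from stopword removal and from tokens
#' absent from the lexicon; it should be reported alongside alignment
#' results.
#'
#' @param tokens a token table after [join_norms()].
#' @param dims dimensions to report; defaults to all joined dimensions.
#' @return Data frame: `event_id`, `dimension`, `n_tokens`, `frac_na`.
#' @export
missingness_report <- function(tokens, dims = attr(tokens, "dimensions")) {
  stopifnot(!is.null(dims), all(dims %in% names(tokens)))
  evs <- unique(tokens$event_id)
  grid <- expand.grid(event_id = evs, dimension = dims,
                      stringsAsFactors = FALSE)
  grid$n_tokens <- NA_integer_
  grid$frac_na <- NA_real_
  for (i in seq_len(nrow(grid))) {
    v <- tokens[[grid$dimension[i]]][tokens$event_id == grid$event_id[i]]
    grid$n_tokens[i] <- length(v)
    grid$frac_na[i] <- mean(is.na(v))
  }
  grid
}

# ---------------------------------------------------------------------------
# Synthetic fixture lexicon
# ---------------------------------------------------------------------------

fixture_words <- function() {
  list(
    concrete_nouns = c(
      "dog", "cat", "house", "tree", "flower", "bird", "fish", "horse",
      "water", "fire", "sun", "moon", "star", "rain", "snow", "wind",
      "mountain", "river", "ocean", "stone", "cloud", "storm", "beach",
      "forest", "field", "farm", "village", "home", "bed", "room", "wall",
      "floor", "roof", "box", "bag", "cup", "plate", "spoon", "clock",
      "phone", "computer", "paper", "pen", "key", "lock", "shoe", "hat",
      "coat", "picture", "table", "chair", "window", "door", "car", "train",
      "road", "bread", "milk", "coffee", "tea", "apple", "fruit", "hand",
      "face", "eye", "arm", "leg", "bone", "muscle", "hair", "skin",
      "blood", "tooth", "foot", "child", "baby", "book", "letter", "school",
      "garden", "kitchen", "street", "city", "ball", "gift", "knife",
      "sunshine", "rainbow", "puppy", "kitten"),
    person_nouns = c("mother", "father", "sister", "brother", "friend",
                     "teacher", "doctor", "family", "woman", "man"),
    abstract_nouns = c(
      "love", "hate", "fear", "anger", "joy", "peace", "war", "pain",
      "hope", "truth", "idea", "mind", "dream", "life", "death", "story",
      "song", "voice", "music", "word", "smile", "noise", "sound", "smell",
      "taste", "shadow", "silence", "reason", "problem", "question",
      "answer", "money", "job", "game", "morning", "night", "summer",
      "winter", "heart", "color", "dinner", "funeral", "murder", "heaven"),
    verbs = c(
      "walk", "jump", "swim", "run", "sing", "dance", "play", "talk",
      "speak", "listen", "hear", "watch", "read", "write", "learn", "teach",
      "help", "give", "find", "lose", "keep", "hold", "open", "close",
      "start", "stop", "build", "break", "eat", "drink", "cook", "clean",
      "wash", "drive", "travel", "visit", "meet", "leave", "stay", "return",
      "remember", "forget", "believe", "understand", "explain", "laugh",
      "cry", "shout", "whisper", "sleep", "die", "hurt", "heal", "live",
      "grow", "change", "feel", "stand", "sit", "paint", "touch", "fly"),
    pos_adjs = c("happy", "glad", "proud", "warm", "sweet", "fresh",
                 "bright", "beautiful", "wonderful", "pleasant", "gentle",
                 "nice", "good", "strong", "rich", "lovely", "delightful"),
    neg_adjs = c("sad", "angry", "afraid", "lonely", "tired", "hungry",
                 "bitter", "dark", "ugly", "cruel", "terrible", "horrible",
                 "bad", "weak", "poor", "sick", "awful"),
    neutral_adjs = c("cold", "hot", "cool", "soft", "hard", "heavy",
                     "loud", "quiet", "old", "young", "new", "big", "small",
                     "tall", "short", "long", "fast", "slow"))
}

# morpheme count heuristic: 1 + derivational suffix + compound membership
count_morphemes <- function(w) {
  compounds <- c(sunshine = 2L, rainbow = 2L)
  if (w %in% names(compounds)) return(unname(compounds[w]))
  suff <- c("ful", "ness", "tion", "able", "ible", "ous", "er", "or", "ly")
  1L + as.integer(any(vapply(suff, function(s)
    endsWith(w, s) && nchar(w) > nchar(s) + 2L, logical(1))))
}

#' Build the synthetic fixture lexicon
#'
#' Generates a small (~250 word) norm lexicon with deterministic,
#' **synthetic** values for five dimensions: `valence` (1-9; unpleasant to
#' pleasant), `concreteness` (1-5), `freq_lg10` (log10 corpus frequency,
#' roughly 1-6.5), `letters` (orthographic length, exact), `morphemes`
#' (heuristic morpheme count). Values are plausible in range and direction
#' (e.g., "happy" high valence, concrete nouns high concreteness, shorter
#' words more frequent) but are generated, not normed: they are for tests,
#' examples and simulations only, never for substantive analyses.
#'
#' The same table is shipped as `inst/extdata/lexicon_synthetic.csv`; the
#' generator and the file are byte-equivalent.
#'
#' @return A `norm_lexicon`.
#' @export
build_fixture_lexicon <- function() {
  wl <- fixture_words()
  words <- unlist(wl, use.names = FALSE)
  stopifnot(!anyDuplicated(words))
  grp <- rep(names(wl), lengths(wl))
  n <- length(words)

  # deterministic stream, independent of caller's RNG state
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(20260909L, kind = "Mersenne-Twister")

  valence_base <- c(concrete_nouns = 5.4, person_nouns = 6.2,
                    abstract_nouns = 5.0, verbs = 5.2, pos_adjs = 7.6,
                    neg_adjs = 2.4, neutral_adjs = 5.0)
  conc_base <- c(concrete_nouns = 4.6, person_nouns = 4.3,
                 abstract_nouns = 2.0, verbs = 3.2, pos_adjs = 1.9,
                 neg_adjs = 1.9, neutral_adjs = 3.0)
  valence <- clamp(valence_base[grp] + stats::rnorm(n, 0, 0.7), 1, 9)
  concreteness <- clamp(conc_base[grp] + stats::rnorm(n, 0, 0.35), 1, 5)
  # anchor a few words with strongly interpretable values
  anchors_v <- c(love = 8.7, happy = 8.5, sunshine = 8.2, joy = 8.6,
                 hate = 1.6, sad = 1.9, death = 1.4, murder = 1.2,
                 funeral = 1.8, war = 1.7, heaven = 8.1, puppy = 8.3,
                 fear = 2.2, anger = 2.0, pain = 1.9, peace = 7.8,
                 hope = 7.5, smile = 8.0)
  valence[match(names(anchors_v), words)] <- anchors_v
  anchors_c <- c(dog = 4.9, cat = 4.9, stone = 4.8, truth = 1.3,
                 idea = 1.4, hope = 1.6, love = 2.1)
  concreteness[match(names(anchors_c), words)] <- anchors_c
  freq <- clamp(6.2 - 0.45 * nchar(words) + stats::rnorm(n, 0, 0.4), 1, 6.5)

  lex <- data.frame(
    headword = words,
    valence = round(valence, 2),
    concreteness = round(concreteness, 2),
    freq_lg10 = round(freq, 2),
    letters = nchar(words),
    morphemes = vapply(words, count_morphemes, integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  lex <- lex[order(lex$headword), , drop = FALSE]
  rownames(lex) <- NULL
  as_norm_lexicon(lex)
}

#' Path to the shipped synthetic lexicon CSV
#' @return File path of `lexicon_synthetic.csv`.
#' @export
fixture_lexicon_path <- function() {
  p <- system.file("extdata", "lexicon_synthetic.csv", package = "dyadalign")
  if (p == "") p <- file.path("inst", "extdata", "lexicon_synthetic.csv")
  p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
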