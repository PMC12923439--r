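# Column names owned by the pipeline; metadata may not collide with them.
RESERVED_COLUMNS <- c("event_id", "participant_id", "text", "row_order",
                      "turn_index", "exchange_index")

#' Read a folder of dyadic conversation transcripts
#'
#' Scans `dir_path` for `.txt` and `.csv` transcript files, parses each into
#' speaker/utterance rows, concatenates all conversations into one ordered
#' utterance table, and annotates turns and exchanges. The filename (extension
#' stripped, stem kept verbatim) becomes the conversation identifier
#' `event_id`.
#'
#' CSV files must carry a header row containing `id_column` and `text_column`;
#' any further columns are carried along as metadata, aligned by row. TXT
#' files use one `"Speaker: utterance"` line per utterance with the first
#' colon as delimiter; lines without a colon are treated as continuations and
#' appended to the previous utterance.
#'
#' Files are decoded as UTF-8; on invalid bytes a latin1 fallback is tried and
#' the decision is recorded in the attached read log (attribute `"read_log"`).
#' Undecodable files, duplicate file stems, and missing required columns are
#' errors naming the offending file.
#'
#' @param dir_path directory containing one transcript file per conversation.
#' @param id_column name of the speaker-identifier column in CSV files.
#' @param text_column name of the utterance-text column in CSV files.
#' @return A data frame (class `utterance_table`) with columns `event_id`,
#'   `participant_id`, `text`, `row_order`, `turn_index`, `exchange_index`,
#'   plus any metadata columns.
#' @export
read_dyads <- function(dir_path, id_column = "participant_id",
                       text_column = "text") {
  if (!dir.exists(dir_path)) {
    stop("directory not found: ", dir_path, call. = FALSE)
  }
  files <- list.files(dir_path, pattern = "\\.(txt|csv)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) {
    stop("no transcripts found in ", dir_path, call. = FALSE)
  }
  stems <- tools::file_path_sans_ext(basename(files))
  if (anyDuplicated(stems)) {
    dups <- unique(stems[duplicated(stems)])
    stop("duplicate transcript filenames (same stem, different extension): ",
         paste(dups, collapse = ", "), call. = FALSE)
  }

  log <- list()
  parts <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    dec <- read_text_file(f)
    log[[length(log) + 1L]] <- list(step = "read", file = basename(f),
                                    encoding = dec$encoding)
    tab <- if (grepl("\\.csv$", f, ignore.case = TRUE)) {
      parse_csv_transcript(dec$lines, basename(f), id_column, text_column)
    } else {
      parse_txt_transcript(dec$lines, basename(f))
    }
    if (nrow(tab) == 0L) {
      stop("transcript contains no utterances: ", basename(f), call. = FALSE)
    }
    tab$event_id <- stems[i]
    tab$row_order <- seq_len(nrow(tab))
    parts[[i]] <- tab
  }

  out <- rbind_fill(parts)
  front <- c("event_id", "participant_id", "text", "row_order")
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  if (any(is.na(out$participant_id) | out$participant_id == "")) {
    stop("missing participant_id values after parsing", call. = FALSE)
  }
  out <- mark_turns(out)
  attr(out, "read_log") <- log
  out
}

# Decode a file as UTF-8, falling back to latin1; errors if undecodable.
read_text_file <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (all(validUTF8(lines))) {
    return(list(lines = lines, encoding = "UTF-8"))
  }
  raw_lines <- readLines(path, warn = FALSE)
  conv <- iconv(raw_lines, from = "latin1", to = "UTF-8")
  if (anyNA(conv)) {
    stop("undecodable character encoding in file: ", basename(path),
         call. = FALSE)
  }
  list(lines = conv, encoding = "latin1")
}

parse_csv_transcript <- function(lines, fname, id_column, text_column) {
  tab <- utils::read.csv(text = paste(lines, collapse = "\n"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_column, text_column)) {
    if (!col %in% names(tab)) {
      stop("file ", fname, " is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  names(tab)[names(tab) == id_column] <- "participant_id"
  names(tab)[names(tab) == text_column] <- "text"
  meta <- setdiff(names(tab), c("participant_id", "text"))
  clash <- intersect(meta, RESERVED_COLUMNS)
  if (length(clash)) {
    stop("file ", fname, " metadata column collides with reserved name: ",
         paste(clash, collapse = ", "), call. = FALSE)
  }
  tab$participant_id <- as.character(tab$participant_id)
  tab$text <- as.character(tab$text)
  tab
}

parse_txt_transcript <- function(lines, fname) {
  lines <- lines[trimws(lines) != ""]
  spk <- character(0)
  txt <- character(0)
  for (ln in lines) {
    pos <- regexpr(":", ln, fixed = TRUE)
    if (pos > 0L) {
      spk <- c(spk, trimws(substr(ln, 1L, pos - 1L)))
      txt <- c(txt, trimws(substr(ln, pos + 1L, nchar(ln))))
    } else {
      if (length(txt) == 0L) {
        stop("file ", fname, " starts with a line lacking a 'Speaker:' ",
             "delimiter", call. = FALSE)
      }
      # continuation line: belongs to the previous utterance
      txt[length(txt)] <- paste(txt[length(txt)], trimws(ln))
    }
  }
  data.frame(participant_id = spk, text = txt, stringsAsFactors = FALSE)
}

# rbind data frames with unequal metadata columns, filling with NA.
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (m in setdiff(cols, names(d))) d[[m]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, c(dfs, list(make.row.names = FALSE)))
}

#' Annotate turns and exchanges
#'
#' A turn is all language produced by one interlocutor until the other speaks:
#' `turn_index` starts at 1 within each conversation and increments at every
#' change of `participant_id`. An exchange is a back-and-forth over two
#' successive turns: `exchange_index = ceiling(turn_index / 2)`.
#'
#' @param table an utterance table grouped by `event_id`, ordered by
#'   `row_order` within event.
#' @return The table with `turn_index` and `exchange_index` (re)assigned.
#' @export
mark_turns <- function(table) {
  stopifnot(all(c("event_id", "participant_id") %in% names(table)))
  if ("row_order" %in% names(table)) {
    table <- table[order(match(table$event_id, unique(table$event_id)),
                         table$row_order), , drop = FALSE]
  }
  bad <- vapply(split(table$participant_id, table$event_id),
                function(p) length(unique(p)) != 2L, logical(1))
  if (any(bad)) {
    stop("not a dyad (need exactly 2 speakers): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  turn <- unlist(lapply(split(table$participant_id, factor(
    table$event_id, levels = unique(table$event_id))), run_length_index),
    use.names = FALSE)
  table$turn_index <- turn
  table$exchange_index <- as.integer(ceiling(turn / 2))
  rownames(table) <- NULL
  class(table) <- unique(c("utterance_table", class(table)))
  table
}

# 1-based index of the maximal same-value run each element belongs to
run_length_index <- function(x) {
  if (length(x) == 0L) return(integer(0))
  as.integer(cumsum(c(TRUE, x[-1] != x[-length(x)])))
}

#' Warn about short conversations
#'
#' Alignment indices are unstable on brief conversations; a warning is issued
#' for every conversation with fewer than `threshold` (default 50) turns.
#'
#' @param table an utterance table with `turn_index` assigned.
#' @param threshold minimum turn count not considered short.
#' @return Invisibly, a data frame with one row per short event
#'   (`event_id`, `turn_count`); zero rows when none are short.
#' @export
warn_short <- function(table, threshold = 50L) {
  stopifnot("turn_index" %in% names(table))
  counts <- vapply(split(table$turn_index, table$event_id), max, numeric(1))
  short <- counts < threshold
  res <- data.frame(event_id = names(counts)[short],
                    turn_count = as.integer(counts[short]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(res) > 0L) {
    warning("conversation(s) with fewer than ", threshold, " turns: ",
            paste0(res$event_id, " (", res$turn_count, ")", collapse = ", "),
            call. = FALSE)
  }
  invisible(res)
}

#' Write an utterance table back to per-conversation CSV files
#'
#' One `<event_id>.csv` per conversation, containing `participant_id`,
#' `text`, and metadata columns (turn bookkeeping columns are recomputed on
#' re-read, so they are not written).
#'
#' @param table an utterance table.
#' @param dir_path output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_dyads <- function(table, dir_path) {
  if (!dir.exists(dir_path)) dir.create(dir_path, recursive = TRUE)
  drop <- c("event_id", "row_order", "turn_index", "exchange_index")
  paths <- character(0)
  for (ev in unique(table$event_id)) {
    sub <- table[table$event_id == ev, , drop = FALSE]
    sub <- sub[order(sub$row_order), setdiff(names(sub), drop), drop = FALSE]
    p <- file.path(dir_path, paste0(ev, ".csv"))
    utils::write.csv(sub, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
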