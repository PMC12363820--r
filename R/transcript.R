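#' Construct a transcript
#'
#' A transcript is the timed word sequence of one narrative story: a tibble
#' with columns `word`, `onset`, `offset` (seconds from story start), carrying
#' the story identifier as an attribute. Word onsets must be strictly
#' increasing and every offset must be at least its onset.
#'
#' @param words Character vector of tokens (nonempty strings).
#' @param onset,offset Numeric vectors of word timings in seconds.
#' @param story_id Story identifier string.
#' @return A `qa_transcript` tibble with columns `word`, `onset`, `offset`.
#' @examples
#' transcript(c("the", "dog"), c(0, 0.2), c(0.2, 0.5), story_id = "toy")
#' @export
transcript <- function(words, onset, offset, story_id = "story") {
  out <- tibble::tibble(
    word = as.character(words),
    onset = as.numeric(onset),
    offset = as.numeric(offset)
  )
  attr(out, "story_id") <- as.character(story_id)[1]
  class(out) <- c("qa_transcript", class(out))
  validate_transcript(out)
}

#' Validate a transcript
#'
#' Checks the transcript invariants: nonempty tokens, strictly increasing
#' onsets, `offset >= onset` for every word, no missing values.
#'
#' @param x A `qa_transcript` (or a data frame with `word`, `onset`, `offset`).
#' @return `x` invisibly reclassed as `qa_transcript`, or an error.
#' @export
validate_transcript <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("word", "onset", "offset")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("transcript is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(x$word) || anyNA(x$onset) || anyNA(x$offset)) {
    stop("transcript contains missing values")
  }
  if (nrow(x) > 0) {
    if (any(!nzchar(trimws(x$word)))) stop("transcript contains empty tokens")
    if (any(diff(x$onset) <= 0)) {
      bad <- which(diff(x$onset) <= 0)[1] + 1L
      stop("word onsets must be strictly increasing (violation at word ", bad, ")")
    }
    if (any(x$offset < x$onset)) {
      bad <- which(x$offset < x$onset)[1]
      stop("offset earlier than onset at word ", bad)
    }
  }
  if (is.null(attr(x, "story_id"))) attr(x, "story_id") <- "story"
  if (!inherits(x, "qa_transcript")) class(x) <- c("qa_transcript", class(x))
  x
}

#' Story id of a transcript
#' @param x A `qa_transcript`.
#' @return The story identifier string.
#' @export
story_id <- function(x) attr(x, "story_id") %||% "story"

#' Read a word-timed transcript
#'
#' Reads a transcript from disk in one of two dialects:
#' * `"tsv"` — UTF-8, tab-separated with header `word<TAB>onset<TAB>offset`,
#'   times in seconds as decimals;
#' * `"textgrid"` — a Praat TextGrid; the words come from the interval tier
#'   named in `tier` (default `"words"`, falling back to the first interval
#'   tier).
#'
#' Rows whose token is empty or a silence marker (`sp`, `sil`, `{SL}`, `""`)
#' are dropped before validation.
#'
#' @param path Path to the transcript file.
#' @param dialect Either `"tsv"` or `"textgrid"`. Default guesses from the
#'   file extension.
#' @param story_id Story identifier; defaults to the file name without
#'   extension.
#' @param tier TextGrid tier name holding the word intervals.
#' @return A validated [transcript()].
#' @export
read_transcript <- function(path, dialect = c("auto", "tsv", "textgrid"),
                            story_id = NULL, tier = "words") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("transcript file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.textgrid$", tolower(path))) "textgrid" else "tsv"
  }
  sid <- story_id %||% sub("\\.[^.]*$", "", basename(path))
  raw <- if (dialect == "tsv") read_transcript_tsv(path) else read_textgrid_words(path, tier)
  silence <- c("", "sp", "sil", "{sl}", "{br}", "{ns}")
  keep <- !(tolower(trimws(raw$word)) %in% silence)
  transcript(raw$word[keep], raw$onset[keep], raw$offset[keep], story_id = sid)
}

read_transcript_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0) return(tibble::tibble(word = character(), onset = numeric(), offset = numeric()))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:3], c("word", "onset", "offset"))) {
    stop("transcript TSV must start with header 'word\\tonset\\toffset' (", path, ")")
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    stop("malformed transcript row at line ", which(nfield < 3)[1] + 1L, " of ", path)
  }
  onset <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  offset <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(onset) | is.na(offset))
  if (length(bad) > 0) {
    stop("malformed timing at line ", bad[1] + 1L, " of ", path)
  }
  tibble::tibble(word = vapply(parts, `[[`, "", 1L), onset = onset, offset = offset)
}

# Minimal Praat TextGrid reader (long or short text format) for one interval
# tier. Only the fields needed for word timing are parsed.
read_textgrid_words <- function(path, tier = "words") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  if (!grepl("ooTextFile", txt)) stop("not a Praat TextGrid: ", path)
  # split into tier blocks ("item [k]:" in long format)
  starts <- grep("item\\s*\\[\\d+\\]", lines)
  if (length(starts) == 0) stop("no tiers found in TextGrid: ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  pick <- NA_integer_
  first_interval <- NA_integer_
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:ends[k]]
    if (!any(grepl("IntervalTier", block))) next
    if (is.na(first_interval)) first_interval <- k
    nm <- sub('.*name\\s*=\\s*"([^"]*)".*', "\\1", grep("name\\s*=", block, value = TRUE)[1])
    if (identical(tolower(nm), tolower(tier))) { pick <- k; break }
  }
  if (is.na(pick)) pick <- first_interval
  if (is.na(pick)) stop("no interval tier in TextGrid: ", path)
  block <- lines[starts[pick]:ends[pick]]
  xmin <- as.numeric(sub(".*xmin\\s*=\\s*([-0-9.eE+]+).*", "\\1", grep("xmin\\s*=", block, value = TRUE)))
  xmax <- as.numeric(sub(".*xmax\\s*=\\s*([-0-9.eE+]+).*", "\\1", grep("xmax\\s*=", block, value = TRUE)))
  text <- sub('.*text\\s*=\\s*"([^"]*)".*', "\\1", grep("text\\s*=", block, value = TRUE))
  # first xmin/xmax pair describes the tier itself, the rest the intervals
  n <- length(text)
  if (length(xmin) == n + 1) { xmin <- xmin[-1]; xmax <- xmax[-1] }
  if (length(xmin) != n || length(xmax) != n) stop("malformed TextGrid intervals in ", path)
  tibble::tibble(word = text, onset = xmin, offset = xmax)
}

#' Write a transcript to TSV
#'
#' Writes the canonical tab-separated dialect read back by
#' [read_transcript()]: UTF-8 with header `word<TAB>onset<TAB>offset`.
#'
#' @param x A `qa_transcript`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript <- function(x, path) {
  x <- validate_transcript(x)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("word\tonset\toffset", con)
  if (nrow(x) > 0) {
    writeLines(sprintf("%s\t%.10g\t%.10g", x$word, x$onset, x$offset), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
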