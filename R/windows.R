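#' Slice a transcript into annotation windows
#'
#' Produces exactly one window per word (dense windowing), anchored at that
#' word's onset. Two modes:
#' * `"ngram"` — the window is the up-to-`n` most recent words ending at the
#'   anchor word (truncated at story start); `n = 10` gives the classic
#'   10-gram annotation unit used for fMRI features.
#' * `"time_context"` — the window holds every word whose onset is at least
#'   `anchor_onset - context` seconds, plus the anchor word itself;
#'   `context = 0` gives single-word windows. Used for the multi-timescale
#'   ECoG features (1.5 s and 3 s of context).
#'
#' @param t A [transcript()].
#' @param mode `"ngram"` or `"time_context"`.
#' @param n Window length in words (ngram mode), `n >= 1`.
#' @param context Context length in seconds (time_context mode), `>= 0`.
#' @return A `qa_windows` tibble with one row per word: `story_id`,
#'   `anchor_index`, `anchor_time` (onset of the final word), `first_index`,
#'   `text` (space-joined tokens).
#' @examples
#' t <- transcript(c("we", "climbed", "the", "mountain"),
#'                 c(0, .4, .8, 1.1), c(.3, .7, 1.0, 1.6))
#' make_windows(t, "ngram", n = 2)
#' @export
make_windows <- function(t, mode = c("ngram", "time_context"), n = 10, context = NULL) {
  mode <- match.arg(mode)
  t <- validate_transcript(t)
  W <- nrow(t)
  if (W == 0) {
    return(empty_windows(story_id(t)))
  }
  if (mode == "ngram") {
    if (is.null(n) || n < 1) stop("ngram mode needs n >= 1")
    first <- pmax(1L, seq_len(W) - as.integer(n) + 1L)
  } else {
    if (is.null(context) || context < 0) stop("time_context mode needs context >= 0")
    # first index whose onset >= anchor_onset - context
    first <- vapply(seq_len(W), function(i) {
      match(TRUE, t$onset >= t$onset[i] - context)
    }, integer(1))
  }
  text <- vapply(seq_len(W), function(i) paste(t$word[first[i]:i], collapse = " "), "")
  out <- tibble::tibble(
    story_id = story_id(t),
    anchor_index = seq_len(W),
    anchor_time = t$onset,
    first_index = first,
    text = text
  )
  class(out) <- c("qa_windows", class(out))
  out
}

empty_windows <- function(sid = "story") {
  out <- tibble::tibble(
    story_id = character(), anchor_index = integer(),
    anchor_time = numeric(), first_index = integer(), text = character()
  )
  class(out) <- c("qa_windows", class(out))
  out
}
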