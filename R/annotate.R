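#' Build a deterministic keyword annotator
#'
#' An annotator is a function `f(text, question)` returning a 0/1 answer,
#' carrying an `annotator_id` attribute; [annotate()] accepts any such
#' function. The keyword annotator answers yes when the window contains any
#' word of the question's lexicon. It is deterministic, so it doubles as the
#' reference annotator for synthetic corpora whose gold annotations are built
#' from the same lexicons.
#'
#' @param lexicons Named list: one character vector of trigger words per qid.
#'   Questions without a lexicon always answer 0.
#' @param case_fold Lower-case both window tokens and lexicon entries before
#'   matching (default `TRUE`).
#' @param id Annotator identifier used in the cache key.
#' @return A function of `(text, question_qid)` returning integers in `{0,1}`,
#'   vectorised over `text`, of class `qa_annotator`.
#' @export
keyword_annotator <- function(lexicons, case_fold = TRUE, id = "keyword-v1") {
  stopifnot(is.list(lexicons))
  lex <- lapply(lexicons, function(w) {
    w <- as.character(w)
    if (case_fold) tolower(w) else w
  })
  f <- function(text, qid) {
    words <- strsplit(if (case_fold) tolower(text) else text, "\\s+")
    trig <- lex[[qid]]
    if (is.null(trig)) return(rep(0L, length(text)))
    vapply(words, function(w) as.integer(any(w %in% trig)), integer(1))
  }
  structure(f, annotator_id = id, vectorized = TRUE, class = c("qa_annotator", "function"))
}

#' Annotation caches
#'
#' The annotation cache guarantees that an annotator is consulted at most
#' once per (annotator id, question, window text) key, making [annotate()]
#' idempotent and resumable. The key is the tuple itself; the store is
#' append-only. `annotation_cache()` makes an in-memory cache, optionally
#' persisted as a tab-separated file that is re-read on construction.
#'
#' @param path Optional path of a persistent TSV store (`key`, `answer`).
#' @return A `qa_annotation_cache` environment.
#' @export
annotation_cache <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  env$store <- store
  env$path <- path
  if (!is.null(path) && file.exists(path)) {
    rows <- readr::read_tsv(path, col_names = c("key", "answer"),
                            col_types = "ci", progress = FALSE)
    for (i in seq_len(nrow(rows))) assign(rows$key[i], rows$answer[i], envir = store)
  }
  class(env) <- "qa_annotation_cache"
  env
}

cache_key <- function(id, qtext, wtext) paste(id, qtext, wtext, sep = "\x1f")

cache_get <- function(cache, keys) {
  vapply(keys, function(k) {
    if (exists(k, envir = cache$store, inherits = FALSE)) {
      get(k, envir = cache$store)
    } else NA_integer_
  }, integer(1), USE.NAMES = FALSE)
}

cache_put <- function(cache, keys, answers) {
  for (i in seq_along(keys)) assign(keys[i], answers[i], envir = cache$store)
  if (!is.null(cache$path)) {
    con <- file(cache$path, open = "a", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(sprintf("%s\t%d", gsub("\t", " ", keys), answers), con)
  }
  invisible(cache)
}

#' Annotate windows with a question bank
#'
#' Answers every question of the bank for every window, producing the binary
#' annotation matrix that serves as the interpretable text embedding of the
#' stimulus. The cache is consulted before the annotator is called; answers
#' outside `{0, 1}` are an error naming the offending window and question.
#'
#' @param windows A `qa_windows` tibble from [make_windows()].
#' @param bank A [question_bank()].
#' @param annotator An annotator function (see [keyword_annotator()]). Called
#'   as `annotator(texts, qid)` when it carries a `vectorized` attribute,
#'   else once per `(window, question)` as `annotator(text, question_text)`.
#' @param cache Optional [annotation_cache()].
#' @return A `qa_annotation`: list with `values` (W x Q binary matrix, columns
#'   named by qid), `anchor_time`, `qids`, `story_id`, `annotator_id`.
#' @export
annotate <- function(windows, bank, annotator, cache = NULL) {
  stopifnot(inherits(windows, "qa_windows") || is.data.frame(windows))
  W <- nrow(windows)
  Q <- nrow(bank)
  id <- attr(annotator, "annotator_id") %||% "annotator"
  vals <- matrix(0L, nrow = W, ncol = Q, dimnames = list(NULL, bank$qid))
  for (j in seq_len(Q)) {
    keys <- cache_key(id, bank$text[j], windows$text)
    ans <- if (!is.null(cache)) cache_get(cache, keys) else rep(NA_integer_, W)
    todo <- which(is.na(ans))
    if (length(todo) > 0) {
      new_ans <- if (isTRUE(attr(annotator, "vectorized"))) {
        annotator(windows$text[todo], bank$qid[j])
      } else {
        vapply(todo, function(i) as.integer(annotator(windows$text[i], bank$text[j])), integer(1))
      }
      bad <- which(!(new_ans %in% c(0L, 1L)))
      if (length(bad) > 0) {
        stop("non-binary answer for window ", todo[bad[1]], ", question '", bank$qid[j], "'")
      }
      ans[todo] <- as.integer(new_ans)
      if (!is.null(cache)) cache_put(cache, keys[todo], ans[todo])
    }
    vals[, j] <- ans
  }
  new_annotation(vals, windows$anchor_time, bank$qid,
                 story_id = windows$story_id[1] %||% "story", annotator_id = id)
}

new_annotation <- function(values, anchor_time, qids, story_id = "story",
                           annotator_id = "annotator") {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (!all(values %in% c(0L, 1L))) stop("annotation values must be binary")
  if (length(anchor_time) != nrow(values)) stop("anchor_time length mismatch")
  if (is.unsorted(anchor_time)) stop("anchor times must be nondecreasing")
  if (length(qids) != ncol(values)) stop("qids length mismatch")
  colnames(values) <- qids
  structure(
    list(values = values, anchor_time = as.numeric(anchor_time),
         qids = as.character(qids), story_id = story_id,
         annotator_id = annotator_id),
    class = "qa_annotation"
  )
}

#' @export
print.qa_annotation <- function(x, ...) {
  cat("<qa_annotation> ", nrow(x$values), " windows x ", ncol(x$values),
      " questions (story '", x$story_id, "', annotator '", x$annotator_id, "')\n",
      sep = "")
  invisible(x)
}

#' @export
dim.qa_annotation <- function(x) dim(x$values)

#' Majority vote over an annotator ensemble
#'
#' Combines the annotation matrices of several annotators into one by
#' majority: an entry answers yes when the mean across annotators is at
#' least 0.5 (a tie answers yes).
#'
#' @param mats List of `qa_annotation` objects sharing shape, qids and
#'   anchor times.
#' @return A single binary `qa_annotation`.
#' @export
ensemble_vote <- function(mats) {
  stopifnot(length(mats) >= 1)
  ref <- mats[[1]]
  for (m in mats[-1]) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        !identical(m$qids, ref$qids) ||
        !isTRUE(all.equal(m$anchor_time, ref$anchor_time))) {
      stop("annotation matrices do not share shape, qids and anchor times")
    }
  }
  mean_mat <- Reduce(`+`, lapply(mats, function(m) m$values)) / length(mats)
  new_annotation((mean_mat >= 0.5) * 1L, ref$anchor_time, ref$qids,
                 story_id = ref$story_id,
                 annotator_id = paste0("ensemble(", length(mats), ")"))
}

#' Per-question agreement with gold annotations
#'
#' Fraction of windows on which an annotation matrix agrees with a gold
#' (reference) matrix, per question — the faithfulness of the annotator.
#'
#' @param A,gold `qa_annotation` objects of identical shape and qids.
#' @return A tibble with columns `qid`, `accuracy`, plus attribute
#'   `overall` (mean accuracy).
#' @export
annotator_faithfulness <- function(A, gold) {
  if (!identical(dim(A$values), dim(gold$values)) || !identical(A$qids, gold$qids)) {
    stop("annotation and gold matrices differ in shape or qids")
  }
  acc <- colMeans(A$values == gold$values)
  out <- tibble::tibble(qid = A$qids, accuracy = unname(acc))
  attr(out, "overall") <- mean(acc)
  out
}

#' Write / read an annotation matrix as TSV
#'
#' Plain-text round-trip format: columns `anchor_time` then one 0/1 column
#' per qid; story and annotator ids in a comment header.
#'
#' @param A A `qa_annotation`.
#' @param path File path.
#' @return `write_annotation`: `path` invisibly; `read_annotation`: a
#'   `qa_annotation`.
#' @export
write_annotation <- function(A, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# story=%s annotator=%s", A$story_id, A$annotator_id), con)
  writeLines(paste(c("anchor_time", A$qids), collapse = "\t"), con)
  body <- cbind(sprintf("%.10g", A$anchor_time),
                matrix(as.character(A$values), nrow = nrow(A$values)))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- lines[1]
  sid <- sub(".*story=(\\S+).*", "\\1", meta)
  aid <- sub(".*annotator=(\\S+).*", "\\1", meta)
  tab <- utils::read.delim(text = lines[-1], check.names = FALSE)
  new_annotation(as.matrix(tab[, -1, drop = FALSE]), tab$anchor_time,
                 colnames(tab)[-1], story_id = sid, annotator_id = aid)
}
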