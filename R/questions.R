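#' Construct a question bank
#'
#' A question bank is an ordered set of yes/no questions, each expressing a
#' qualitative theory of language selectivity (e.g. "Does the input mention a
#' specific location?"). The order is stable and defines the feature-column
#' order of every annotation matrix built from the bank.
#'
#' @param qid Character vector of unique question identifiers.
#' @param text Character vector of question texts. A question not ending in
#'   "?" raises a warning but is kept.
#' @param tags Optional character vector of free-form tags.
#' @return A `qa_question_bank` tibble with columns `qid`, `text` (and `tags`).
#' @examples
#' question_bank(c("q1", "q2"),
#'               c("Does the input mention time?", "Does the input include dialogue?"))
#' @export
question_bank <- function(qid, text, tags = NULL) {
  qid <- as.character(qid)
  text <- as.character(text)
  if (length(qid) != length(text)) stop("qid and text lengths differ")
  if (anyDuplicated(qid)) {
    stop("duplicate qid in question bank: ",
         paste(unique(qid[duplicated(qid)]), collapse = ", "))
  }
  no_q <- nzchar(text) & !endsWith(trimws(text), "?")
  if (any(no_q)) {
    warning(sum(no_q), " question(s) do not end in '?'; kept as-is")
  }
  out <- tibble::tibble(qid = qid, text = text)
  if (!is.null(tags)) out$tags <- as.character(tags)
  class(out) <- c("qa_question_bank", class(out))
  out
}

#' Read a question bank from JSON or CSV
#'
#' JSON files hold a list of objects with `qid` and `text` fields (optionally
#' `tags`); CSV files have `qid,text` columns. Question order in the file is
#' preserved; duplicate qids are an error.
#'
#' @param path Path to a `.json` or `.csv` file.
#' @return A [question_bank()].
#' @export
read_question_bank <- function(path) {
  if (!file.exists(path)) stop("question bank file not found: ", path)
  if (grepl("\\.json$", tolower(path))) {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(raw) == 0) return(question_bank(character(), character()))
    question_bank(raw$qid, raw$text, tags = raw$tags)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    if (nrow(raw) == 0) return(question_bank(character(), character()))
    if (!all(c("qid", "text") %in% names(raw))) {
      stop("question bank CSV needs qid,text columns: ", path)
    }
    question_bank(raw$qid, raw$text, tags = raw$tags)
  }
}

#' Write a question bank to JSON
#' @param bank A `qa_question_bank`.
#' @param path Output path ending in `.json`.
#' @return `path`, invisibly.
#' @export
write_question_bank <- function(bank, path) {
  jsonlite::write_json(as.data.frame(bank), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' The packaged 35-question bank
#'
#' Loads the compact 35-question set shipped with the package. The published
#' compact QA set is not available verbatim, so this bank is a synthetic
#' reconstruction: the handful of questions whose wording is public, filled
#' out with plausible questions in the same thematic categories (tactile
#' sensations, visuospatial information, numerical information, planning,
#' communication, abstract beliefs or values). It is suitable for exercising
#' the full pipeline and as a template for user banks.
#'
#' @return A [question_bank()] of 35 questions.
#' @export
qa35_bank <- function() {
  path <- system.file("extdata", "qa35_synthetic.json", package = "qaenc")
  if (!nzchar(path)) stop("packaged question bank not found; is qaenc installed?")
  read_question_bank(path)
}

#' Correlation matrix of question answers
#'
#' Pearson correlations between every pair of question columns of a binary
#' annotation matrix, the standard descriptive summary of how much the
#' questions overlap on a stimulus set. A constant column has undefined
#' correlation; such columns are flagged and their off-diagonal entries set
#' to 0 so the heatmap stays computable on degenerate data.
#'
#' @param A A `qa_annotation` (see [annotate()]) or a numeric matrix with one
#'   column per question.
#' @return A symmetric Q x Q matrix with unit diagonal, entries in `[-1, 1]`,
#'   with attribute `constant` marking all-constant columns.
#' @export
answer_correlation_matrix <- function(A) {
  vals <- if (inherits(A, "qa_annotation")) A$values else as.matrix(A)
  if (nrow(vals) < 2) stop("need at least 2 windows to correlate answers")
  sds <- apply(vals, 2, stats::sd)
  const <- sds == 0
  R <- suppressWarnings(stats::cor(vals))
  R[const, ] <- 0
  R[, const] <- 0
  diag(R) <- 1
  attr(R, "constant") <- const
  R
}

#' Heatmap of answer correlations
#'
#' @param R A correlation matrix from [answer_correlation_matrix()].
#' @return A ggplot object.
#' @export
plot_answer_correlations <- function(R) {
  qids <- colnames(R) %||% as.character(seq_len(ncol(R)))
  df <- tibble::tibble(
    q1 = factor(rep(qids, times = ncol(R)), levels = qids),
    q2 = factor(rep(qids, each = nrow(R)), levels = rev(qids)),
    r = as.vector(R)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q1, y = .data$q2, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1, vjust = 0.5))
}
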