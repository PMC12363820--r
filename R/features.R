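#' Feature matrix container
#'
#' A design matrix ready for encoding-model fitting: numeric values on a
#' regular time grid (fMRI TR grid) or on the word grid (ECoG), with one
#' label row per column. Labels carry at least `qid`; resampled-and-delayed
#' designs add `delay` (in samples), multi-timescale ECoG designs add
#' `timescale`.
#'
#' @param values Numeric T x F matrix, finite throughout.
#' @param labels Tibble with one row per column; must contain `qid`.
#' @param grid `"tr"` or `"word"`.
#' @param tr Sampling interval in seconds when `grid = "tr"`.
#' @return A `qa_features` object.
#' @export
feature_matrix <- function(values, labels, grid = c("tr", "word"), tr = NULL) {
  grid <- match.arg(grid)
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("feature matrix contains non-finite values")
  labels <- tibble::as_tibble(labels)
  if (nrow(labels) != ncol(values)) stop("one label row per feature column required")
  if (!"qid" %in% names(labels)) stop("labels need a qid column")
  key <- do.call(paste, c(labels, sep = "\x1f"))
  if (anyDuplicated(key)) stop("feature column labels must be unique")
  structure(list(values = values, labels = labels, grid = grid, tr = tr),
            class = "qa_features")
}

#' @export
print.qa_features <- function(x, ...) {
  cat("<qa_features> ", nrow(x$values), " samples x ", ncol(x$values),
      " features (", x$grid, " grid", if (!is.null(x$tr)) paste0(", TR=", x$tr, "s"),
      ")\n", sep = "")
  invisible(x)
}

#' @export
dim.qa_features <- function(x) dim(x$values)

lanczos_kernel <- function(dt, tr, a) {
  # low-pass sinc windowed by a lobes, cutoff at the output Nyquist 1/(2*tr)
  x <- dt / tr
  k <- ifelse(abs(x) < 1e-12, 1,
              a * sin(pi * x) * sin(pi * x / a) / (pi^2 * x^2))
  k[abs(x) >= a] <- 0
  k
}

#' Resample word-rate annotations to the scan grid
#'
#' Converts a binary word-rate annotation matrix to a smooth feature
#' timecourse on the TR grid with a Lanczos kernel: output sample `i`
#' (time `i * tr`, `i = 0 .. n_tr-1`) is a kernel-weighted sum of the word
#' values near that time, with the weights normalised to sum to one, so a
#' constant input column stays constant.
#'
#' @param A A `qa_annotation` (or `qa_features` on a word grid).
#' @param tr Repetition time in seconds (> 0).
#' @param n_tr Number of output samples.
#' @param a Number of kernel lobes (default 3).
#' @return A `qa_features` on the TR grid with one column per question
#'   (`delay = 0`).
#' @export
lanczos_downsample <- function(A, tr, n_tr, a = 3) {
  if (tr <= 0) stop("tr must be positive")
  if (inherits(A, "qa_annotation")) {
    times <- A$anchor_time
    vals <- A$values
    labels <- tibble::tibble(qid = A$qids, delay = 0L)
  } else if (inherits(A, "qa_features")) {
    stopifnot(A$grid == "word")
    times <- attr(A$values, "times") %||% stop("word-grid features need times")
    vals <- A$values
    labels <- A$labels
  } else stop("A must be a qa_annotation or word-grid qa_features")
  span <- n_tr * tr
  inside <- times >= 0 & times < span
  if (!any(inside)) stop("no words inside the scan grid span [0, ", span, ")")
  grid_t <- (seq_len(n_tr) - 1) * tr
  # weight matrix n_tr x W; rows normalised to unit sum
  Wmat <- outer(grid_t, times, function(g, w) lanczos_kernel(g - w, tr, a))
  rs <- rowSums(Wmat)
  ok <- abs(rs) > 1e-10
  Wmat[ok, ] <- Wmat[ok, , drop = FALSE] / rs[ok]
  Wmat[!ok, ] <- 0
  out <- Wmat %*% vals
  colnames(out) <- colnames(vals)
  feature_matrix(out, labels, grid = "tr", tr = tr)
}

#' Append finite-impulse-response delays
#'
#' Replaces each feature column by copies shifted 1, 2, ... samples into the
#' past, letting a linear model absorb the hemodynamic lag without an
#' explicit response function. Column `(q, d)` at row `t` equals column `q`
#' at row `t - d`; rows before the story start are zero-filled. The default
#' delays 1-4 TRs (at TR = 2 s) span the hemodynamic peak.
#'
#' @param X A `qa_features` on the TR grid.
#' @param delays Positive integer delays in samples; must be nonempty.
#' @return A `qa_features` with `F * length(delays)` columns, delays-major
#'   within each original column.
#' @export
add_fir_delays <- function(X, delays = c(1L, 2L, 3L, 4L)) {
  stopifnot(inherits(X, "qa_features"))
  if (length(delays) == 0) stop("delay list must be nonempty")
  delays <- as.integer(delays)
  if (any(delays < 1)) stop("delays must be positive integers")
  T_ <- nrow(X$values)
  F_ <- ncol(X$values)
  pieces <- lapply(delays, function(d) {
    shifted <- matrix(0, nrow = T_, ncol = F_)
    if (d < T_) shifted[(d + 1):T_, ] <- X$values[1:(T_ - d), , drop = FALSE]
    shifted
  })
  # delays-major within each qid: order columns q1d1 q1d2 ... q2d1 ...
  out <- matrix(0, nrow = T_, ncol = F_ * length(delays))
  labels <- X$labels[rep(seq_len(F_), each = length(delays)), , drop = FALSE]
  labels$delay <- rep(delays, times = F_)
  for (j in seq_len(F_)) {
    for (k in seq_along(delays)) {
      out[, (j - 1) * length(delays) + k] <- pieces[[k]][, j]
    }
  }
  colnames(out) <- paste0(labels$qid, "_d", labels$delay)
  feature_matrix(out, labels, grid = X$grid, tr = X$tr)
}

#' Restrict a feature matrix to a set of questions
#'
#' Keeps the columns (all delays/timescales) of the given qids, preserving
#' original column order.
#'
#' @param X A `qa_features`.
#' @param qids Character vector of question ids; all must be present.
#' @return A `qa_features` with the restricted columns.
#' @export
restrict_features <- function(X, qids) {
  stopifnot(inherits(X, "qa_features"))
  unknown <- setdiff(qids, unique(X$labels$qid))
  if (length(unknown) > 0) stop("unknown qid(s): ", paste(unknown, collapse = ", "))
  keep <- which(X$labels$qid %in% qids)
  if (length(keep) == 0) stop("empty design after restriction")
  feature_matrix(X$values[, keep, drop = FALSE], X$labels[keep, , drop = FALSE],
                 grid = X$grid, tr = X$tr)
}
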