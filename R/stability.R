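#' Stability selection of questions
#'
#' Selects a compact, stable subset of questions from a large bank by
#' resampled sparse regression: on each of `B` chunk-respecting subsamples of
#' the rows, an L1-penalized (lasso) regression of each target on the design
#' is fit along a penalty path, and a question counts as selected in that fit
#' when any of its (delayed) columns has a nonzero coefficient. The selection
#' frequency of a question is the maximum over the penalty grid of the
#' fraction of subsample fits in which it was selected, averaged over
#' targets. Subsamples are complementary contiguous-chunk halves, the
#' time-series adaptation of half-sample stability selection.
#'
#' @param X A `qa_features` (delayed or not); delayed copies of one question
#'   count as a single selection unit.
#' @param Y Numeric T x V response matrix.
#' @param B Number of subsamples (rounded up to even; default 100).
#' @param frac Subsample fraction of rows (default 0.5; 0.5 uses
#'   complementary halves).
#' @param lambdas Lasso penalty grid shared by all fits. Default: 10
#'   log-spaced values from `lambda_max` (smallest penalty zeroing every
#'   coefficient on the full data) down to `0.2 * lambda_max`, the sparse
#'   region of the path.
#' @param target_k Select exactly this many questions (ranked by frequency,
#'   ties by mean absolute coefficient, then qid). If `NULL`, select all
#'   questions with `frequency >= threshold`.
#' @param threshold Frequency threshold when `target_k` is `NULL`
#'   (default 0.5).
#' @param chunk_len Chunk length in rows for the resampling (default 20).
#' @param targets Optional integer subset of target columns to pool over
#'   (default: all).
#' @param seed Integer seed; fixes the subsample stream.
#' @return A `qa_selection`: list with `frequency` (named, per question),
#'   `selected_qids` (ordered by the ranking), `threshold`, `mean_abs_weight`,
#'   `B`, `frac`, `lambdas`, `seed`.
#' @export
stability_select <- function(X, Y, B = 100, frac = 0.5, lambdas = NULL,
                             target_k = NULL, threshold = 0.5,
                             chunk_len = 20, targets = NULL, seed = 1) {
  stopifnot(inherits(X, "qa_features"))
  Y <- as.matrix(Y)
  if (nrow(X$values) != nrow(Y)) stop("X and Y row mismatch")
  if (B < 2) stop("need at least 2 subsamples")
  if (frac <= 0 || frac >= 1) stop("frac must be in (0, 1)")
  qids <- unique(X$labels$qid)
  Q <- length(qids)
  if (!is.null(target_k) && target_k > Q) stop("target_k exceeds number of questions")
  group <- match(X$labels$qid, qids)
  V <- ncol(Y)
  targets <- targets %||% seq_len(V)
  Xm <- X$values
  zero_cols <- apply(Xm, 2, function(col) all(col == 0))
  dead_q <- qids[unique(group[zero_cols])]
  dead_q <- setdiff(dead_q, qids[unique(group[!zero_cols])])
  if (length(dead_q) > 0) {
    warning("all-zero design for question(s): ", paste(dead_q, collapse = ", "))
  }
  if (is.null(lambdas)) {
    # grid over the sparse region of the path: from lambda_max down to the
    # larger of 0.2*lambda_max and the pure-noise entry scale, so that under
    # a null response the grid stays where selections are rare
    Xs <- scale(Xm); Xs[, !is.finite(colSums(Xs))] <- 0
    Yt <- Y[, targets, drop = FALSE]
    lam_max <- max(abs(crossprod(Xs, sweep(Yt, 2, colMeans(Yt))))) / nrow(Xm)
    if (!is.finite(lam_max) || lam_max <= 0) stop("degenerate design: cannot set a lambda grid")
    lam_noise <- mean(apply(Yt, 2, stats::sd)) *
      sqrt(log(max(2, ncol(Xm))) / max(2, floor(frac * nrow(Xm))))
    lam_min <- min(lam_max * 0.999, max(0.2 * lam_max, lam_noise))
    lambdas <- exp(seq(log(lam_max), log(lam_min), length.out = 10))
  }
  lambdas <- sort(as.numeric(lambdas), decreasing = TRUE)
  L <- length(lambdas)
  B <- 2L * ceiling(B / 2)
  chunks <- split(seq_len(nrow(Xm)), ceiling(seq_len(nrow(Xm)) / chunk_len))
  n_chunks <- length(chunks)
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  subsamples <- vector("list", B)
  if (isTRUE(all.equal(frac, 0.5))) {
    for (p in seq_len(B / 2)) {
      half <- sample(n_chunks, floor(n_chunks / 2))
      subsamples[[2 * p - 1]] <- sort(unlist(chunks[half], use.names = FALSE))
      subsamples[[2 * p]] <- sort(unlist(chunks[-half], use.names = FALSE))
    }
  } else {
    for (b in seq_len(B)) {
      take <- sample(n_chunks, max(1, round(frac * n_chunks)))
      subsamples[[b]] <- sort(unlist(chunks[take], use.names = FALSE))
    }
  }
  # counts[q, lambda]: number of (subsample, target) fits with q nonzero
  counts <- matrix(0, nrow = Q, ncol = L, dimnames = list(qids, NULL))
  abs_w <- numeric(Q)
  n_fits <- 0L
  for (b in seq_len(B)) {
    rows <- subsamples[[b]]
    Xb <- Xm[rows, , drop = FALSE]
    keep <- apply(Xb, 2, function(col) stats::sd(col) > 0)
    if (!any(keep)) next
    for (v in targets) {
      yb <- Y[rows, v]
      if (stats::sd(yb) == 0) next
      fit <- glmnet::glmnet(Xb[, keep, drop = FALSE], yb, alpha = 1,
                            lambda = lambdas, standardize = TRUE)
      beta <- as.matrix(fit$beta)  # kept-features x fitted-lambdas
      li <- match(signif(fit$lambda, 8), signif(lambdas, 8))
      nz <- beta != 0
      g <- group[keep]
      for (col in seq_along(fit$lambda)) {
        if (is.na(li[col])) next
        sel_q <- unique(g[nz[, col]])
        counts[sel_q, li[col]] <- counts[sel_q, li[col]] + 1
      }
      aw <- tapply(rowMeans(abs(beta)), g, mean)
      abs_w[as.integer(names(aw))] <- abs_w[as.integer(names(aw))] + aw
      n_fits <- n_fits + 1L
    }
  }
  if (n_fits == 0) stop("no valid stability-selection fits")
  # counts are pooled over (subsample, target) fits; frequency = max over
  # lambda of the pooled selection fraction (equals the target-mean of
  # per-target subsample fractions)
  freq <- apply(counts / n_fits, 1, max)
  names(freq) <- qids
  abs_w <- abs_w / n_fits
  names(abs_w) <- qids
  ord <- order(-freq, -abs_w, qids)
  if (!is.null(target_k)) {
    selected <- qids[ord[seq_len(target_k)]]
    threshold <- freq[selected[target_k]]
  } else {
    selected <- qids[ord][freq[qids[ord]] >= threshold]
  }
  structure(
    list(frequency = freq, selected_qids = selected,
         threshold = unname(threshold), mean_abs_weight = abs_w,
         B = B, frac = frac, lambdas = lambdas, seed = seed),
    class = "qa_selection"
  )
}

#' @export
print.qa_selection <- function(x, ...) {
  cat("<qa_selection> ", length(x$selected_qids), " of ", length(x$frequency),
      " questions selected (threshold ", round(x$threshold, 3), ", B = ", x$B,
      ")\n", sep = "")
  invisible(x)
}

#' Restrict a design to the selected questions
#'
#' Keeps the columns (all delays) of the selected questions, preserving the
#' original column order — the compact design of the reduced encoding model.
#'
#' @param X A `qa_features`.
#' @param sel A `qa_selection`.
#' @return A `qa_features` restricted to the selected questions.
#' @export
compact_design <- function(X, sel) {
  stopifnot(inherits(sel, "qa_selection"))
  if (length(sel$selected_qids) == 0) stop("empty design: no questions selected")
  restrict_features(X, sel$selected_qids)
}

#' Write / read a selection result as JSON
#' @param sel A `qa_selection`.
#' @param path File path.
#' @return `write_selection`: `path` invisibly; `read_selection`: a
#'   `qa_selection`.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(frequency = as.list(sel$frequency),
         selected_qids = sel$selected_qids,
         threshold = sel$threshold,
         mean_abs_weight = as.list(sel$mean_abs_weight),
         B = sel$B, frac = sel$frac, lambdas = sel$lambdas, seed = sel$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  raw <- jsonlite::fromJSON(path)
  structure(
    list(frequency = unlist(raw$frequency),
         selected_qids = raw$selected_qids,
         threshold = raw$threshold,
         mean_abs_weight = unlist(raw$mean_abs_weight),
         B = raw$B, frac = raw$frac, lambdas = raw$lambdas, seed = raw$seed),
    class = "qa_selection"
  )
}
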