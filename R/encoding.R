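#' Contiguous-chunk cross-validation folds
#'
#' Rows are grouped into contiguous chunks of `chunk_len` samples and chunks
#' are dealt round-robin to folds, so held-out data is never interleaved
#' sample-by-sample with training data. Narrative fMRI/ECoG timecourses are
#' strongly autocorrelated; row-wise shuffled CV would leak that
#' autocorrelation and inflate held-out estimates.
#'
#' @param n_rows Number of time samples.
#' @param chunk_len Chunk length in samples (default 20).
#' @param n_folds Number of folds (default 5).
#' @return Integer vector of fold ids, length `n_rows`.
#' @export
chunk_folds <- function(n_rows, chunk_len = 20, n_folds = 5) {
  chunk <- ceiling(seq_len(n_rows) / chunk_len)
  ((chunk - 1L) %% n_folds) + 1L
}

zstats <- function(M) {
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  degenerate <- !is.finite(sd) | sd == 0
  sd[degenerate] <- 1
  list(mu = mu, sd = sd, degenerate = degenerate)
}

zapply <- function(M, s) sweep(sweep(M, 2, s$mu, "-"), 2, s$sd, "/")

# Ridge solutions for all alphas from one SVD of the standardized design.
ridge_weights_svd <- function(sv, Ys, alpha) {
  d <- sv$d
  shrink <- d / (d^2 + alpha)
  sv$v %*% (shrink * crossprod(sv$u, Ys))
}

# columnwise Pearson correlation of two conformable matrices; degenerate
# columns (either side constant) get the sentinel 0
colwise_cor <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  a <- sweep(A, 2, colMeans(A))
  b <- sweep(B, 2, colMeans(B))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  r <- ifelse(den > 0, num / den, 0)
  attr(r, "valid") <- den > 0
  r
}

#' Fit per-target ridge encoding models with chunked cross-validation
#'
#' Fits one regularized linear model per target (voxel or electrode),
#' choosing each target's ridge penalty to maximize its mean held-out
#' Pearson correlation over contiguous-chunk CV folds, then refitting on all
#' rows at the chosen penalty. Design and response columns are z-scored with
#' training statistics only; weights are stored in standardized space
#' together with the scaling parameters, so [predict()] and
#' [score_predictions()] reproduce raw-scale predictions.
#'
#' @param X A `qa_features` or numeric T x F matrix.
#' @param Y Numeric T x V response matrix (same rows as `X`).
#' @param alphas Ridge penalty grid; default 10 log-spaced values in
#'   `[1, 1e4]`.
#' @param chunk_len,n_folds Chunked-CV layout (see [chunk_folds()]).
#' @param seed Unused by the deterministic fold layout; kept for interface
#'   stability.
#' @return A `qa_encoding` with elements `weights` (F x V, standardized
#'   space), `alpha` (length V), `cv_r` (length V held-out correlation at the
#'   chosen penalty), `x_stats`, `y_stats`, `labels`, `degenerate` (targets
#'   whose response was constant).
#' @export
fit_ridge_cv <- function(X, Y, alphas = 10^seq(0, 4, length.out = 10),
                         chunk_len = 20, n_folds = 5, seed = NULL) {
  labels <- if (inherits(X, "qa_features")) X$labels else NULL
  Xm <- if (inherits(X, "qa_features")) X$values else as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(Xm) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (anyNA(Xm) || anyNA(Y)) stop("NaN/NA in inputs")
  if (any(alphas <= 0)) stop("alphas must be positive")
  if (nrow(Xm) <= ncol(Xm)) {
    warning("fewer samples than features; ridge fit may be unstable")
  }
  V <- ncol(Y)
  folds <- chunk_folds(nrow(Xm), chunk_len, n_folds)
  n_alpha <- length(alphas)
  cv_r <- array(0, dim = c(n_alpha, V))
  used_folds <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (sum(tr) < 2 || sum(!tr) < 3) next
    xs <- zstats(Xm[tr, , drop = FALSE])
    ys <- zstats(Y[tr, , drop = FALSE])
    Xtr <- zapply(Xm[tr, , drop = FALSE], xs)
    Ytr <- zapply(Y[tr, , drop = FALSE], ys)
    Xte <- zapply(Xm[!tr, , drop = FALSE], xs)
    Yte <- Y[!tr, , drop = FALSE]
    sv <- svd(Xtr)
    for (ai in seq_len(n_alpha)) {
      W <- ridge_weights_svd(sv, Ytr, alphas[ai])
      cv_r[ai, ] <- cv_r[ai, ] + colwise_cor(Xte %*% W, Yte)
    }
    used_folds <- used_folds + 1L
  }
  if (used_folds == 0) stop("not enough rows for chunked cross-validation")
  cv_r <- cv_r / used_folds
  best <- apply(cv_r, 2, which.max)
  alpha <- alphas[best]
  # refit on all rows at each target's chosen alpha
  xs <- zstats(Xm)
  ys <- zstats(Y)
  Xs <- zapply(Xm, xs)
  Ys <- zapply(Y, ys)
  sv <- svd(Xs)
  W <- matrix(0, nrow = ncol(Xm), ncol = V)
  for (a in unique(best)) {
    cols <- which(best == a)
    W[, cols] <- ridge_weights_svd(sv, Ys[, cols, drop = FALSE], alphas[a])
  }
  rownames(W) <- colnames(Xm)
  structure(
    list(weights = W, alpha = alpha,
         cv_r = vapply(seq_len(V), function(v) cv_r[best[v], v], numeric(1)),
         x_stats = xs, y_stats = ys, labels = labels,
         degenerate = ys$degenerate, alphas = alphas),
    class = "qa_encoding"
  )
}

#' @export
print.qa_encoding <- function(x, ...) {
  cat("<qa_encoding> ", nrow(x$weights), " features x ", ncol(x$weights),
      " targets; mean held-out r = ", round(mean(x$cv_r), 4), "\n", sep = "")
  invisible(x)
}

#' Raw-scale coefficients of a fitted encoding model
#'
#' Maps the standardized-space ridge weights back to the scale of the
#' original design and responses; the attribute `intercept` completes the
#' affine prediction `Y ~ X %*% coef + intercept`.
#'
#' @param object A `qa_encoding`.
#' @param ... Unused.
#' @return F x V matrix of raw-scale weights with attribute `intercept`.
#' @export
coef.qa_encoding <- function(object, ...) {
  W <- sweep(sweep(object$weights, 2, object$y_stats$sd, "*"),
             1, object$x_stats$sd, "/")
  structure(W, intercept = object$y_stats$mu - drop(crossprod(W, object$x_stats$mu)))
}

#' Predict responses from a fitted encoding model
#' @param object A `qa_encoding`.
#' @param X New design (`qa_features` or matrix) with the training columns.
#' @param ... Unused.
#' @return Numeric matrix of raw-scale predictions.
#' @export
predict.qa_encoding <- function(object, X, ...) {
  Xm <- if (inherits(X, "qa_features")) X$values else as.matrix(X)
  if (ncol(Xm) != nrow(object$weights)) stop("design has wrong number of columns")
  P <- zapply(Xm, object$x_stats) %*% object$weights
  sweep(sweep(P, 2, object$y_stats$sd, "*"), 2, object$y_stats$mu, "+")
}

#' Score a model on held-out data
#'
#' Per-target Pearson correlation between predicted and observed held-out
#' responses — the standard encoding-model test statistic. Targets whose
#' prediction or observation is constant get the sentinel score 0 and are
#' flagged invalid.
#'
#' @param m A `qa_encoding`.
#' @param X_test Held-out design.
#' @param Y_test Held-out response matrix.
#' @return A `qa_scores`: list with `r` (length V), `valid` (logical), and
#'   `n_test`.
#' @export
score_predictions <- function(m, X_test, Y_test) {
  Y_test <- as.matrix(Y_test)
  P <- predict(m, X_test)
  if (nrow(P) != nrow(Y_test) || ncol(P) != ncol(Y_test)) {
    stop("prediction and observation shapes differ")
  }
  r <- colwise_cor(P, Y_test)
  structure(list(r = as.numeric(r), valid = attr(r, "valid"), n_test = nrow(Y_test)),
            class = "qa_scores")
}

#' @export
print.qa_scores <- function(x, ...) {
  cat("<qa_scores> ", length(x$r), " targets, n_test = ", x$n_test,
      ", mean r = ", round(mean(x$r), 4), "\n", sep = "")
  invisible(x)
}

#' Relative improvement of one model's scores over another's
#'
#' The percent improvement of mean test correlation,
#' `100 * (mean(r_a) - mean(r_b)) / mean(r_b)`, optionally restricted to a
#' target mask. The comparison is meaningless when the baseline mean is not
#' positive, which is an error.
#'
#' @param r_a,r_b `qa_scores` or numeric score vectors over the same targets.
#' @param mask Optional integer/logical target subset.
#' @return Percent improvement (scalar).
#' @export
relative_improvement <- function(r_a, r_b, mask = NULL) {
  a <- if (inherits(r_a, "qa_scores")) r_a$r else as.numeric(r_a)
  b <- if (inherits(r_b, "qa_scores")) r_b$r else as.numeric(r_b)
  if (length(a) != length(b)) stop("score vectors cover different targets")
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  mb <- mean(b)
  if (mb <= 0) {
    stop("baseline mean correlation is not positive (", signif(mb, 3),
         "); restrict to a mask where the baseline predicts")
  }
  100 * (mean(a) - mb) / mb
}
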