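#' Word-aligned multi-timescale QA features for ECoG
#'
#' ECoG's temporal resolution supports features at several contextual
#' timescales. The QA block annotates the transcript three times — single
#' words, 1.5 s of context, 3 s of context — and concatenates the binary
#' columns, so a Q-question bank yields `3 * Q` QA features (105 for a
#' 35-question bank). An optional spectral block (e.g. per-word mel-band
#' energies) is appended unchanged to capture low-level acoustics.
#'
#' @param t A [transcript()].
#' @param bank A [question_bank()].
#' @param annotator Annotator function (see [keyword_annotator()]).
#' @param spectral Optional numeric W x S matrix of per-word spectral
#'   features (rows = words).
#' @param timescales Numeric context lengths in seconds; 0 means single-word
#'   windows. Default `c(0, 1.5, 3)`.
#' @param cache Optional [annotation_cache()].
#' @return A `qa_features` on the word grid; labels carry `qid` and
#'   `timescale` (`"word"`, `"1.5s"`, ...; spectral columns get qid
#'   `"spectral_k"` and timescale `"spectral"`). Word onsets are kept in
#'   `attr(x$values, "times")`.
#' @export
build_multiscale_features <- function(t, bank, annotator, spectral = NULL,
                                      timescales = c(0, 1.5, 3), cache = NULL) {
  stopifnot(nrow(bank) >= 1)
  t <- validate_transcript(t)
  blocks <- list()
  labels <- list()
  for (ts in timescales) {
    wins <- if (ts == 0) make_windows(t, "ngram", n = 1) else {
      make_windows(t, "time_context", context = ts)
    }
    A <- annotate(wins, bank, annotator, cache = cache)
    tag <- if (ts == 0) "word" else paste0(format(ts, trim = TRUE), "s")
    blocks[[tag]] <- A$values
    labels[[tag]] <- tibble::tibble(qid = bank$qid, timescale = tag)
  }
  vals <- do.call(cbind, blocks)
  labs <- dplyr::bind_rows(labels)
  if (!is.null(spectral)) {
    spectral <- as.matrix(spectral)
    if (nrow(spectral) != nrow(t)) stop("spectral block must have one row per word")
    vals <- cbind(vals, spectral)
    labs <- dplyr::bind_rows(labs, tibble::tibble(
      qid = paste0("spectral_", seq_len(ncol(spectral))), timescale = "spectral"))
  }
  colnames(vals) <- paste0(labs$qid, "_", labs$timescale)
  attr(vals, "times") <- t$onset
  feature_matrix(vals, labs, grid = "word")
}

#' Fit per-lag encoding models around word onset
#'
#' Fits one cross-validated ridge model per lag of the response grid,
#' predicting the high-gamma value of every electrode at that lag relative
#' to word onset from the word-aligned features. Negative lags are
#' legitimate (contextual features carry predictive information before the
#' word is heard). Scores are the per-electrode held-out CV correlations at
#' each lag's chosen penalty.
#'
#' @param feat A word-grid `qa_features` (W rows).
#' @param resp Numeric W x L x E array of responses; `dimnames[[2]]` or the
#'   `lags` argument give the lag in milliseconds of each slice.
#' @param lags Numeric vector of lags (ms) matching `dim(resp)[2]`.
#' @param alphas,chunk_len,n_folds Passed to [fit_ridge_cv()].
#' @param seed Kept for interface stability.
#' @return A `qa_lagmodels`: list with `lags`, `models` (per lag),
#'   `scores` (L x E matrix of held-out correlations), `labels`.
#' @export
fit_lagged_models <- function(feat, resp, lags = NULL,
                              alphas = 10^seq(0, 4, length.out = 10),
                              chunk_len = 20, n_folds = 5, seed = NULL) {
  stopifnot(inherits(feat, "qa_features"))
  d <- dim(resp)
  if (length(d) != 3) stop("resp must be a word x lag x electrode array")
  if (d[1] != nrow(feat$values)) stop("resp rows must match feature rows")
  lags <- lags %||% as.numeric(dimnames(resp)[[2]])
  if (length(lags) != d[2]) stop("lag grid does not match the response array")
  models <- vector("list", d[2])
  scores <- matrix(NA_real_, nrow = d[2], ncol = d[3],
                   dimnames = list(lags, dimnames(resp)[[3]]))
  for (l in seq_len(d[2])) {
    Y <- resp[, l, , drop = TRUE]
    if (is.null(dim(Y))) Y <- matrix(Y, ncol = d[3])
    m <- fit_ridge_cv(feat, Y, alphas = alphas, chunk_len = chunk_len,
                      n_folds = n_folds, seed = seed)
    models[[l]] <- m
    scores[l, ] <- m$cv_r
  }
  structure(list(lags = lags, models = models, scores = scores,
                 labels = feat$labels),
            class = "qa_lagmodels")
}

#' @export
print.qa_lagmodels <- function(x, ...) {
  best <- best_lag(x)
  cat("<qa_lagmodels> ", length(x$lags), " lags x ", ncol(x$scores),
      " electrodes; best lag ", best, " ms (mean r = ",
      round(mean(x$scores[match(best, x$lags), ]), 4), ")\n", sep = "")
  invisible(x)
}

#' Best-performing lag of a lag-model set
#' @param m A `qa_lagmodels`.
#' @param electrodes Optional electrode subset over which to average.
#' @return The lag (ms) maximizing the mean held-out score.
#' @export
best_lag <- function(m, electrodes = NULL) {
  sc <- if (is.null(electrodes)) m$scores else m$scores[, electrodes, drop = FALSE]
  m$lags[which.max(rowMeans(sc))]
}

#' Select electrodes by minimum performance across models
#'
#' Keeps electrodes whose minimum held-out score across a set of encoding
#' models reaches the threshold — electrodes every model predicts.
#'
#' @param scores_by_model List of `qa_scores` (or numeric vectors) over the
#'   same electrodes.
#' @param threshold Minimum score.
#' @return Integer indices of the kept electrodes.
#' @export
select_electrodes_min_performance <- function(scores_by_model, threshold) {
  vecs <- lapply(scores_by_model, function(s) if (inherits(s, "qa_scores")) s$r else as.numeric(s))
  n <- unique(lengths(vecs))
  if (length(n) != 1) stop("model score sets cover different electrodes")
  mins <- do.call(pmin, vecs)
  which(mins >= threshold)
}

#' Cluster electrode weight profiles
#'
#' Groups electrodes by their question-weight profiles at the best lag:
#' weights are averaged over the timescale copies of each question, each
#' electrode's profile is z-scored, and Ward agglomerative clustering is cut
#' at `k` clusters. Deterministic given its input.
#'
#' @param m A `qa_lagmodels`, or a Q x E weight matrix already averaged over
#'   timescales.
#' @param k Number of clusters (`2 <= k <= E`).
#' @param electrodes Optional electrode subset (indices).
#' @param lag Lag to use; default the best-performing lag.
#' @return Integer cluster labels (length E or `length(electrodes)`), with
#'   the Q x E profile matrix in attribute `profiles`.
#' @export
cluster_electrode_weights <- function(m, k, electrodes = NULL, lag = NULL) {
  if (inherits(m, "qa_lagmodels")) {
    lag <- lag %||% best_lag(m, electrodes)
    model <- m$models[[match(lag, m$lags)]]
    qa_cols <- m$labels$timescale != "spectral"
    qids <- unique(m$labels$qid[qa_cols])
    prof <- t(vapply(qids, function(q) {
      rows <- which(m$labels$qid == q)
      colMeans(model$weights[rows, , drop = FALSE])
    }, numeric(ncol(model$weights))))
    rownames(prof) <- qids
  } else {
    prof <- as.matrix(m)
  }
  if (!is.null(electrodes)) prof <- prof[, electrodes, drop = FALSE]
  E <- ncol(prof)
  if (k < 2) stop("k must be at least 2")
  if (k > E) stop("k exceeds the number of electrodes")
  z <- apply(prof, 2, function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  attr(labels, "profiles") <- prof
  labels
}

#' Interpolate a vertex map to electrode locations
#'
#' Inverse-distance-weighted average of the `n_neighbors` nearest template
#' vertices, the standard proxy for comparing a surface (fMRI) map at
#' electrode coordinates. An electrode coincident with a vertex takes that
#' vertex's value exactly. The output is a convex combination, so it stays
#' within the range of the input values.
#'
#' @param vertex_values Numeric per-vertex map (length V) or Q x V matrix
#'   (one map per row).
#' @param vertex_coords V x 3 matrix of template coordinates.
#' @param electrode_coords E x 3 matrix (or an electrode table with
#'   `x`, `y`, `z` columns).
#' @param n_neighbors Number of nearest vertices (default 10).
#' @return Length-E vector, or Q x E matrix when `vertex_values` is a matrix.
#' @export
interpolate_fmri_to_electrodes <- function(vertex_values, vertex_coords,
                                           electrode_coords, n_neighbors = 10) {
  vertex_coords <- as.matrix(vertex_coords)
  if (is.data.frame(electrode_coords)) {
    electrode_coords <- as.matrix(electrode_coords[, c("x", "y", "z")])
  }
  electrode_coords <- as.matrix(electrode_coords)
  Vn <- nrow(vertex_coords)
  if (n_neighbors < 1) stop("n_neighbors must be >= 1")
  if (n_neighbors > Vn) {
    warning("fewer vertices than n_neighbors; using all ", Vn)
    n_neighbors <- Vn
  }
  one <- is.null(dim(vertex_values))
  M <- if (one) matrix(vertex_values, nrow = 1) else as.matrix(vertex_values)
  if (ncol(M) != Vn) stop("vertex map length does not match vertex_coords")
  E <- nrow(electrode_coords)
  out <- matrix(NA_real_, nrow = nrow(M), ncol = E)
  for (e in seq_len(E)) {
    d2 <- colSums((t(vertex_coords) - electrode_coords[e, ])^2)
    nn <- order(d2)[seq_len(n_neighbors)]
    dn <- sqrt(d2[nn])
    if (any(dn == 0)) {
      w <- as.numeric(dn == 0)
    } else {
      w <- 1 / dn
    }
    w <- w / sum(w)
    out[, e] <- M[, nn, drop = FALSE] %*% w
  }
  rownames(out) <- rownames(M)
  if (one) drop(out) else out
}

#' Cross-modality agreement between fMRI and ECoG selectivity maps
#'
#' For each question, correlates the ECoG electrode weights with the fMRI
#' vertex map interpolated to the electrode locations, over the best
#' `fraction` of electrodes by prediction score. Significance comes from a
#' paired permutation test: each draw permutes the electrode assignment of
#' the interpolated fMRI values (one shared permutation across questions,
#' preserving the paired structure), recomputes all correlations, and the
#' p-value is the add-one fraction of draws whose mean paired difference
#' (observed minus permuted) is non-positive.
#'
#' @param fmri_maps Q x V matrix of per-question vertex maps.
#' @param vertex_coords V x 3 template coordinates.
#' @param ecog_weights Q x E matrix of per-question electrode weights
#'   (timescale-averaged).
#' @param electrode_coords E x 3 coordinates (or table with x, y, z).
#' @param electrode_scores Length-E prediction scores used to pick the best
#'   fraction.
#' @param fraction Best-electrode fraction in `(0, 1]` (default 1).
#' @param n_neighbors Vertices per interpolation (default 10).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `r` (tibble `qid`, `r`), `p`, `n_electrodes`,
#'   `null_stats`.
#' @export
crossmodal_correlation_test <- function(fmri_maps, vertex_coords, ecog_weights,
                                        electrode_coords, electrode_scores,
                                        fraction = 1, n_neighbors = 10,
                                        n_perm = 1000, seed = 1) {
  fmri_maps <- as.matrix(fmri_maps)
  ecog_weights <- as.matrix(ecog_weights)
  if (nrow(fmri_maps) != nrow(ecog_weights)) {
    stop("fMRI and ECoG map sets must cover the same questions")
  }
  interp <- interpolate_fmri_to_electrodes(fmri_maps, vertex_coords,
                                           electrode_coords, n_neighbors)
  keep <- top_fraction_mask(electrode_scores, fraction)
  if (length(keep) < 3) stop("fewer than 3 electrodes after masking")
  A <- interp[, keep, drop = FALSE]
  B <- ecog_weights[, keep, drop = FALSE]
  Q <- nrow(A)
  obs <- vapply(seq_len(Q), function(q) as.numeric(map_correlation(B[q, ], A[q, ])),
                numeric(1))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  E <- length(keep)
  null_stats <- vapply(seq_len(n_perm), function(b) {
    perm <- sample.int(E)
    mean(obs - vapply(seq_len(Q), function(q) {
      as.numeric(map_correlation(B[q, ], A[q, perm]))
    }, numeric(1)))
  }, numeric(1))
  p <- (1 + sum(null_stats <= 0)) / (1 + n_perm)
  qids <- rownames(fmri_maps) %||% as.character(seq_len(Q))
  list(r = tibble::tibble(qid = qids, r = obs), p = p,
       n_electrodes = E, null_stats = null_stats)
}

#' Electrode table constructor
#'
#' @param electrode_id Unique electrode ids.
#' @param subject_id Subject of each electrode.
#' @param x,y,z Template-space coordinates (finite).
#' @param label Optional anatomical label.
#' @return A tibble with one row per electrode.
#' @export
electrode_table <- function(electrode_id, subject_id, x, y, z, label = NULL) {
  electrode_id <- as.character(electrode_id)
  if (anyDuplicated(electrode_id)) stop("electrode ids must be unique")
  if (!all(is.finite(c(x, y, z)))) stop("electrode coordinates must be finite")
  out <- tibble::tibble(electrode_id = electrode_id,
                        subject_id = as.character(subject_id),
                        x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!is.null(label)) out$label <- as.character(label)
  out
}
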