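#' Themed lexicons for a question bank
#'
#' One small trigger-word lexicon per question, disjoint from each other and
#' from the filler vocabulary, used both to sample synthetic corpora and to
#' build the matching [keyword_annotator()].
#'
#' @param bank A [question_bank()].
#' @param n_words Trigger words per question (default 3).
#' @return Named list of character vectors, one per qid.
#' @export
default_lexicons <- function(bank, n_words = 3) {
  stats::setNames(lapply(bank$qid, function(q) {
    sprintf("%s_term%d", q, seq_len(n_words))
  }), bank$qid)
}

filler_vocabulary <- function() {
  c("the", "a", "and", "then", "she", "he", "they", "we", "it", "was",
    "said", "went", "very", "quite", "later", "soon", "again", "still",
    "once", "slowly", "quietly", "morning", "evening", "after", "before",
    "while", "maybe", "really", "almost", "finally")
}

#' Generate a synthetic themed corpus with gold annotations
#'
#' Samples a word sequence in which each active question's lexicon words
#' appear at a rate calibrated so that the question is positive in a target
#' fraction of annotation windows; all other positions are filler words.
#' Gold window annotations are computed directly from the lexicons, so the
#' matching keyword annotator reproduces them exactly — the corpus is a
#' ground-truth fixture for every downstream module.
#'
#' @param bank A [question_bank()].
#' @param lexicons Per-qid trigger lexicons (default [default_lexicons()]);
#'   must be disjoint from the filler vocabulary.
#' @param n_words Corpus length in words.
#' @param word_rate Speech rate in words/second (default 2).
#' @param window_rate Target fraction of windows in which each active
#'   question is positive (default 0.1; the per-word trigger probabilities
#'   must sum below 0.9, which bounds feasible rates for large banks).
#' @param active_qids Questions allowed to occur (default: all); inactive
#'   questions get all-zero gold columns.
#' @param mode,n Windowing used for the gold annotations (default 10-grams).
#' @param seed Integer seed; with the configuration it fully determines the
#'   output.
#' @return List with `transcript`, `windows`, `gold` (a `qa_annotation`),
#'   `lexicons`, `annotator` (the matching keyword annotator).
#' @export
generate_synthetic_corpus <- function(bank, lexicons = NULL, n_words = 1000,
                                      word_rate = 2, window_rate = 0.1,
                                      active_qids = NULL, mode = "ngram",
                                      n = 10, seed = 1) {
  lexicons <- lexicons %||% default_lexicons(bank)
  active_qids <- active_qids %||% bank$qid
  fillers <- filler_vocabulary()
  lex_words <- unlist(lexicons, use.names = FALSE)
  if (any(lex_words %in% fillers)) stop("lexicons must be disjoint from filler vocabulary")
  empty <- active_qids[!vapply(active_qids, function(q) length(lexicons[[q]]) > 0, logical(1))]
  if (length(empty) > 0) stop("empty lexicon for active question(s): ",
                              paste(empty, collapse = ", "))
  eff_n <- if (identical(mode, "ngram")) n else max(1, round(1.5 * word_rate))
  p_word <- 1 - (1 - window_rate)^(1 / eff_n)
  p <- stats::setNames(rep(0, nrow(bank)), bank$qid)
  p[active_qids] <- p_word
  if (sum(p) > 0.9) {
    stop("infeasible window_rate: per-word trigger probabilities sum to ",
         round(sum(p), 2), "; lower window_rate or the number of active questions")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  probs <- c(p, filler = 1 - sum(p))
  choice <- sample.int(length(probs), n_words, replace = TRUE, prob = probs)
  words <- vapply(choice, function(k) {
    if (k > nrow(bank)) sample(fillers, 1) else sample(lexicons[[bank$qid[k]]], 1)
  }, "")
  onset <- (seq_len(n_words) - 1) / word_rate
  t <- transcript(words, onset, onset + 0.9 / word_rate,
                  story_id = paste0("synthetic_seed", seed))
  wins <- if (identical(mode, "ngram")) make_windows(t, "ngram", n = n) else {
    make_windows(t, "time_context", context = n)
  }
  toks <- strsplit(tolower(wins$text), "\\s+")
  gold_vals <- vapply(bank$qid, function(q) {
    trig <- tolower(lexicons[[q]])
    vapply(toks, function(w) as.integer(any(w %in% trig)), integer(1))
  }, integer(nrow(wins)))
  gold <- new_annotation(gold_vals, wins$anchor_time, bank$qid,
                         story_id = story_id(t), annotator_id = "gold")
  list(transcript = t, windows = wins, gold = gold, lexicons = lexicons,
       annotator = keyword_annotator(lexicons))
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities with peak at 5 s, undershoot at 15 s
#' and undershoot ratio 1/6, normalized to unit peak — a fixed reference
#' kernel for simulation and tests.
#'
#' @param t Time points in seconds.
#' @return HRF values at `t`.
#' @export
canonical_hrf <- function(t) {
  dg <- function(x) stats::dgamma(x, shape = 6, rate = 1) -
    stats::dgamma(x, shape = 16, rate = 1) / 6
  dg(t) / max(dg(seq(0, 30, by = 0.01)))
}

ar1_noise <- function(n, v, phi = 0.3) {
  # n x v matrix of AR(1) processes with unit marginal variance
  innov_sd <- sqrt(1 - phi^2)
  out <- matrix(stats::rnorm(n * v, sd = innov_sd), n, v)
  out[1, ] <- stats::rnorm(v)
  for (i in 2:n) out[i, ] <- phi * out[i - 1, ] + out[i, ]
  out
}

#' Synthetic ground truth for planted encoding structure
#'
#' Sparse planted weights over questions and targets plus a noise model: a
#' subset of questions is active, each with nonzero weights on a random
#' subset of targets.
#'
#' @param bank A [question_bank()].
#' @param n_targets Number of voxels/electrodes (default 200).
#' @param n_active Number of active questions (default 5).
#' @param support_frac Fraction of targets each active question drives
#'   (default 0.2).
#' @param ar1 AR(1) noise coefficient (default 0.3).
#' @param snr Signal-to-noise variance ratio (default 1).
#' @param seed Integer seed.
#' @return A `qa_ground_truth`: list with `weights` (Q x V), `active_qids`,
#'   `support` (per-question target indices), `ar1`, `snr`, `seed`.
#' @export
synthetic_ground_truth <- function(bank, n_targets = 200, n_active = 5,
                                   support_frac = 0.2, ar1 = 0.3, snr = 1,
                                   seed = 1) {
  if (snr <= 0) stop("SNR must be positive")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  Q <- nrow(bank)
  active <- sort(sample(bank$qid, n_active))
  W <- matrix(0, nrow = Q, ncol = n_targets, dimnames = list(bank$qid, NULL))
  support <- list()
  k <- max(1, round(support_frac * n_targets))
  for (q in active) {
    idx <- sort(sample.int(n_targets, k))
    W[q, idx] <- stats::rnorm(k, mean = 0, sd = 1) + sign(stats::rnorm(k))
    support[[q]] <- idx
  }
  structure(list(weights = W, active_qids = active, support = support,
                 ar1 = ar1, snr = snr, seed = seed),
            class = "qa_ground_truth")
}

#' Simulate BOLD responses from planted weights
#'
#' Downsamples the word-rate annotations to the scan grid, projects them
#' through the planted weights, convolves each target timecourse with the
#' canonical double-gamma HRF, and adds AR(1) Gaussian noise scaled per
#' target to the requested signal-to-noise variance ratio. At SNR `s` the
#' signal fraction is `s / (1 + s)`, so the attainable test correlation is
#' approximately `sqrt(s / (1 + s))`.
#'
#' @param gt A [synthetic_ground_truth()].
#' @param A Gold `qa_annotation` of the corpus.
#' @param tr Repetition time in seconds (default 2).
#' @param n_tr Number of scan samples.
#' @param snr Override of `gt$snr`; `Inf` gives noise-free responses.
#' @param seed Integer seed for the noise draw.
#' @return List with `Y` (T x V response matrix), `X_tr` (the downsampled
#'   question-level `qa_features`), `signal` (noise-free responses).
#' @export
simulate_bold_responses <- function(gt, A, tr = 2, n_tr, snr = gt$snr, seed = 1) {
  if (snr <= 0) stop("SNR must be positive")
  X_tr <- lanczos_downsample(A, tr = tr, n_tr = n_tr)
  S <- X_tr$values %*% gt$weights[X_tr$labels$qid, , drop = FALSE]
  h <- canonical_hrf(seq(0, 30, by = tr))
  signal <- apply(S, 2, function(s) {
    stats::convolve(s, rev(h), type = "open")[seq_len(n_tr)]
  })
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  noise <- ar1_noise(n_tr, ncol(signal), phi = gt$ar1)
  if (is.infinite(snr)) {
    Y <- signal
  } else {
    sd_sig <- apply(signal, 2, stats::sd)
    sd_noise <- ifelse(sd_sig > 0, sd_sig / sqrt(snr), 1)
    Y <- signal + sweep(noise, 2, sd_noise, "*")
  }
  list(Y = Y, X_tr = X_tr, signal = signal)
}

#' Simulate lagged ECoG responses from planted weights
#'
#' Builds a word x lag x electrode response array whose linear signal is
#' present only at the planted lag; every other lag (and the planted lag's
#' residual) is Gaussian noise matched in scale. Per-electrode SNR can be
#' graded to support analyses that rank electrodes by prediction quality.
#'
#' @param gt A [synthetic_ground_truth()] (its weights index the feature
#'   questions; timescale copies of a question share the question weight).
#' @param feat A word-grid `qa_features` from [build_multiscale_features()].
#' @param lags Lag grid in milliseconds.
#' @param planted_lag The lag (ms) carrying the signal; must be in `lags`.
#' @param snr Scalar or per-electrode vector of SNRs (default `gt$snr`).
#' @param seed Integer seed.
#' @return Numeric W x L x E array with lag dimnames.
#' @export
simulate_ecog_responses <- function(gt, feat, lags, planted_lag, snr = gt$snr,
                                    seed = 1) {
  if (!planted_lag %in% lags) stop("planted_lag must be one of the lag grid values")
  qrows <- match(feat$labels$qid, rownames(gt$weights))
  if (anyNA(qrows)) {
    # columns without a planted question (e.g. spectral) contribute nothing
    Wfeat <- matrix(0, nrow = ncol(feat$values), ncol = ncol(gt$weights))
    Wfeat[!is.na(qrows), ] <- gt$weights[qrows[!is.na(qrows)], , drop = FALSE]
  } else {
    Wfeat <- gt$weights[qrows, , drop = FALSE]
  }
  n_ts <- length(unique(feat$labels$timescale[feat$labels$timescale != "spectral"]))
  Wfeat <- Wfeat / max(1, n_ts)
  signal <- feat$values %*% Wfeat
  E <- ncol(signal)
  snr <- rep_len(snr, E)
  if (any(snr <= 0)) stop("SNR must be positive")
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  W <- nrow(signal)
  L <- length(lags)
  out <- array(0, dim = c(W, L, E), dimnames = list(NULL, lags, colnames(signal)))
  sd_sig <- apply(signal, 2, stats::sd)
  scale_sd <- ifelse(sd_sig > 0, sd_sig / sqrt(snr), 1)
  for (l in seq_len(L)) {
    noise <- matrix(stats::rnorm(W * E), W, E)
    noise <- sweep(noise, 2, scale_sd, "*")
    out[, l, ] <- if (lags[l] == planted_lag) signal + noise else noise
  }
  out
}
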