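test_that("multiscale QA features have 3 columns per question", {
  bank1 <- tiny_bank(1)
  corp <- generate_synthetic_corpus(bank1, n_words = 40, window_rate = 0.3, seed = 1)
  f1 <- build_multiscale_features(corp$transcript, bank1, corp$annotator)
  expect_equal(ncol(f1$values), 3)

  bank5 <- tiny_bank(5)
  corp5 <- generate_synthetic_corpus(bank5, n_words = 40, window_rate = 0.1, seed = 1)
  f5 <- build_multiscale_features(corp5$transcript, bank5, corp5$annotator)
  expect_equal(ncol(f5$values), 15)
  expect_equal(sum(f5$labels$timescale == "word"), 5)

  # the word-level block equals the 1-gram annotation column
  A1 <- annotate(make_windows(corp5$transcript, "ngram", n = 1), bank5, corp5$annotator)
  expect_equal(unname(f5$values[, f5$labels$timescale == "word"]),
               unname(A1$values) + 0)

  # spectral block is appended unchanged
  spec <- matrix(rnorm(nrow(corp5$transcript) * 4), ncol = 4)
  fs <- build_multiscale_features(corp5$transcript, bank5, corp5$annotator,
                                  spectral = spec)
  expect_equal(ncol(fs$values), 19)
  expect_equal(unname(fs$values[, fs$labels$timescale == "spectral"]), unname(spec))
  expect_error(build_multiscale_features(corp5$transcript, bank5, corp5$annotator,
                                         spectral = spec[1:3, ]),
               "one row per word")
})

test_that("lagged models peak at the planted lag and flatten on noise", {
  bank <- tiny_bank(4)
  corp <- generate_synthetic_corpus(bank, n_words = 400, window_rate = 0.15, seed = 2)
  feat <- build_multiscale_features(corp$transcript, bank, corp$annotator)
  gt <- synthetic_ground_truth(bank, n_targets = 8, n_active = 3,
                               support_frac = 0.5, seed = 2)
  lags <- seq(-300, 300, by = 150)
  resp <- simulate_ecog_responses(gt, feat, lags, planted_lag = 150, snr = 3, seed = 2)
  lm_ <- fit_lagged_models(feat, resp, lags, alphas = c(1, 100))
  expect_equal(best_lag(lm_), 150)

  gt0 <- gt; gt0$weights[] <- 0
  resp0 <- simulate_ecog_responses(gt0, feat, lags, planted_lag = 150, seed = 3)
  lm0 <- fit_lagged_models(feat, resp0, lags, alphas = c(1, 100))
  expect_lt(max(abs(rowMeans(lm0$scores))), 0.1)

  expect_error(simulate_ecog_responses(gt, feat, lags, planted_lag = 999),
               "lag grid")
})

test_that("lagged-model scores ignore per-electrode affine response rescaling", {
  bank <- tiny_bank(3)
  corp <- generate_synthetic_corpus(bank, n_words = 200, window_rate = 0.2, seed = 4)
  feat <- build_multiscale_features(corp$transcript, bank, corp$annotator)
  gt <- synthetic_ground_truth(bank, n_targets = 4, n_active = 2,
                               support_frac = 0.6, seed = 4)
  lags <- c(-100, 0, 100)
  resp <- simulate_ecog_responses(gt, feat, lags, planted_lag = 0, snr = 2, seed = 4)
  resp2 <- resp
  for (e in 1:4) resp2[, , e] <- resp[, , e] * (e + 1) + 5 * e
  s1 <- fit_lagged_models(feat, resp, lags, alphas = c(1, 100))$scores
  s2 <- fit_lagged_models(feat, resp2, lags, alphas = c(1, 100))$scores
  expect_equal(s1, s2, tolerance = 1e-8)
})

test_that("electrode selection thresholds the minimum score across models", {
  scores <- list(c(0.3, 0.1, 0.25), c(0.2, 0.3, 0.25), c(0.25, 0.3, 0.25))
  expect_equal(select_electrodes_min_performance(scores, 0.2), c(1, 3))
  expect_equal(select_electrodes_min_performance(scores, -1), 1:3)
  expect_error(select_electrodes_min_performance(list(1:3, 1:4), 0),
               "different electrodes")
})

test_that("Ward clustering recovers planted electrode profiles", {
  set.seed(5)
  # 5 planted profiles over 25 electrodes, 8 questions
  centers <- matrix(rnorm(8 * 5, sd = 3), 8, 5)
  truth <- rep(1:5, each = 5)
  prof <- centers[, truth] + matrix(rnorm(8 * 25, sd = 0.2), 8, 25)
  rownames(prof) <- paste0("q", 1:8)
  cl <- cluster_electrode_weights(prof, k = 5)
  expect_equal(length(unique(cl)), 5)
  # perfect agreement: every planted group maps to exactly one cluster
  tab <- table(truth, cl)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  cl2 <- cluster_electrode_weights(prof[, 1:10], k = 2)
  tab2 <- table(rep(1:2, each = 5), cl2)
  expect_true(all(rowSums(tab2 > 0) == 1))

  # degenerate identical profiles still split deterministically
  flat <- matrix(1, 4, 6)
  c_a <- cluster_electrode_weights(flat, k = 2)
  c_b <- cluster_electrode_weights(flat, k = 2)
  expect_identical(c_a, c_b)
  expect_error(cluster_electrode_weights(flat, k = 7), "exceeds")
})

test_that("vertex-to-electrode interpolation is an exact convex combination", {
  vc <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(2, 2, 2))
  vals <- c(10, 20, 30, 40)
  # electrode on a vertex takes its value
  expect_equal(interpolate_fmri_to_electrodes(vals, vc, rbind(c(1, 0, 0)), 3), 20)
  # equidistant between two vertices with values (0, 1): exactly 0.5
  expect_equal(interpolate_fmri_to_electrodes(c(0, 1, 99, 99), vc,
                                              rbind(c(0.5, 0, 0)), 2), 0.5)
  # constant map stays constant
  expect_equal(interpolate_fmri_to_electrodes(rep(7, 4), vc, rbind(c(.3, .2, .1)), 4), 7)
  # convex combination: always inside [min, max]
  set.seed(6)
  vc2 <- matrix(rnorm(60), 20, 3)
  v2 <- rnorm(20)
  ec <- matrix(rnorm(30), 10, 3)
  out <- interpolate_fmri_to_electrodes(v2, vc2, ec, 5)
  expect_true(all(out >= min(v2) & out <= max(v2)))
  expect_warning(interpolate_fmri_to_electrodes(v2, vc2, ec, 50), "fewer vertices")
})

test_that("cross-modal agreement: self-agreement floors, null calibrates, masking helps", {
  set.seed(7)
  Q <- 6; V <- 120; E <- 30
  vc <- matrix(rnorm(V * 3), V, 3)
  ec <- matrix(rnorm(E * 3), E, 3)
  fmri <- matrix(rnorm(Q * V), Q, V, dimnames = list(paste0("q", 1:Q), NULL))
  interp <- interpolate_fmri_to_electrodes(fmri, vc, ec, 10)
  scores <- runif(E)

  self <- crossmodal_correlation_test(fmri, vc, interp, ec, scores,
                                      n_perm = 499, seed = 1)
  expect_equal(self$r$r, rep(1, Q), tolerance = 1e-12)
  expect_equal(self$p, 1 / 500)

  # independent weights: non-significant in a small calibration battery
  ps <- sapply(1:10, function(s) {
    w <- matrix(rnorm(Q * E), Q, E)
    crossmodal_correlation_test(fmri, vc, w, ec, scores, n_perm = 199, seed = s)$p
  })
  expect_gt(mean(ps > 0.05), 0.6)

  # graded SNR: restricting to better electrodes raises the mean correlation
  noise_sd <- seq(0.2, 3, length.out = E)
  w <- interp + matrix(rnorm(Q * E), Q, E) %*% diag(noise_sd)
  grade <- -noise_sd  # score tracks SNR
  r_all <- mean(crossmodal_correlation_test(fmri, vc, w, ec, grade,
                                            fraction = 1, n_perm = 199, seed = 2)$r$r)
  r_top <- mean(crossmodal_correlation_test(fmri, vc, w, ec, grade,
                                            fraction = 0.25, n_perm = 199, seed = 2)$r$r)
  expect_gt(r_top, r_all)
  expect_error(crossmodal_correlation_test(fmri, vc, w, ec, grade,
                                           fraction = 0.01, n_perm = 199),
               "fewer than 3")
})

test_that("electrode tables enforce unique ids and finite coordinates", {
  tab <- electrode_table(c("e1", "e2"), "s1", c(0, 1), c(0, 1), c(0, 1))
  expect_equal(nrow(tab), 2)
  expect_error(electrode_table(c("e1", "e1"), "s1", 0:1, 0:1, 0:1), "unique")
  expect_error(electrode_table(c("e1", "e2"), "s1", c(0, NA), 0:1, 0:1), "finite")
})
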