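test_that("top-fraction masks count and tie-break as specified", {
  set.seed(1)
  r <- runif(100)
  expect_length(top_fraction_mask(r, 0.1), 10)
  expect_setequal(top_fraction_mask(r, 1), 1:100)
  expect_error(top_fraction_mask(r, 0), "fraction")
  # boundary tie: lower index wins
  r2 <- c(0.9, 0.5, 0.5, 0.1)
  expect_equal(top_fraction_mask(r2, 0.5), c(1, 2))
})

test_that("map correlation matches hand values and respects the mask", {
  a <- c(1, 2, 3, 4)
  expect_equal(as.numeric(map_correlation(a, c(2, 4, 6, 8))), 1)
  expect_equal(as.numeric(map_correlation(a, a)), 1)
  set.seed(2)
  v <- rnorm(50); w <- rnorm(50)
  expect_equal(as.numeric(map_correlation(v, w, mask = 1:50)),
               as.numeric(map_correlation(v, w)))
  cc <- map_correlation(a, rep(1, 4))
  expect_equal(as.numeric(cc), 0)
  expect_false(attr(cc, "valid"))
  expect_error(map_correlation(a, c(1, 2)), "different lengths")
  # shuffled maps decorrelate on average
  set.seed(3)
  big <- rnorm(1000)
  rs <- replicate(50, as.numeric(map_correlation(big, sample(big))))
  expect_lt(abs(mean(rs)), 0.02)
})

test_that("permutation p-values hit the add-one floor and ceiling", {
  set.seed(4)
  V <- 60; Q <- 4
  Wm <- matrix(rnorm(Q * V), Q, V)
  res_hi <- permutation_pvalue_mean(Wm, Wm, n_perm = 999, seed = 1)
  expect_equal(res_hi$p, 1 / 1000)
  res_lo <- permutation_pvalue_mean(Wm, -Wm, n_perm = 999, seed = 1)
  expect_equal(res_lo$p, 1)
  expect_error(permutation_pvalue_mean(Wm[0, , drop = FALSE], Wm, n_perm = 200),
               "empty")
  expect_error(permutation_pvalue_mean(Wm, Wm, n_perm = 50), "n_perm")
})

test_that("BH step-up matches the hand example and the brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5), 0.05), 1:3)
  expect_length(bh_fdr(rep(1, 6), 0.05), 0)
  expect_equal(bh_fdr(0.05, 0.05), 1L)  # boundary is inclusive
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:50) {
    p <- runif(sample(3:30, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p, 0.1), stepup_oracle(p, 0.1))
  }
})

test_that("inter-subject consistency is exact for identical maps and attenuates with noise", {
  set.seed(6)
  Q <- 5; V <- 400
  shared <- matrix(rnorm(Q * V), Q, V, dimnames = list(paste0("q", 1:Q), NULL))
  maps <- list(s1 = shared, s2 = shared, s3 = shared)
  res <- intersubject_consistency(maps)
  expect_equal(res$r, rep(1, nrow(res)), tolerance = 1e-12)

  # independent maps decorrelate
  indep <- lapply(1:3, function(i) {
    m <- matrix(rnorm(Q * V), Q, V); rownames(m) <- paste0("q", 1:Q); m
  })
  names(indep) <- paste0("s", 1:3)
  res0 <- intersubject_consistency(indep)
  expect_lt(abs(mean(res0$r)), 0.05)

  # shared signal + unit noise at SNR 1: r ~= 1/sqrt((1+1)(1+1/2))
  noisy <- lapply(1:3, function(i) {
    m <- shared + matrix(rnorm(Q * V), Q, V); rownames(m) <- paste0("q", 1:Q); m
  })
  names(noisy) <- paste0("s", 1:3)
  resn <- intersubject_consistency(noisy)
  expect_equal(mean(resn$r), 1 / sqrt(3), tolerance = 0.05)
})

test_that("inter-subject consistency applies alignment operators and skips missing qids", {
  Q <- 3; V <- 30
  set.seed(7)
  base <- matrix(rnorm(Q * V), Q, V, dimnames = list(paste0("q", 1:Q), NULL))
  flip <- diag(V)[V:1, ]
  # subject 2 stores its maps reversed; operators undo the reversal
  maps <- list(s1 = base, s2 = t(flip %*% t(base)))
  res <- intersubject_consistency(
    maps,
    to_template = list(s1 = diag(V), s2 = flip),
    from_template = list(s1 = diag(V), s2 = flip)
  )
  expect_equal(res$r, rep(1, nrow(res)), tolerance = 1e-12)

  maps$s2 <- maps$s2[1:2, , drop = FALSE]
  expect_warning(res2 <- intersubject_consistency(maps), "skipped")
  expect_setequal(unique(res2$qid), c("q1", "q2"))
})

test_that("condition averages apply the hemodynamic shift and recover planted contrasts", {
  Y <- matrix(7, 10, 3)
  segs <- data.frame(qid = "q1", start = 2, end = 3)
  expect_equal(unname(condition_average_response(Y, segs)[1, ]), rep(7, 3))

  Y2 <- matrix(seq_len(20), 10, 2)  # columns 1:10 and 11:20
  m <- condition_average_response(Y2, data.frame(qid = "a", start = 2, end = 3),
                                  offset = 2)
  expect_equal(unname(m[1, ]), c(mean(c(4, 5)), mean(c(14, 15))))
  expect_error(condition_average_response(Y2, data.frame(qid = "a", start = 3, end = 2)),
               "empty segment")

  # planted contrast: each question's segments add +1 to its voxels
  set.seed(8)
  V <- 40; T_ <- 60
  planted <- list(q1 = 1:12, q2 = 21:34)
  Yp <- matrix(rnorm(T_ * V, sd = 0.1), T_, V)
  segs <- data.frame(qid = c("q1", "q1", "q2", "q2"),
                     start = c(1, 31, 11, 41), end = c(8, 38, 18, 48))
  for (i in seq_len(nrow(segs))) {
    rows <- (segs$start[i]:segs$end[i]) + 2  # place signal at the shifted rows
    Yp[rows, planted[[segs$qid[i]]]] <- Yp[rows, planted[[segs$qid[i]]]] + 1
  }
  cr <- condition_average_response(Yp, segs, offset = 2)
  wtrue <- rbind(q1 = as.numeric(seq_len(V) %in% planted$q1),
                 q2 = as.numeric(seq_len(V) %in% planted$q2))
  for (q in c("q1", "q2")) {
    expect_gt(as.numeric(map_correlation(cr[q, ], wtrue[q, ])), 0.9)
  }
})

test_that("masking to well-predicted targets raises the condition-average agreement", {
  # planted weights drive only half the targets; masked correlation must beat
  # the unmasked one because unpredicted targets contribute pure noise
  set.seed(9)
  V <- 200
  good <- 1:80
  w <- numeric(V); w[good] <- rnorm(80)
  ref <- w + rnorm(V, sd = 0.4)
  score <- numeric(V); score[good] <- 0.8; score <- score + runif(V, 0, 0.1)
  ref[-good] <- rnorm(V - 80)  # reference is noise where the model fails
  mask <- top_fraction_mask(score, 0.25)
  r_masked <- as.numeric(map_correlation(w, ref, mask))
  r_full <- as.numeric(map_correlation(w, ref))
  expect_gt(r_masked, r_full)
})

test_that("flat maps round-trip through TSV", {
  v <- setNames(rnorm(5), paste0("t", 1:5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_map_tsv(v, path)
  expect_equal(read_map_tsv(path), v, tolerance = 1e-9)
})
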