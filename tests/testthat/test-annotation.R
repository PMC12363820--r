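test_that("ngram windows truncate at story start and span the recent words", {
  t3 <- tiny_transcript(3)
  w3 <- make_windows(t3, "ngram", n = 10)
  expect_equal(nrow(w3), 3)
  expect_equal(w3$anchor_index - w3$first_index + 1L, 1:3)

  t12 <- tiny_transcript(12)
  w12 <- make_windows(t12, "ngram", n = 10)
  expect_equal(nrow(w12), 12)
  expect_equal(w12$first_index[12], 3L)
  expect_equal(w12$anchor_time, t12$onset)
  expect_equal(nrow(make_windows(transcript(character(), numeric(), numeric()),
                                 "ngram", n = 10)), 0)
})

test_that("time-context windows apply the onset threshold exactly", {
  t <- transcript(c("a", "b", "c", "d"), c(0, 0.5, 1.0, 1.6), c(0.4, 0.9, 1.4, 2))
  w <- make_windows(t, "time_context", context = 1.5)
  # anchor word 4 at 1.6 s: words with onset >= 0.1 are words 2,3,4
  expect_equal(w$first_index[4], 2L)
  expect_equal(w$text[4], "b c d")
})

test_that("ngram n=1 and context 0 windows agree on any transcript", {
  for (seed in 1:3) {
    corp <- generate_synthetic_corpus(tiny_bank(), n_words = 30,
                                      window_rate = 0.3, seed = seed)
    a <- make_windows(corp$transcript, "ngram", n = 1)
    b <- make_windows(corp$transcript, "time_context", context = 0)
    expect_equal(a$text, b$text)
    expect_equal(a$first_index, b$first_index)
  }
})

test_that("keyword annotator answers by lexicon membership with case folding", {
  bank <- question_bank("location", "Does the input mention a location?")
  ann <- keyword_annotator(list(location = c("city", "mountain")))
  t <- transcript(c("we", "climbed", "the", "mountain"), 0:3, 0:3 + 0.5)
  A <- annotate(make_windows(t, "ngram", n = 10), bank, ann)
  expect_equal(unname(A$values[4, 1]), 1L)

  t2 <- transcript(c("she", "spoke", "softly"), 0:2, 0:2 + 0.5)
  A2 <- annotate(make_windows(t2, "ngram", n = 10), bank, ann)
  expect_true(all(A2$values == 0L))

  t3 <- transcript(c("THE", "CITY"), 0:1, 0:1 + 0.5)
  A3 <- annotate(make_windows(t3, "ngram", n = 10), bank, ann)
  expect_equal(unname(A3$values[2, 1]), 1L)
})

test_that("annotation is cached and idempotent; non-binary answers error", {
  bank <- tiny_bank(2)
  wins <- make_windows(tiny_transcript(5), "ngram", n = 3)
  calls <- 0L
  flaky <- structure(function(text, qtext) {
    calls <<- calls + 1L
    as.integer(nchar(text) %% 2)
  }, annotator_id = "parity")
  cache <- annotation_cache()
  A1 <- annotate(wins, bank, flaky, cache = cache)
  n1 <- calls
  A2 <- annotate(wins, bank, flaky, cache = cache)
  expect_identical(A1$values, A2$values)
  expect_equal(calls, n1)  # second run fully served from cache

  bad <- structure(function(text, qtext) 2L, annotator_id = "bad")
  expect_error(annotate(wins, bank, bad), "non-binary")
})

test_that("a persistent cache survives a reload", {
  bank <- tiny_bank(1)
  wins <- make_windows(tiny_transcript(4), "ngram", n = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  ann <- keyword_annotator(list(q01 = "w2"), id = "kw")
  A1 <- annotate(wins, bank, ann, cache = annotation_cache(path))
  cache2 <- annotation_cache(path)
  keys <- ls(cache2$store)
  expect_equal(length(keys), 4)
  A2 <- annotate(wins, bank, ann, cache = cache2)
  expect_identical(A1$values, A2$values)
})

test_that("ensemble vote is majority with ties answering yes", {
  base <- random_annotation(W = 6, Q = 2, seed = 3)
  ones <- new_annotation(matrix(1L, 6, 2), base$anchor_time, base$qids)
  zeros <- new_annotation(matrix(0L, 6, 2), base$anchor_time, base$qids)
  expect_equal(ensemble_vote(list(ones, ones, zeros))$values, ones$values)
  expect_equal(ensemble_vote(list(zeros, zeros, ones))$values, zeros$values)
  expect_equal(ensemble_vote(list(ones, zeros))$values, ones$values)  # tie -> 1
  expect_equal(ensemble_vote(list(base, base, base))$values, base$values)
  short <- new_annotation(matrix(0L, 5, 2), base$anchor_time[1:5], base$qids)
  expect_error(ensemble_vote(list(base, short)), "shape")
})

test_that("faithfulness counts per-question agreement with gold", {
  gold <- random_annotation(W = 10, Q = 1, seed = 9)
  expect_equal(annotator_faithfulness(gold, gold)$accuracy, 1)
  flipped <- new_annotation(1L - gold$values, gold$anchor_time, gold$qids)
  expect_equal(annotator_faithfulness(flipped, gold)$accuracy, 0)
  one_off <- gold
  one_off$values[4, 1] <- 1L - one_off$values[4, 1]
  expect_equal(annotator_faithfulness(one_off, gold)$accuracy, 0.9)
})

test_that("annotation matrices round-trip through TSV", {
  A <- random_annotation(W = 8, Q = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(A, path)
  B <- read_annotation(path)
  expect_equal(B$values, A$values, ignore_attr = TRUE)
  expect_equal(B$qids, A$qids)
  expect_equal(B$anchor_time, A$anchor_time, tolerance = 1e-9)
})
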