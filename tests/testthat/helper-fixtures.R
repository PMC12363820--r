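# Small fixtures shared across tests; everything is built in code.

tiny_bank <- function(n = 3) {
  question_bank(sprintf("q%02d", seq_len(n)),
                sprintf("Does the input mention topic %d?", seq_len(n)))
}

tiny_transcript <- function(n = 6, rate = 2) {
  transcript(sprintf("w%d", seq_len(n)),
             onset = (seq_len(n) - 1) / rate,
             offset = (seq_len(n) - 1) / rate + 0.4,
             story_id = "tiny")
}

random_annotation <- function(W = 20, Q = 4, seed = 1) {
  set.seed(seed)
  new_annotation(matrix(rbinom(W * Q, 1, 0.4), W, Q),
                 anchor_time = seq(0, by = 0.5, length.out = W),
                 qids = sprintf("q%02d", seq_len(Q)))
}

# closed-form ridge on z-scored data, the independent oracle for fit_ridge_cv
ridge_oracle <- function(X, Y, alpha) {
  Xs <- scale(X) ; Ys <- scale(Y)
  solve(crossprod(Xs) + diag(alpha, ncol(Xs)), crossprod(Xs, Ys))
}

# brute-force step-up FDR, the independent oracle for bh_fdr
stepup_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i * q / m) k <- i
  if (k == 0) integer(0) else sort(ord[seq_len(k)])
}
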