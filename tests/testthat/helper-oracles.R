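# Independent oracles used across the suite.  Each recomputes a quantity by
# a different route than the implementation under test.

# Ridge solution via QR on the penalty-augmented centered system (never
# touches the normal equations the implementation solves).
ridge_qr_oracle <- function(X, Y, lambda) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  Xa <- rbind(Xc, sqrt(lambda) * diag(ncol(X)))
  Ya <- rbind(Yc, matrix(0, ncol(X), ncol(Y)))
  W <- qr.solve(Xa, Ya)
  list(weights = W,
       bias = colMeans(Y) - as.numeric(crossprod(W, colMeans(X))))
}

# Benjamini-Hochberg step-up by literal enumeration of the definition.
bh_stepup_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- 0L
  for (i in m:1) if (p[o[i]] <= i / m * alpha) { k <- i; break }
  sig <- logical(m)
  if (k > 0L) sig[o[seq_len(k)]] <- TRUE
  sig
}

# Brute-force per-word MSE over an explicit cell list (double loop).
word_mse_bruteforce <- function(M, M_hat, members) {
  cells <- which(members, arr.ind = TRUE)
  n <- dim(M)[1]
  out <- numeric(n)
  for (w in seq_len(n)) {
    acc <- 0
    for (k in seq_len(nrow(cells)))
      acc <- acc + (M_hat[w, cells[k, 1], cells[k, 2]] -
                      M[w, cells[k, 1], cells[k, 2]])^2
    out[w] <- acc / nrow(cells)
  }
  out
}

# Small planted-dataset factory shared by divergence/discovery tests.
small_planted_sim <- function(seed, n_sentences = 40, planted_fraction = 0.3,
                              planted_effect = 3, noise_sd = 1) {
  sim_config(n_words = n_sentences * 8L, n_sentences = n_sentences,
             n_channels = 8L, n_timebins = 4L, embed_dim = 12L,
             context_len = 5L, noise_sd = noise_sd,
             planted_effect = planted_effect,
             planted_fraction = planted_fraction, seed = seed)
}

withr_like_tempdir <- function() {
  d <- tempfile("megdiverge-test-")
  dir.create(d)
  d
}

planted_sentence_ids <- function(events) {
  unique(events$sentence_id[grepl("(^|,)planted(,|$)", events$categories)])
}
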