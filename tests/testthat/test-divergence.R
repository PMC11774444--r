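# Divergence statistic: significance gating, per-word MSE, sentence
# aggregation, contrast corpora, and planted-effect behaviour.

test_that("correlation gating matches the exact one-sided t transform", {
  r <- matrix(c(0, 0.99, 0.05, -0.5), 2, 2)
  S <- significant_channels(r, n_words = 100, alpha = 0.001)
  expect_false(S$members[1, 1])  # r = 0 never significant
  expect_true(S$members[2, 1])   # r = 0.99, n = 100
  expect_false(S$members[2, 2])  # negative r, one-sided

  # critical r against the inverse-t oracle at n = 1000, alpha = 0.001
  n <- 1000; alpha <- 0.001
  tcrit <- qt(1 - alpha, df = n - 2)
  rcrit <- tcrit / sqrt(n - 2 + tcrit^2)
  eps <- 1e-6
  S_hi <- significant_channels(matrix(rcrit + eps), n, alpha)
  S_lo <- significant_channels(matrix(rcrit - eps), n, alpha)
  expect_true(S_hi$members[1, 1])
  expect_false(S_lo$members[1, 1])

  expect_error(significant_channels(r, 100, alpha = 0), "alpha")
  expect_error(significant_channels(r, 100, alpha = 1), "alpha")

  # channel pooling admits whole rows
  Sc <- significant_channels(matrix(c(0.9, 0, 0, 0), 2, 2), n_words = 50,
                             alpha = 0.001, pool = "channel")
  expect_true(all(Sc$members[1, ]))
  expect_false(any(Sc$members[2, ]))
})

test_that("per-word MSE equals the brute-force double loop and Eq-style arithmetic", {
  # |S| = 2, actual (1, 2), predicted (0, 0): (1 + 4) / 2 = 2.5
  M <- array(0, c(1, 2, 1)); M[1, , 1] <- c(1, 2)
  Mh <- array(0, c(1, 2, 1))
  S <- structure(list(members = matrix(TRUE, 2, 1), alpha = 0.001,
                      n_words = 1, pool = "cell"), class = "channel_set")
  expect_equal(word_mse(M, Mh, S), 2.5)

  # perfect prediction: all zeros
  expect_equal(word_mse(M, M, S), 0)

  # random instances against the brute-force oracle
  set.seed(11)
  for (i in 1:10) {
    M <- array(rnorm(7 * 4 * 3), c(7, 4, 3))
    Mh <- array(rnorm(7 * 4 * 3), c(7, 4, 3))
    members <- matrix(runif(12) < 0.5, 4, 3)
    if (!any(members)) members[2, 2] <- TRUE
    S <- structure(list(members = members, alpha = 0.001, n_words = 7,
                        pool = "cell"), class = "channel_set")
    expect_equal(word_mse(M, Mh, S), word_mse_bruteforce(M, Mh, members))
  }

  # statistic is invariant to cells outside S
  M2 <- M
  M2[, which(!members[, 1]), 1] <- 99
  expect_identical(word_mse(M, Mh, S), word_mse(M2, Mh, S))

  S_empty <- structure(list(members = matrix(FALSE, 4, 3), alpha = 0.001,
                            n_words = 7, pool = "cell"), class = "channel_set")
  expect_error(word_mse(M, Mh, S_empty), "empty")
})

test_that("time-resolved word MSE agrees with per-bin brute force", {
  set.seed(12)
  M <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  Mh <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  members <- matrix(runif(20) < 0.4, 5, 4)
  members[, 2] <- FALSE  # a bin with no members -> NA
  S <- structure(list(members = members, alpha = 0.001, n_words = 6,
                      pool = "cell"), class = "channel_set")
  bt <- word_mse_by_time(M, Mh, S)
  expect_true(all(is.na(bt[, 2])))
  for (t in c(1, 3, 4)) {
    m1 <- members; m1[, setdiff(1:4, t)] <- FALSE
    if (!any(m1)) next
    expect_equal(bt[, t], word_mse_bruteforce(M, Mh, m1))
  }
})

test_that("sentence aggregation and ranking follow the mean-MSE rule", {
  ev <- generate_word_stream(sim_config(n_words = 20, n_sentences = 4, seed = 13))
  # all equal: ranking falls back to sentence-id order
  tab <- sentence_scores(rep(2, 20), ev)
  expect_equal(tab$ranking, 0:3)
  expect_equal(tab$sentences$mean_mse, rep(2, 4))

  # one dominant sentence ranks first
  mse <- rep(1, 20); mse[ev$sentence_id == 2] <- 10
  expect_equal(sentence_scores(mse, ev)$ranking[1], 2)

  # random vector against a group-by oracle
  set.seed(13)
  mse <- rexp(20)
  tab <- sentence_scores(mse, ev)
  oracle <- tapply(mse, ev$sentence_id, mean)
  expect_equal(tab$sentences$mean_mse,
               as.numeric(oracle[as.character(tab$sentences$sentence_id)]))
  expect_error(sentence_scores(mse[1:5], ev), "length")
})

test_that("contrast corpora split the ranking symmetrically and disjointly", {
  ev <- generate_word_stream(sim_config(n_words = 100, n_sentences = 20, seed = 14))
  set.seed(14)
  tab <- sentence_scores(rexp(100), ev)
  txt <- sentence_texts(ev)

  corp <- build_contrast(tab, txt, top_n = 10)
  expect_equal(sort(c(corp$D0$sentence_id, corp$D1$sentence_id)), 0:19)
  expect_length(intersect(corp$D0$sentence_id, corp$D1$sentence_id), 0)

  c1 <- build_contrast(tab, txt, top_n = 1)
  expect_equal(c1$D0$sentence_id,
               tab$sentences$sentence_id[which.max(tab$sentences$mean_mse)])
  expect_equal(c1$D1$sentence_id,
               tab$sentences$sentence_id[which.min(tab$sentences$mean_mse)])

  expect_warning(cr <- build_contrast(tab, txt, top_n = 15), "reducing")
  expect_equal(cr$top_n, 10L)
})

test_that("planted-category sentences dominate D0; absent effect stays at chance", {
  cfg <- small_planted_sim(seed = 15)
  d <- simulate_dataset(cfg)
  fit <- meg_encoding(d$embeddings, d$responses, folds = 10,
                      lambda_grid = c(0.1, 1, 10), inner_folds = 4)
  S <- significant_channels(fit, alpha = 0.001)
  tab <- sentence_scores(word_mse(d$responses, fit$predicted, S), d$events)
  corp <- build_contrast(tab, sentence_texts(d$events), top_n = 12)
  enr <- mean(corp$D0$sentence_id %in% planted_sentence_ids(d$events))
  expect_gte(enr, 0.8)

  # null: no planted effect -> enrichment at the chance rate
  hits <- 0L; tot <- 0L
  for (s in 1:4) {
    cfg0 <- small_planted_sim(seed = 20 + s, planted_effect = 0)
    d0 <- simulate_dataset(cfg0)
    f0 <- meg_encoding(d0$embeddings, d0$responses, folds = 10,
                       lambda_grid = c(0.1, 1, 10), inner_folds = 4)
    S0 <- significant_channels(f0, alpha = 0.001)
    t0 <- sentence_scores(word_mse(d0$responses, f0$predicted, S0), d0$events)
    c0 <- build_contrast(t0, sentence_texts(d0$events), top_n = 12)
    hits <- hits + sum(c0$D0$sentence_id %in% planted_sentence_ids(d0$events))
    tot <- tot + 12L
  }
  # chance = planted_fraction = 0.3; binomial 99.9% envelope on 48 draws
  expect_lt(abs(hits / tot - 0.3), 3.3 * sqrt(0.3 * 0.7 / tot))
})
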