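# Synthetic-data generator: stream structure, embedding context dependence,
# forward-model responses, repetition averaging, multiple-choice items.

test_that("word stream partitions sentences and plants the configured fraction", {
  ev <- generate_word_stream(sim_config(n_words = 10, n_sentences = 1,
                                        planted_fraction = 0, seed = 1))
  expect_equal(nrow(ev), 10L)
  expect_true(all(ev$sentence_id == 0L))
  expect_false(any(grepl("planted", ev$categories)))
  expect_equal(ev$word_id, 0:9)

  cfg <- sim_config(n_words = 100, n_sentences = 10, planted_fraction = 0.5,
                    seed = 1)
  ev <- generate_word_stream(cfg)
  expect_equal(length(planted_sentence_ids(ev)), 5L)  # floor(0.5 * 10)
  # every planted sentence contains the keyword
  for (s in planted_sentence_ids(ev))
    expect_true("wplanted" %in% ev$token[ev$sentence_id == s])
  expect_true(all(diff(ev$sentence_id) >= 0))

  # different seeds: different tokens, identical structure
  ev2 <- generate_word_stream(sim_config(n_words = 100, n_sentences = 10,
                                         planted_fraction = 0.5, seed = 2))
  expect_false(identical(ev$token, ev2$token))
  expect_identical(table(ev$sentence_id), table(ev2$sentence_id))
  expect_equal(length(planted_sentence_ids(ev2)), 5L)

  expect_error(sim_config(n_words = 5, n_sentences = 10), "n_sentences")
})

test_that("identical configuration reproduces the dataset bit for bit", {
  cfg <- small_planted_sim(seed = 3)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$embeddings, d2$embeddings)
  expect_identical(d1$responses, d2$responses)
})

test_that("embeddings mix a decaying context and respect the no-context limit", {
  cfg0 <- sim_config(n_words = 60, n_sentences = 6, embed_dim = 8,
                     context_mix = 0, seed = 4)
  ev <- generate_word_stream(cfg0)
  L0 <- generate_embeddings(ev, cfg0)
  # mixing weight 0: rows of repeated tokens are identical token vectors
  dup <- ev$token[duplicated(ev$token)][1]
  rows <- which(ev$token == dup)
  expect_equal(L0[rows[1], ], L0[rows[2], ])

  cfg1 <- sim_config(n_words = 60, n_sentences = 6, embed_dim = 8,
                     context_mix = 0.5, seed = 4)
  L1 <- generate_embeddings(ev, cfg1)
  # same token, different context: different rows when mixing weight > 0
  expect_gt(max(abs(L1[rows[1], ] - L1[rows[2], ])), 1e-8)
  # first word has no preceding context: equals its bare token vector
  expect_equal(L1[1, ], L0[1, ])
  # row w depends only on tokens w-context_len..w: truncating the tail of
  # the stream leaves earlier rows unchanged
  L1b <- generate_embeddings(ev[1:30, ], cfg1)
  expect_equal(L1[1:30, ], L1b, ignore_attr = TRUE)
  expect_error(generate_embeddings(ev[0, ], cfg1), "non-empty")
})

test_that("responses follow the linear forward model with calibrated noise", {
  cfg <- sim_config(n_words = 200, n_sentences = 20, n_channels = 10,
                    n_timebins = 10, embed_dim = 8, noise_sd = 0,
                    planted_effect = 0, seed = 5)
  ev <- generate_word_stream(cfg)
  L <- generate_embeddings(ev, cfg)
  tr <- make_ground_truth(cfg, ev)
  M <- generate_responses(L, tr, cfg)
  Wmat <- matrix(tr$true_weights, cfg$embed_dim, cfg$n_channels * cfg$n_timebins)
  expected <- sweep(L %*% Wmat, 2, as.numeric(tr$true_bias), "+")
  expect_equal(as.numeric(M), as.numeric(expected), tolerance = 1e-12)

  # Monte-Carlo residual variance: Var(M - LW - b) -> noise_sd^2 (>= 1e4 cells)
  cfg2 <- sim_config(n_words = 200, n_sentences = 20, n_channels = 10,
                     n_timebins = 10, embed_dim = 8, noise_sd = 1,
                     planted_effect = 0, seed = 5)
  M2 <- generate_responses(L, tr, cfg2)
  resid <- as.numeric(M2) - as.numeric(expected)
  expect_equal(stats::var(resid), 1, tolerance = 0.05)

  expect_error(generate_responses(L[, 1:3], tr, cfg2), "mismatch")
})

test_that("planted words carry residual power ~ planted_effect^2 above noise", {
  cfg <- sim_config(n_words = 400, n_sentences = 40, n_channels = 10,
                    n_timebins = 10, embed_dim = 8, noise_sd = 1,
                    planted_effect = 5, planted_fraction = 0.5, seed = 6)
  ev <- generate_word_stream(cfg)
  L <- generate_embeddings(ev, cfg)
  tr <- make_ground_truth(cfg, ev)
  M <- generate_responses(L, tr, cfg)
  Wmat <- matrix(tr$true_weights, cfg$embed_dim, cfg$n_channels * cfg$n_timebins)
  resid <- matrix(M, nrow(L)) - sweep(L %*% Wmat, 2, as.numeric(tr$true_bias), "+")
  power <- rowMeans(resid^2)
  pl <- ev$word_id %in% tr$planted_word_ids
  # per-cell second moments: ~ planted_effect^2 + noise^2 = 26 vs ~ 1
  expect_equal(mean(power[pl]), 26, tolerance = 0.25 * 26)
  expect_equal(mean(power[!pl]), 1, tolerance = 0.1)
  # separation factor >= 5 at planted_effect = 3 * noise_sd already
  cfg3 <- small_planted_sim(seed = 7)
  d3 <- simulate_dataset(cfg3)
  W3 <- matrix(d3$truth$true_weights, cfg3$embed_dim,
               cfg3$n_channels * cfg3$n_timebins)
  r3 <- matrix(d3$responses, nrow(d3$embeddings)) -
    sweep(d3$embeddings %*% W3, 2, as.numeric(d3$truth$true_bias), "+")
  pw <- rowMeans(r3^2)
  pl3 <- d3$events$word_id %in% d3$truth$planted_word_ids
  expect_gt(mean(pw[pl3]) / mean(pw[!pl3]), 5)
})

test_that("repetition averaging reduces noise as 1/n and raises signal correlation", {
  x <- array(rnorm(60), c(5, 4, 3))
  expect_equal(average_repetitions(list(x)), x, ignore_attr = TRUE)
  expect_equal(as.numeric(average_repetitions(list(x, -x))), rep(0, 60))
  expect_error(average_repetitions(list()), "non-empty")
  expect_error(average_repetitions(list(x, array(0, c(5, 4, 2)))), "shape")

  # 10 independent noise-only repetitions: variance ~ 1/10
  set.seed(8)
  reps <- lapply(1:10, function(i) array(rnorm(4000), c(40, 10, 10)))
  av <- average_repetitions(reps)
  expect_equal(stats::var(as.numeric(av)), 0.1, tolerance = 0.05)

  # correlation with noiseless signal non-decreasing in repetitions
  cfg <- sim_config(n_words = 150, n_sentences = 15, n_channels = 6,
                    n_timebins = 5, embed_dim = 8, noise_sd = 2,
                    n_repetitions = 10, seed = 9)
  ev <- generate_word_stream(cfg)
  L <- generate_embeddings(ev, cfg)
  tr <- make_ground_truth(cfg, ev)
  cfg0 <- sim_config(n_words = 150, n_sentences = 15, n_channels = 6,
                     n_timebins = 5, embed_dim = 8, noise_sd = 0,
                     n_repetitions = 1, seed = 9)
  signal <- as.numeric(generate_responses(L, tr, cfg0))
  reps <- lapply(1:10, function(r) generate_responses(L, tr, cfg, repetition = r))
  cors <- vapply(c(1, 2, 5, 10), function(n)
    cor(as.numeric(average_repetitions(reps[seq_len(n)])), signal), numeric(1))
  expect_true(all(diff(cors) >= 0))
})

test_that("multiple-choice items obey the planted rule and chance baseline", {
  expect_error(generate_mc_dataset(10, 1, seed = 1), "n_options")
  expect_length(generate_mc_dataset(0, 3, seed = 1), 0L)

  for (n_opt in c(2L, 3L)) {  # binary and ternary task formats
    items <- generate_mc_dataset(300, n_opt, seed = 10)
    expect_true(all(vapply(items, function(it)
      length(it$options) == n_opt && it$correct_index >= 0 &&
        it$correct_index < n_opt, logical(1))))
    # planted rule: correct option opens with the context's final token
    opens <- vapply(items, function(it) {
      ok_correct <- it$options[[it$correct_index + 1]][1] ==
        it$context[length(it$context)]
      others <- setdiff(seq_along(it$options), it$correct_index + 1)
      ok_wrong <- all(vapply(others, function(j)
        it$options[[j]][1] != it$context[length(it$context)], logical(1)))
      ok_correct && ok_wrong
    }, logical(1))
    expect_true(all(opens))
    # constant-choice baseline ~ 1 / n_options
    acc0 <- mean(vapply(items, function(it) it$correct_index == 0L, logical(1)))
    expect_lt(abs(acc0 - 1 / n_opt), 3 * sqrt((1 / n_opt) * (1 - 1 / n_opt) / 300))
  }
})
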