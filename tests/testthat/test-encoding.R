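# Encoding model: fold construction, ridge solver, penalty selection,
# cross-validated fitting, layer selection, and the fitted-object methods.

test_that("contiguous folds partition words with balanced contiguous chunks", {
  sp <- contiguous_kfold(10, 10)
  expect_true(all(vapply(sp, function(s) length(s$test) == 1L, logical(1))))

  sp <- contiguous_kfold(10, 3)
  expect_equal(lapply(sp, `[[`, "test"), list(1:4, 5:7, 8:10))

  # exhaustive property: disjoint, exhaustive, contiguous
  set.seed(1)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    k <- sample(2:n, 1)
    sp <- contiguous_kfold(n, k)
    tests <- lapply(sp, `[[`, "test")
    expect_equal(sort(unlist(tests)), 1:n)
    expect_equal(sum(lengths(tests)), n)   # disjoint + exhaustive
    expect_true(all(vapply(tests, function(x) all(diff(x) == 1L), logical(1))))
    expect_lte(diff(range(lengths(tests))), 1L)
  }
  expect_error(contiguous_kfold(5, 6), "k")
  expect_error(contiguous_kfold(5, 1), "k")
})

test_that("ridge solution matches the QR oracle and its limits", {
  # exact interpolation at lambda = 0 (tall design, full column rank)
  set.seed(2)
  X <- matrix(rnorm(72), 12, 6)
  f <- fit_ridge(X, X, 0)
  expect_equal(f$weights, diag(6), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(f$bias, rep(0, 6), tolerance = 1e-9)

  # infinite-penalty limit: weights -> 0, bias -> column means
  Y <- matrix(rnorm(12 * 3), 12, 3)
  f <- fit_ridge(X, Y, 1e12)
  expect_lt(max(abs(f$weights)), 1e-8)
  expect_equal(f$bias, colMeans(Y), tolerance = 1e-8)

  # closed-form equivalence on random instances
  for (i in 1:10) {
    set.seed(100 + i)
    X <- matrix(rnorm(30 * 5), 30, 5)
    Y <- matrix(rnorm(30 * 4), 30, 4)
    f <- fit_ridge(X, Y, 2.5)
    o <- ridge_qr_oracle(X, Y, 2.5)
    expect_lt(max(abs(f$weights - o$weights)), 1e-8)
    expect_lt(max(abs(f$bias - o$bias)), 1e-8)
  }

  # rank-deficient design with lambda = 0 errors rather than pseudo-inverting
  Xr <- cbind(1:8, 2 * (1:8), rnorm(8))
  expect_error(fit_ridge(Xr, matrix(rnorm(8), 8, 1), 0), "singular")
  expect_error(fit_ridge(X, Y, -1), "lambda")
})

test_that("training residual error is non-decreasing in the penalty", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40, 6)
  Y <- X %*% matrix(rnorm(6 * 3), 6, 3) + matrix(rnorm(40 * 3), 40, 3)
  rss <- vapply(10^seq(-3, 3, by = 1), function(l) {
    f <- fit_ridge(X, Y, l)
    sum((Y - predict(f, X))^2)
  }, numeric(1))
  expect_true(all(diff(rss) >= -1e-8))
})

test_that("nested penalty selection honors the grid and the noiseless limit", {
  set.seed(4)
  X <- matrix(rnorm(100 * 6), 100, 6)
  expect_equal(nested_select_lambda(X, matrix(rnorm(100), 100, 1), 3.7, 5), 3.7)
  # noiseless targets: smallest grid value wins
  Y <- X %*% matrix(rnorm(6 * 4), 6, 4)
  expect_equal(nested_select_lambda(X, Y, c(0.01, 1, 100), 5), 0.01)
  expect_error(nested_select_lambda(X[1:3, ], Y[1:3, ], c(0.01, 1), 5),
               "fewer training rows")
})

test_that("cross-validated encoding recovers a noiseless forward model", {
  cfg <- sim_config(n_words = 400, n_sentences = 40, n_channels = 6,
                    n_timebins = 3, embed_dim = 10, noise_sd = 0,
                    planted_effect = 0, seed = 5)
  d <- simulate_dataset(cfg)
  fit <- meg_encoding(d$embeddings, d$responses, folds = 10,
                      lambda_grid = c(1e-8, 1e-2, 1), inner_folds = 5)
  expect_gte(mean(fit$correlations, na.rm = TRUE), 0.999)
  expect_false(anyNA(fit$predicted))  # every word predicted exactly once
  for (t in 1:cfg$n_timebins)
    expect_lt(max(abs(fit$fold_models[[1]][[t]]$weights -
                        d$truth$true_weights[, , t])), 1e-6)
})

test_that("no information leaks from test folds into training fits", {
  cfg <- sim_config(n_words = 200, n_sentences = 20, n_channels = 4,
                    n_timebins = 2, embed_dim = 8, noise_sd = 1, seed = 6)
  d <- simulate_dataset(cfg)
  fit1 <- meg_encoding(d$embeddings, d$responses, folds = 5,
                       lambda_grid = c(0.1, 10), inner_folds = 4)
  # shuffle responses inside fold 1's test chunk only
  M2 <- d$responses
  test1 <- fit1$splits[[1]]$test
  perm <- rev(test1)
  M2[test1, , ] <- M2[perm, , ]
  fit2 <- meg_encoding(d$embeddings, M2, folds = 5,
                       lambda_grid = c(0.1, 10), inner_folds = 4)
  for (t in 1:2)
    expect_identical(fit1$fold_models[[1]][[t]]$weights,
                     fit2$fold_models[[1]][[t]]$weights)
})

test_that("parameter recovery holds at moderate noise", {
  cfg <- sim_config(n_words = 2000, n_sentences = 200, n_channels = 6,
                    n_timebins = 2, embed_dim = 15, noise_sd = 1,
                    planted_effect = 0, seed = 7)
  d <- simulate_dataset(cfg)
  fit <- meg_encoding(d$embeddings, d$responses, folds = 10,
                      lambda_grid = c(0.1, 1, 10, 100), inner_folds = 5)
  rs <- vapply(1:cfg$n_timebins, function(t)
    stats::median(vapply(1:cfg$n_channels, function(ch)
      cor(fit$fold_models[[1]][[t]]$weights[, ch],
          d$truth$true_weights[, ch, t]), numeric(1))), numeric(1))
  expect_true(all(rs > 0.8))
})

test_that("layer selection prefers the generating embeddings deterministically", {
  cfg <- sim_config(n_words = 300, n_sentences = 30, n_channels = 5,
                    n_timebins = 2, embed_dim = 8, noise_sd = 0.5, seed = 8)
  d <- simulate_dataset(cfg)
  set.seed(8)
  L_perm <- d$embeddings[sample(nrow(d$embeddings)), ]
  grid <- c(0.1, 10)
  fits <- list(signal = meg_encoding(d$embeddings, d$responses, folds = 5,
                                     lambda_grid = grid, inner_folds = 3),
               permuted = meg_encoding(L_perm, d$responses, folds = 5,
                                       lambda_grid = grid, inner_folds = 3))
  expect_equal(select_best_layer(fits), "signal")
  expect_equal(select_best_layer(fits["signal"]), "signal")
  expect_error(select_best_layer(list()), "non-empty")
})

test_that("fitted-object methods are coherent", {
  cfg <- sim_config(n_words = 150, n_sentences = 15, n_channels = 4,
                    n_timebins = 3, embed_dim = 6, noise_sd = 0.5, seed = 9)
  d <- simulate_dataset(cfg)
  fit <- meg_encoding(d$embeddings, d$responses, folds = 5,
                      lambda_grid = c(0.1, 10), inner_folds = 3)
  expect_output(print(fit), "ridge encoding")
  expect_output(print(summary(fit)), "mean held-out r")
  W <- coef(fit)
  expect_equal(dim(W), c(6L, 4L, 3L))
  expect_identical(fitted(fit), fit$predicted)
  res <- residuals(fit)
  expect_equal(as.numeric(res),
               as.numeric(unclass(d$responses)) - as.numeric(unclass(fit$predicted)))
  pr <- predict(fit, newdata = d$embeddings)
  expect_equal(dim(pr), dim(d$responses))
  # predictions from the all-data refit track the responses well
  expect_gt(cor(as.numeric(pr), as.numeric(d$responses)), 0.5)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  expect_invisible(plot(fit, which = "map"))
})
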