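# Time-resolved ridge encoding model: embeddings -> sensor responses, fitted
# per time bin with contiguous k-fold cross-validation and nested
# regularization selection.  Held-out predictions from all folds are
# concatenated in word order, and prediction quality is summarized as a
# per-channel / per-timebin Pearson correlation map.

#' Contiguous k-fold splits
#'
#' Partitions `n_words` presentation-ordered items into `k` contiguous test
#' chunks (the appropriate split for temporally autocorrelated recordings).
#' Chunk sizes differ by at most one; earlier folds absorb the remainder.
#'
#' @param n_words Number of items.
#' @param k Number of folds, `2 <= k <= n_words`.
#' @return List of `k` splits, each a list with `fold_index`, `test`
#'   (contiguous 1-based row indices) and `train` (the complement).
#' @examples
#' contiguous_kfold(10, 3)[[1]]$test
#' @export
contiguous_kfold <- function(n_words, k) {
  if (k < 2L || k > n_words) stop("'k' must satisfy 2 <= k <= n_words")
  sizes <- rep(n_words %/% k, k)
  rem <- n_words %% k
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, ends[-k] + 1L)
  lapply(seq_len(k), function(i) {
    test <- starts[i]:ends[i]
    list(fold_index = i, test = test, train = setdiff(seq_len(n_words), test))
  })
}

#' Fit a multi-target ridge regression
#'
#' Minimizes `||Y - XW - b||^2 + lambda ||W||^2` with an unpenalized
#' intercept: predictors and targets are centered, `W` solves the penalized
#' normal equations on the centered data, and the bias absorbs the means.
#' With `lambda = 0` a rank-deficient design is an error (no silent
#' pseudo-inverse).
#'
#' @param X Numeric matrix `n x p`.
#' @param Y Numeric matrix `n x q` (a vector is treated as one column).
#' @param lambda Non-negative ridge penalty.
#' @return Object of class `"ridge_model"`: list with `weights` (`p x q`),
#'   `bias` (length `q`) and `lambda`.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' fit <- fit_ridge(X, X, lambda = 0)
#' max(abs(fit$weights - diag(4)))
#' @export
fit_ridge <- function(X, Y, lambda) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows")
  if (nrow(X) < 2L) stop("need at least 2 rows")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0)
    stop("'lambda' must be a single non-negative number")
  if (anyNA(X) || anyNA(Y) || !all(is.finite(X)) || !all(is.finite(Y)))
    stop("non-finite values in X or Y")
  xm <- colMeans(X); ym <- colMeans(Y)
  Xc <- sweep(X, 2L, xm); Yc <- sweep(Y, 2L, ym)
  A <- crossprod(Xc)
  diag(A) <- diag(A) + lambda
  W <- tryCatch(solve(A, crossprod(Xc, Yc)),
                error = function(e)
                  stop("ridge system is singular (rank-deficient X with lambda = 0?)"))
  structure(list(weights = W, bias = as.numeric(ym - crossprod(W, xm)),
                 lambda = lambda),
            class = "ridge_model")
}

#' @export
predict.ridge_model <- function(object, newdata, ...) {
  sweep(as.matrix(newdata) %*% object$weights, 2L, object$bias, "+")
}

#' @export
print.ridge_model <- function(x, ...) {
  cat(sprintf("Ridge model: %d predictors -> %d targets, lambda = %.4g\n",
              nrow(x$weights), ncol(x$weights), x$lambda))
  invisible(x)
}

# Column-wise Pearson r between two matrices, across rows.  Zero-variance
# columns give NA (excluded from averages downstream).
colwise_pearson <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  Ac <- sweep(A, 2L, colMeans(A)); Bc <- sweep(B, 2L, colMeans(B))
  sa <- sqrt(colSums(Ac^2)); sb <- sqrt(colSums(Bc^2))
  r <- colSums(Ac * Bc) / (sa * sb)
  r[sa == 0 | sb == 0] <- NA_real_
  r
}

#' Select the ridge penalty by inner contiguous cross-validation
#'
#' Splits the training rows into `inner_k` contiguous folds; for each
#' candidate penalty, fits on the inner-train rows and scores the mean
#' held-out Pearson correlation across target columns (undefined,
#' zero-variance columns excluded).  Returns the grid value with the highest
#' mean inner score; ties break to the smallest penalty.
#'
#' @param X_train,Y_train Training design and targets.
#' @param lambda_grid Non-empty vector of candidate penalties, all `>= 0`.
#' @param inner_k Number of inner folds.
#' @return The selected penalty (scalar).
#' @export
nested_select_lambda <- function(X_train, Y_train, lambda_grid, inner_k = 5L) {
  if (length(lambda_grid) == 0L || any(lambda_grid < 0))
    stop("'lambda_grid' must be non-empty with values >= 0")
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  if (length(lambda_grid) == 1L) return(lambda_grid)
  X_train <- as.matrix(X_train); Y_train <- as.matrix(Y_train)
  if (nrow(X_train) < inner_k)
    stop("fewer training rows than inner folds")
  splits <- contiguous_kfold(nrow(X_train), inner_k)
  score <- numeric(length(lambda_grid))
  for (sp in splits) {
    Xtr <- X_train[sp$train, , drop = FALSE]
    Ytr <- Y_train[sp$train, , drop = FALSE]
    Xte <- X_train[sp$test, , drop = FALSE]
    Yte <- Y_train[sp$test, , drop = FALSE]
    xm <- colMeans(Xtr); ym <- colMeans(Ytr)
    Xc <- sweep(Xtr, 2L, xm); Yc <- sweep(Ytr, 2L, ym)
    A0 <- crossprod(Xc); B <- crossprod(Xc, Yc)
    Xtec <- sweep(Xte, 2L, xm)
    for (li in seq_along(lambda_grid)) {
      A <- A0
      diag(A) <- diag(A) + lambda_grid[li]
      W <- solve(A, B)
      pred <- sweep(Xtec %*% W, 2L, ym, "+")
      r <- colwise_pearson(Yte, pred)
      score[li] <- score[li] + mean(r, na.rm = TRUE) / length(splits)
    }
  }
  score[is.na(score)] <- -Inf
  lambda_grid[which.max(score)]  # first max = smallest lambda on ties
}

#' Fit the time-resolved encoding model
#'
#' The central fitting function.  For each time bin, responses across all
#' channels are regressed jointly on the embeddings with ridge regression
#' under contiguous `folds`-fold cross-validation: within each fold the
#' penalty is chosen by nested contiguous cross-validation on the training
#' rows only, the model is fitted on those rows, and the held-out chunk is
#' predicted.  Held-out predictions are concatenated in presentation order
#' (every word predicted exactly once) and summarized as a per-channel /
#' per-timebin Pearson correlation map across words.  Per-timebin models are
#' also refitted on all words (penalty = per-timebin median of the fold
#' choices, snapped to the grid) for use by [predict.meg_encoding()] and
#' [coef.meg_encoding()].
#'
#' @param embeddings Numeric matrix `n_words x embed_dim` (one layer).
#' @param responses Numeric array `n_words x n_channels x n_timebins`.
#' @param folds Number of outer contiguous folds (default 10).
#' @param lambda_grid Candidate ridge penalties (default `10^(-4:4)`).
#' @param inner_folds Inner folds for penalty selection (default 5).
#' @param lambda_per_channel If `TRUE`, the penalty is selected per channel
#'   within each fold/time bin instead of shared across channels.
#' @return An object of class `"meg_encoding"`; see Details.
#' @details The returned object contains `predicted` (held-out prediction
#'   array, same shape as `responses`), `correlations`
#'   (`n_channels x n_timebins`), `chosen_lambdas` (`folds x n_timebins`
#'   matrix, or a list when `lambda_per_channel`), `fold_models`,
#'   `final_models`, `splits`, `dims`, and the inputs (for residuals).
#' @examples
#' cfg <- sim_config(n_words = 120, n_sentences = 12, n_channels = 4,
#'                   n_timebins = 3, embed_dim = 6, noise_sd = 0.5, seed = 1)
#' d <- simulate_dataset(cfg)
#' fit <- meg_encoding(d$embeddings, d$responses, folds = 5,
#'                     lambda_grid = c(0.1, 1, 10), inner_folds = 3)
#' fit
#' @export
meg_encoding <- function(embeddings, responses, folds = 10L,
                         lambda_grid = 10^(-4:4), inner_folds = 5L,
                         lambda_per_channel = FALSE) {
  L <- as.matrix(embeddings)
  if (!all(is.finite(L))) stop("non-finite values in embeddings")
  if (length(dim(responses)) != 3L)
    stop("'responses' must be a 3-d array (words x channels x timebins)")
  if (!all(is.finite(responses))) stop("non-finite values in responses")
  n <- nrow(L)
  if (dim(responses)[1] != n)
    stop("embeddings and responses disagree on the number of words")
  C <- dim(responses)[2]; Tb <- dim(responses)[3]
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  splits <- contiguous_kfold(n, folds)

  predicted <- array(NA_real_, dim(responses))
  chosen <- matrix(NA_real_, folds, Tb)
  fold_models <- vector("list", folds)
  for (sp in splits) {
    fold_models[[sp$fold_index]] <- vector("list", Tb)
    Xtr <- L[sp$train, , drop = FALSE]
    Xte <- L[sp$test, , drop = FALSE]
    for (t in seq_len(Tb)) {
      Ytr <- responses[sp$train, , t, drop = TRUE]
      Ytr <- matrix(Ytr, length(sp$train), C)
      if (lambda_per_channel) {
        lam <- vapply(seq_len(C), function(ch)
          nested_select_lambda(Xtr, Ytr[, ch, drop = FALSE], lambda_grid,
                               inner_folds), numeric(1))
        models <- lapply(seq_len(C), function(ch)
          fit_ridge(Xtr, Ytr[, ch, drop = FALSE], lam[ch]))
        pred <- do.call(cbind, lapply(models, function(m) predict(m, Xte)))
        fold_models[[sp$fold_index]][[t]] <- models
        chosen[sp$fold_index, t] <- stats::median(lam)
      } else {
        lam <- nested_select_lambda(Xtr, Ytr, lambda_grid, inner_folds)
        m <- fit_ridge(Xtr, Ytr, lam)
        pred <- predict(m, Xte)
        fold_models[[sp$fold_index]][[t]] <- m
        chosen[sp$fold_index, t] <- lam
      }
      predicted[sp$test, , t] <- pred
    }
  }

  correlations <- matrix(NA_real_, C, Tb)
  for (t in seq_len(Tb))
    correlations[, t] <- colwise_pearson(matrix(responses[, , t], n, C),
                                         matrix(predicted[, , t], n, C))

  final_models <- lapply(seq_len(Tb), function(t) {
    lam_t <- stats::median(chosen[, t])
    lam_t <- lambda_grid[which.min(abs(log10(lambda_grid + 1e-300) -
                                         log10(lam_t + 1e-300)))]
    fit_ridge(L, matrix(responses[, , t], n, C), lam_t)
  })

  structure(list(predicted = structure(predicted, class = "response_tensor",
                                       bin_width = attr(responses, "bin_width")),
                 correlations = correlations,
                 chosen_lambdas = chosen,
                 fold_models = fold_models,
                 final_models = final_models,
                 splits = splits,
                 lambda_grid = lambda_grid,
                 lambda_per_channel = lambda_per_channel,
                 dims = c(n_words = n, n_channels = C, n_timebins = Tb,
                          embed_dim = ncol(L)),
                 embeddings = L,
                 responses = responses,
                 layer_index = attr(embeddings, "layer_index"),
                 call = match.call()),
            class = "meg_encoding")
}

#' Select the best-predicting layer
#'
#' Given encoding results for several embedding layers, returns the layer
#' whose correlation map has the highest mean over all channels and time
#' bins (undefined cells excluded).  Ties break to the lowest layer index /
#' first element.
#'
#' @param results_by_layer Named list (or list) of `"meg_encoding"` objects.
#' @return The selected layer's name (if named) or integer position.
#' @export
select_best_layer <- function(results_by_layer) {
  if (!is.list(results_by_layer) || length(results_by_layer) == 0L)
    stop("'results_by_layer' must be a non-empty list")
  means <- vapply(results_by_layer, function(r) {
    stopifnot(inherits(r, "meg_encoding"))
    mean(r$correlations, na.rm = TRUE)
  }, numeric(1))
  i <- which.max(means)
  if (!is.null(names(results_by_layer)) && nzchar(names(results_by_layer)[i]))
    names(results_by_layer)[i]
  else i
}
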