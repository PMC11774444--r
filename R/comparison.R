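# Base-versus-fine-tuned encoding comparison: per-(channel, timebin)
# permutation tests on the correlation difference, and category-wise
# MSE-improvement analysis with Student's t-tests and Benjamini-Hochberg
# correction across time bins.

#' Per-channel permutation test of two encoding models
#'
#' For every (channel, timebin) cell the statistic is
#' `delta_r = r(M, M_hat_ft) - r(M, M_hat_base)` across words.  The null is
#' built by permuting the word order of the measured responses `M`, the same
#' permutation applied to both correlations in each draw (paired design, so
#' word-level structure is controlled).  Empirical two-sided p-values use
#' the add-one rule; cells with `p < alpha` are labeled `"better"` or
#' `"worse"` by the sign of `delta_r`, the rest `"not-significant"`.  No
#' multiplicity correction is applied by default; `fdr = TRUE` switches the
#' labeling to Benjamini-Hochberg-adjusted p-values.
#'
#' @param M Measured responses, array `n_words x n_channels x n_timebins`.
#' @param M_hat_base,M_hat_ft Predicted responses from the base and
#'   fine-tuned encoding models, same shape as `M`.
#' @param n_perm Number of permutations (default 10000; below 100 a warning
#'   is issued).
#' @param alpha Significance level for labeling.
#' @param seed Integer seed for the permutation stream.
#' @param fdr Apply Benjamini-Hochberg correction across cells before
#'   labeling.
#' @return Object of class `"channel_comparison"`: list with matrices
#'   `delta_r`, `p` and `labels` (`n_channels x n_timebins`), `alpha`,
#'   `n_perm`, `fdr`, and `fractions` (per-timebin data frame of label
#'   shares, summing to 1).
#' @export
permutation_channel_test <- function(M, M_hat_base, M_hat_ft, n_perm = 10000L,
                                     alpha = 0.05, seed = 1L, fdr = FALSE) {
  if (!identical(dim(M), dim(M_hat_base)) || !identical(dim(M), dim(M_hat_ft)))
    stop("response and prediction shapes differ")
  if (n_perm < 100L) warning("n_perm < 100 gives very coarse p-values")
  n <- dim(M)[1]; C <- dim(M)[2]; Tb <- dim(M)[3]
  std_cols <- function(A) {
    A <- sweep(A, 2L, colMeans(A))
    s <- sqrt(colSums(A^2) / (n - 1))
    A <- sweep(A, 2L, pmax(s, .Machine$double.eps), "/")
    attr(A, "zero_var") <- s == 0
    A
  }
  Ms <- std_cols(flatten_tensor(unclass(M)))
  Hb <- std_cols(flatten_tensor(unclass(M_hat_base)))
  Hf <- std_cols(flatten_tensor(unclass(M_hat_ft)))
  bad <- attr(Ms, "zero_var") | attr(Hb, "zero_var") | attr(Hf, "zero_var")
  delta <- colSums(Ms * Hf) / (n - 1) - colSums(Ms * Hb) / (n - 1)
  Dif <- Hf - Hb  # delta_r under a permutation needs one product only
  ge <- with_substream(seed, "channel_perm", {
    cnt <- integer(length(delta))
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      d <- colSums(Ms[perm, , drop = FALSE] * Dif) / (n - 1)
      cnt <- cnt + (abs(d) >= abs(delta))
    }
    cnt
  })
  p <- (1 + ge) / (n_perm + 1)
  p_lab <- if (fdr) stats::p.adjust(p, method = "BH") else p
  labels <- ifelse(p_lab < alpha, ifelse(delta > 0, "better", "worse"),
                   "not-significant")
  labels[bad] <- "not-significant"; p[bad] <- NA_real_; delta[bad] <- NA_real_
  dim(delta) <- dim(p) <- c(C, Tb); dim(labels) <- c(C, Tb)
  fractions <- data.frame(
    timebin = seq_len(Tb) - 1L,
    better = colMeans(labels == "better"),
    worse = colMeans(labels == "worse"),
    not_significant = colMeans(labels == "not-significant"))
  structure(list(delta_r = delta, p = p, labels = labels, alpha = alpha,
                 n_perm = as.integer(n_perm), fdr = fdr,
                 fractions = fractions),
            class = "channel_comparison")
}

#' @export
print.channel_comparison <- function(x, ...) {
  cat(sprintf("Channel comparison (%d permutations, alpha = %g%s)\n",
              x$n_perm, x$alpha, if (x$fdr) ", BH-corrected" else ""))
  cat(sprintf("  better %.1f%%, worse %.1f%%, not significant %.1f%% of cells\n",
              100 * mean(x$labels == "better"),
              100 * mean(x$labels == "worse"),
              100 * mean(x$labels == "not-significant")))
  invisible(x)
}

# Words carrying a category flag in the comma-separated annotation column.
category_flags <- function(events, category) {
  grepl(sprintf("(^|,)%s(,|$)", category), events$categories)
}

#' Category-wise MSE-improvement analysis
#'
#' Per time bin, each word's improvement is
#' `delta_MSE_w = MSE_base,w - MSE_ft,w` (positive = the fine-tuned model
#' predicts the word better).  In-category words are compared with
#' out-of-category words by a two-sample Student's t-test per bin, and the
#' per-bin p-values are Benjamini-Hochberg corrected at level `alpha`.
#'
#' @param word_mse_base,word_mse_ft Per-word divergence from the base and
#'   fine-tuned models: matrices `n_words x n_timebins` (from
#'   [word_mse_by_time()]) or plain vectors (treated as one bin).
#' @param events The matching `"word_events"` data frame.
#' @param category Category label to test (e.g. `"social"`, `"physical"`,
#'   `"planted"`); at least 2 words must carry it.
#' @param alpha FDR level (default 0.05).
#' @return A data frame of class `"category_improvement"` with one row per
#'   time bin: group means and standard errors of the improvement, `t`,
#'   `p`, `p_adj` and `significant`.
#' @export
category_improvement <- function(word_mse_base, word_mse_ft, events, category,
                                 alpha = 0.05) {
  B <- as.matrix(word_mse_base); F_ <- as.matrix(word_mse_ft)
  if (!identical(dim(B), dim(F_))) stop("base and fine-tuned MSE shapes differ")
  if (nrow(B) != nrow(events)) stop("MSE rows must match the word events")
  flag <- category_flags(events, category)
  if (sum(flag) < 2L)
    stop(sprintf("category '%s' has fewer than 2 words", category))
  if (sum(!flag) < 2L) stop("fewer than 2 out-of-category words")
  Delta <- B - F_
  Tb <- ncol(Delta)
  res <- lapply(seq_len(Tb), function(t) {
    d <- Delta[, t]
    if (all(is.na(d)))
      return(c(mean_in = NA, se_in = NA, mean_out = NA, se_out = NA,
               t = NA, p = NA))
    din <- d[flag]; dout <- d[!flag]
    tt <- stats::t.test(din, dout, var.equal = TRUE)
    c(mean_in = mean(din), se_in = stats::sd(din) / sqrt(length(din)),
      mean_out = mean(dout), se_out = stats::sd(dout) / sqrt(length(dout)),
      t = unname(tt$statistic), p = tt$p.value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(timebin = seq_len(Tb) - 1L, out)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- !is.na(out$p_adj) & out$p_adj <= alpha
  attr(out, "category") <- category
  attr(out, "alpha") <- alpha
  class(out) <- c("category_improvement", "data.frame")
  out
}

#' @export
print.category_improvement <- function(x, ...) {
  cat(sprintf("Category improvement ('%s', BH-FDR at %g): %d / %d bins significant\n",
              attr(x, "category"), attr(x, "alpha"),
              sum(x$significant), nrow(x)))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Category-informed embedding variant
#'
#' Appends to the embedding matrix a column encoding membership of the given
#' word category: a toy analogue of representations from a model fine-tuned
#' on category-specific material, whose hidden states come to carry that
#' category.  Used to exercise the model-comparison stage end to end on
#' synthetic data.
#'
#' @param embeddings Embedding matrix `n_words x embed_dim`.
#' @param events The matching `"word_events"` data frame.
#' @param category Category flag to encode (default `"planted"`).
#' @param strength Scale of the appended indicator column.
#' @return Matrix `n_words x (embed_dim + 1)`.
#' @export
finetuned_embeddings <- function(embeddings, events, category = "planted",
                                 strength = 1) {
  if (nrow(embeddings) != nrow(events))
    stop("embeddings and events disagree on word count")
  ind <- as.numeric(category_flags(events, category))
  out <- cbind(as.matrix(embeddings), strength * ind)
  attr(out, "layer_index") <- attr(embeddings, "layer_index")
  out
}
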