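# Per-word divergence statistic and contrast-corpus construction.  Channels
# are gated by one-sided correlation significance; each word's divergence is
# its mean squared prediction error over the significant (channel, timebin)
# cells; sentences are ranked by their mean word divergence and the extremes
# become the contrast corpora D0 (least predicted) and D1 (best predicted).

#' Significance-gate the correlation map
#'
#' A (channel, timebin) cell enters the significant set `S` iff the one-sided
#' p-value of its held-out Pearson correlation being positive, under the
#' exact t transform `t = r sqrt(n - 2) / sqrt(1 - r^2)` with `n - 2` degrees
#' of freedom, falls below `alpha` (default 0.001; no multiplicity correction
#' at this gating step).  With `pool = "channel"` a channel significant in
#' any bin contributes all of its bins.
#'
#' @param correlations A correlation matrix `n_channels x n_timebins`, or a
#'   `"meg_encoding"` fit (its map and word count are used).
#' @param n_words Number of words the correlations were computed across
#'   (ignored when a fit is supplied).
#' @param alpha One-sided significance level in (0, 1).
#' @param pool `"cell"` (default) gates each (channel, timebin) cell
#'   separately; `"channel"` admits whole channels.
#' @return Object of class `"channel_set"`: list with `members` (logical
#'   `n_channels x n_timebins`), `alpha`, `n_words`, `pool`.
#' @export
significant_channels <- function(correlations, n_words = NULL, alpha = 0.001,
                                 pool = c("cell", "channel")) {
  pool <- match.arg(pool)
  if (inherits(correlations, "meg_encoding")) {
    n_words <- correlations$dims[["n_words"]]
    correlations <- correlations$correlations
  }
  if (is.null(n_words) || n_words < 3L) stop("'n_words' must be >= 3")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be in (0, 1)")
  r <- as.matrix(correlations)
  tstat <- r * sqrt(n_words - 2) / sqrt(pmax(1 - r^2, 0))
  p <- stats::pt(tstat, df = n_words - 2, lower.tail = FALSE)
  members <- !is.na(p) & p < alpha
  if (pool == "channel") {
    sig_ch <- rowSums(members) > 0L
    members <- matrix(sig_ch, nrow(r), ncol(r))
  }
  structure(list(members = members, alpha = alpha, n_words = n_words,
                 pool = pool),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("Significant set: %d / %d cells (alpha = %g, one-sided, pooling: %s)\n",
              sum(x$members), length(x$members), x$alpha, x$pool))
  invisible(x)
}

# Internal: flatten a words x channels x timebins array to words x cells.
flatten_tensor <- function(M) {
  d <- dim(M)
  matrix(M, d[1], d[2] * d[3])
}

#' Per-word divergence statistic
#'
#' For each word `w`, the mean squared difference between predicted and
#' actual responses over the members of the significant set `S`:
#' `MSE_w = (1 / |S|) * sum_{i in S} (Mhat_wi - M_wi)^2`.  Cells outside `S`
#' never influence the statistic.
#'
#' @param M Actual responses, array `n_words x n_channels x n_timebins`.
#' @param M_hat Predicted responses, same shape.
#' @param S A `"channel_set"` with at least one member.
#' @return Numeric vector of length `n_words`, non-negative.
#' @export
word_mse <- function(M, M_hat, S) {
  stopifnot(inherits(S, "channel_set"))
  if (!identical(dim(M), dim(M_hat))) stop("M and M_hat shapes differ")
  if (!identical(dim(S$members), dim(M)[2:3]))
    stop("channel set does not match the response grid")
  idx <- which(as.logical(S$members))
  if (length(idx) == 0L) stop("empty significant set: statistic undefined")
  D <- flatten_tensor(unclass(M_hat) - unclass(M))
  rowMeans(D[, idx, drop = FALSE]^2)
}

#' Per-word, per-timebin divergence
#'
#' Same statistic as [word_mse()] but averaged over the members of `S`
#' within each time bin separately, for time-resolved category analyses.
#' Bins with no significant member are `NA`.
#'
#' @inheritParams word_mse
#' @return Matrix `n_words x n_timebins`.
#' @export
word_mse_by_time <- function(M, M_hat, S) {
  stopifnot(inherits(S, "channel_set"))
  if (!identical(dim(M), dim(M_hat))) stop("M and M_hat shapes differ")
  Tb <- dim(M)[3]
  out <- matrix(NA_real_, dim(M)[1], Tb)
  D2 <- (unclass(M_hat) - unclass(M))^2
  for (t in seq_len(Tb)) {
    ch <- which(S$members[, t])
    if (length(ch) > 0L)
      out[, t] <- rowMeans(matrix(D2[, ch, t], dim(M)[1], length(ch)))
  }
  out
}

#' Aggregate word divergence to sentences
#'
#' Each sentence scores the unweighted mean `MSE_w` of its member words;
#' sentences are ranked by descending score (ties to the lower sentence id).
#'
#' @param word_mse Numeric vector of per-word divergences, one per event.
#' @param events The matching `"word_events"` data frame.
#' @return Object of class `"divergence_table"`: list with `words`
#'   (data frame `word_id`, `token`, `sentence_id`, `mse`), `sentences`
#'   (data frame `sentence_id`, `n_words`, `mean_mse`), and `ranking`
#'   (sentence ids, highest divergence first).
#' @export
sentence_scores <- function(word_mse, events) {
  if (length(word_mse) != nrow(events))
    stop("'word_mse' length must equal the number of word events")
  if (any(word_mse < 0, na.rm = TRUE)) stop("MSE values must be non-negative")
  sids <- sort(unique(events$sentence_id))
  scored <- !is.na(word_mse)
  keep <- vapply(sids, function(s) any(scored & events$sentence_id == s),
                 logical(1))
  if (any(!keep)) {
    warning(sprintf("%d sentence(s) with no scored words skipped", sum(!keep)))
    sids <- sids[keep]
  }
  mean_mse <- vapply(sids, function(s)
    mean(word_mse[scored & events$sentence_id == s]), numeric(1))
  n_w <- vapply(sids, function(s) sum(events$sentence_id == s), integer(1))
  ord <- order(-mean_mse, sids)
  structure(list(words = data.frame(word_id = events$word_id,
                                    token = events$token,
                                    sentence_id = events$sentence_id,
                                    mse = word_mse,
                                    stringsAsFactors = FALSE),
                 sentences = data.frame(sentence_id = sids, n_words = n_w,
                                        mean_mse = mean_mse),
                 ranking = sids[ord]),
            class = "divergence_table")
}

#' @export
print.divergence_table <- function(x, ...) {
  cat(sprintf("Divergence table: %d words, %d sentences\n",
              nrow(x$words), nrow(x$sentences)))
  cat(sprintf("  word MSE range [%.4g, %.4g]; top sentence id %d\n",
              min(x$words$mse, na.rm = TRUE), max(x$words$mse, na.rm = TRUE),
              x$ranking[1]))
  invisible(x)
}

#' Build the contrast corpora
#'
#' The `top_n` highest-divergence sentences form D0 (least predicted), the
#' `top_n` lowest form D1 (best predicted).  When fewer than `2 * top_n`
#' sentences are available, `top_n` is reduced symmetrically with a warning
#' so the corpora stay disjoint.
#'
#' @param table A `"divergence_table"`.
#' @param sentences Named character vector of sentence texts (names are
#'   sentence ids), e.g. from [sentence_texts()].
#' @param top_n Corpus size (default 100).
#' @return Object of class `"contrast_corpora"`: list with data frames `D0`
#'   and `D1` (`sentence_id`, `text`, `mean_mse`) and `top_n`.
#' @export
build_contrast <- function(table, sentences, top_n = 100L) {
  stopifnot(inherits(table, "divergence_table"))
  ns <- length(table$ranking)
  if (ns == 0L) stop("empty divergence table")
  if (ns < 2L * top_n) {
    top_n <- ns %/% 2L
    warning(sprintf("fewer than 2*top_n sentences; reducing top_n to %d", top_n))
    if (top_n < 1L) stop("not enough sentences to build disjoint corpora")
  }
  top_n <- as.integer(top_n)
  d0_ids <- table$ranking[seq_len(top_n)]
  d1_ids <- rev(table$ranking)[seq_len(top_n)]
  grab <- function(ids) {
    data.frame(sentence_id = ids,
               text = unname(sentences[as.character(ids)]),
               mean_mse = table$sentences$mean_mse[match(ids, table$sentences$sentence_id)],
               stringsAsFactors = FALSE)
  }
  structure(list(D0 = grab(d0_ids), D1 = grab(d1_ids), top_n = top_n),
            class = "contrast_corpora")
}

#' @export
print.contrast_corpora <- function(x, ...) {
  cat(sprintf("Contrast corpora: |D0| = |D1| = %d\n", x$top_n))
  cat(sprintf("  D0 mean divergence %.4g; D1 mean divergence %.4g\n",
              mean(x$D0$mean_mse), mean(x$D1$mean_mse)))
  invisible(x)
}
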