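# Multiple-choice-as-language-modeling scoring, exercised on a toy sequence
# scorer.  An item's N options are each concatenated to the context; the
# scorer's logits for the realized option tokens (each read from the
# preceding step's prediction) are summed into one score per option, and
# cross-entropy over the N scores against the correct option trains the
# scorer.  The toy scorer is a bigram next-token model: small enough to
# train in seconds, sufficient to exercise the scoring and training
# contracts end to end.

#' Create a toy bigram sequence scorer
#'
#' A next-token model over a synthetic vocabulary: the logit vector at
#' position `t` is a learned function of the token at `t - 1` (a row of a
#' `V x V` transition matrix), and a learned start vector predicts position
#' 1.  Deterministic in evaluation; trainable by gradient descent via
#' [train_mc()] and [train_lm()].
#'
#' @param vocab Character vector of tokens, or an integer vocabulary size
#'   (tokens are then `t001, t002, ...`).
#' @param seed Seed for the random initialization.
#' @param init_sd Standard deviation of the initial weights; `0` gives a
#'   uniform-logit scorer (every prediction flat over the vocabulary).
#' @return Object of class `"toy_scorer"`.
#' @export
toy_scorer <- function(vocab, seed = 1L, init_sd = 0.01) {
  if (is.numeric(vocab) && length(vocab) == 1L)
    vocab <- sprintf("t%03d", seq_len(vocab))
  V <- length(vocab)
  if (V < 2L) stop("vocabulary must contain at least 2 tokens")
  W <- with_substream(seed, "scorer_init",
                      matrix(stats::rnorm(V * V, sd = init_sd), V, V))
  s <- with_substream(seed, "scorer_init_start", stats::rnorm(V, sd = init_sd))
  structure(list(vocab = vocab, W = W, start = s, loss_curve = numeric(0)),
            class = "toy_scorer")
}

#' @export
print.toy_scorer <- function(x, ...) {
  cat(sprintf("Toy bigram scorer: vocabulary %d, %d trained epochs\n",
              length(x$vocab), length(x$loss_curve)))
  invisible(x)
}

#' Per-position logits of a token sequence
#'
#' Returns, for each position of the input, the scorer's logit vector over
#' the vocabulary predicting that position's token from the preceding
#' context (the start vector for position 1).
#'
#' @param scorer A `"toy_scorer"`.
#' @param tokens Character vector of tokens.
#' @return Matrix `length(tokens) x V`.
#' @export
token_logits <- function(scorer, tokens) {
  stopifnot(inherits(scorer, "toy_scorer"))
  idx <- match(tokens, scorer$vocab)
  if (anyNA(idx)) stop("token outside the scorer vocabulary")
  n <- length(idx)
  if (n == 0L) stop("empty token sequence")
  rbind(matrix(scorer$start, 1L),
        if (n > 1L) scorer$W[idx[-n], , drop = FALSE])
}

log_softmax_rows <- function(L) {
  m <- apply(L, 1L, max)
  L - m - log(rowSums(exp(L - m)))
}

#' Score the options of a multiple-choice item
#'
#' For each option, the context and option tokens are concatenated, the
#' sequence is run through the scorer, and the logits assigned to the
#' realized option tokens (one per option position, each read from the
#' prediction made at the preceding step) are summed into the option's
#' score.  `mode = "logit"` sums raw logits (the default);
#' `mode = "logprob"` sums log-softmax probabilities, the conventional
#' log-likelihood reading.  The mode used is recorded on the result.
#'
#' @param scorer A `"toy_scorer"` (or any object supported by
#'   [token_logits()]).
#' @param item A multiple-choice item: list with `context` (character,
#'   non-empty), `options` (list of non-empty character vectors) and
#'   `correct_index` (0-based).
#' @param mode `"logit"` or `"logprob"`.
#' @return Object of class `"option_scores"`: list with `scores` (length N),
#'   `correct_index`, `mode`.
#' @export
score_options <- function(scorer, item, mode = c("logit", "logprob")) {
  mode <- match.arg(mode)
  if (length(item$context) == 0L) stop("item context must be non-empty")
  if (length(item$options) < 2L) stop("need at least 2 options")
  nc <- length(item$context)
  scores <- vapply(item$options, function(opt) {
    if (length(opt) == 0L) stop("empty option")
    seq_tok <- c(item$context, opt)
    L <- token_logits(scorer, seq_tok)
    if (mode == "logprob") L <- log_softmax_rows(L)
    pos <- (nc + 1L):length(seq_tok)
    tok_col <- match(seq_tok[pos], scorer$vocab)
    sum(L[cbind(pos, tok_col)])
  }, numeric(1))
  structure(list(scores = scores, correct_index = item$correct_index,
                 mode = mode),
            class = "option_scores")
}

#' Multiple-choice cross-entropy loss
#'
#' `-log softmax(scores)[correct]`, computed with a numerically stable
#' log-sum-exp.
#'
#' @param scores An `"option_scores"` object, or a numeric vector (then
#'   `correct_index` must be given).
#' @param correct_index 0-based index of the correct option.
#' @return Scalar loss.
#' @export
mc_loss <- function(scores, correct_index = NULL) {
  if (inherits(scores, "option_scores")) {
    correct_index <- scores$correct_index
    scores <- scores$scores
  }
  if (is.null(correct_index)) stop("'correct_index' required")
  ci <- correct_index + 1L
  if (ci < 1L || ci > length(scores)) stop("invalid correct_index")
  m <- max(scores)
  -(scores[ci] - (m + log(sum(exp(scores - m)))))
}

#' Multiple-choice accuracy of a scorer
#'
#' @param scorer A `"toy_scorer"`.
#' @param items List of multiple-choice items.
#' @param mode Scoring mode, see [score_options()].
#' @return Fraction of items whose top-scoring option is correct.
#' @export
mc_accuracy <- function(scorer, items, mode = "logit") {
  mean(vapply(items, function(it) {
    sc <- score_options(scorer, it, mode)
    which.max(sc$scores) == it$correct_index + 1L
  }, logical(1)))
}

# Flatten items once into index structures for fast batched training:
# for every (item, option, option-position) one entry with the linear index
# into W (prev-token row, realized-token column).
index_mc_items <- function(items, vocab) {
  V <- length(vocab)
  lin <- list(); opt_len <- integer(0)
  k <- 0L
  for (i in seq_along(items)) {
    it <- items[[i]]
    ctx <- match(it$context, vocab)
    if (anyNA(ctx)) stop("context token outside vocabulary")
    for (j in seq_along(it$options)) {
      opt <- match(it$options[[j]], vocab)
      if (anyNA(opt)) stop("option token outside vocabulary")
      seq_idx <- c(ctx, opt)
      pos <- (length(ctx) + 1L):length(seq_idx)
      prev <- seq_idx[pos - 1L]
      k <- k + 1L
      lin[[k]] <- (seq_idx[pos] - 1L) * V + prev
      opt_len[k] <- length(pos)
    }
  }
  list(lin = unlist(lin), opt_id = rep.int(seq_len(k), opt_len),
       n_options = k)
}

#' Train the toy scorer on multiple-choice items
#'
#' Full-batch gradient descent on the mean multiple-choice cross-entropy
#' ([mc_loss()] of the summed-logit option scores).  Deterministic given the
#' inputs; the per-epoch training loss is recorded on the returned scorer.
#' With `epochs = 0` the scorer is returned unchanged.
#'
#' @param scorer A `"toy_scorer"`.
#' @param items Non-empty list of multiple-choice items.
#' @param epochs Number of full-batch epochs.
#' @param lr Learning rate.
#' @param seed Unused by the deterministic full-batch optimizer; kept in the
#'   signature for interface stability with stochastic trainers.
#' @return The trained scorer, with attribute-free `loss_curve` field.
#' @export
train_mc <- function(scorer, items, epochs = 200L, lr = 0.5, seed = 1L) {
  stopifnot(inherits(scorer, "toy_scorer"))
  if (length(items) == 0L) stop("'items' must be non-empty")
  if (epochs == 0L) return(scorer)
  V <- length(scorer$vocab)
  ix <- index_mc_items(items, scorer$vocab)
  n_items <- length(items)
  correct1 <- vapply(items, function(it) it$correct_index + 1L, integer(1))
  loss_curve <- numeric(epochs)
  W <- scorer$W
  for (ep in seq_len(epochs)) {
    entry_scores <- W[ix$lin]
    opt_scores <- as.numeric(rowsum(entry_scores, ix$opt_id))
    # group option scores by item
    loss <- 0
    gvec <- numeric(length(opt_scores))
    off <- 0L
    for (i in seq_len(n_items)) {
      nOpt <- length(items[[i]]$options)
      sc <- opt_scores[(off + 1L):(off + nOpt)]
      m <- max(sc); lse <- m + log(sum(exp(sc - m)))
      p <- exp(sc - lse)
      loss <- loss + (lse - sc[correct1[i]])
      y <- numeric(nOpt); y[correct1[i]] <- 1
      gvec[(off + 1L):(off + nOpt)] <- p - y
      off <- off + nOpt
    }
    loss_curve[ep] <- loss / n_items
    if (!is.finite(loss_curve[ep]))
      stop("non-finite multiple-choice loss during training")
    gentry <- gvec[ix$opt_id]
    gw <- rowsum(gentry, ix$lin)
    gidx <- as.integer(rownames(gw))
    W[gidx] <- W[gidx] - lr * gw[, 1L] / n_items
  }
  scorer$W <- W
  scorer$loss_curve <- c(scorer$loss_curve, loss_curve)
  scorer
}

#' Mean next-token loss of a scorer on a token stream
#'
#' Average `-log softmax` probability of each realized token given its
#' predecessor (positions after the first; the start prediction is scored
#' too when `include_start`).  A uniform-logit scorer attains `log(V)`.
#'
#' @param scorer A `"toy_scorer"`.
#' @param tokens Character token stream of length at least 2.
#' @param include_start Score position 1 from the start vector as well.
#' @return Scalar mean loss (nats).
#' @export
lm_loss <- function(scorer, tokens, include_start = FALSE) {
  idx <- match(tokens, scorer$vocab)
  if (anyNA(idx)) stop("token outside the scorer vocabulary")
  if (length(idx) < 2L) stop("need at least 2 tokens")
  LP <- log_softmax_rows(scorer$W[idx[-length(idx)], , drop = FALSE])
  nll <- -LP[cbind(seq_len(nrow(LP)), idx[-1L])]
  if (include_start) {
    sp <- scorer$start - max(scorer$start)
    sp <- sp - log(sum(exp(sp)))
    nll <- c(-sp[idx[1L]], nll)
  }
  mean(nll)
}

#' Train the toy scorer with the language-modeling objective
#'
#' Full-batch gradient descent on the mean next-token cross-entropy of a
#' token stream (bigram transitions).  Used by the language-modeling-loss
#' control to fine-tune base and task-fine-tuned scorers on common text.
#'
#' @param scorer A `"toy_scorer"`.
#' @param tokens Character token stream.
#' @param epochs,lr Optimization parameters.
#' @return The trained scorer.
#' @export
train_lm <- function(scorer, tokens, epochs = 100L, lr = 1, seed = 1L) {
  idx <- match(tokens, scorer$vocab)
  if (anyNA(idx)) stop("token outside the scorer vocabulary")
  if (length(idx) < 2L) stop("need at least 2 tokens")
  V <- length(scorer$vocab)
  Cnt <- matrix(0, V, V)
  tab <- table(factor(idx[-length(idx)], levels = seq_len(V)),
               factor(idx[-1L], levels = seq_len(V)))
  Cnt[] <- as.numeric(tab)
  rowtot <- rowSums(Cnt)
  n_trans <- sum(rowtot)
  W <- scorer$W
  for (ep in seq_len(epochs)) {
    P <- exp(log_softmax_rows(W))
    grad <- rowtot * P - Cnt
    W <- W - lr * grad / n_trans
  }
  scorer$W <- W
  scorer
}

#' Language-modeling-loss control
#'
#' Checks whether a task-fine-tuned scorer owes its encoding advantage to
#' generically better language modeling: the token stream is split into
#' `folds` contiguous folds; in each fold both scorers are fine-tuned on the
#' training portion with the language-modeling objective and evaluated by
#' mean next-token loss on the held-out portion.  Similar average losses
#' indicate the comparison models do not differ in plain language-modeling
#' ability.
#'
#' @param scorer_base,scorer_ft Two `"toy_scorer"` objects over the same
#'   vocabulary.
#' @param tokens Character token stream (length at least `folds + 1`).
#' @param folds Number of contiguous folds (default 3).
#' @param epochs,lr Training parameters per fold.
#' @return Object of class `"lm_loss_control"`: data frame `per_fold`
#'   (`fold`, `loss_base`, `loss_ft`), plus `avg_base`, `avg_ft`,
#'   `difference` (`avg_ft - avg_base`).
#' @export
lm_loss_control <- function(scorer_base, scorer_ft, tokens, folds = 3L,
                            epochs = 100L, lr = 1) {
  if (length(tokens) < folds + 1L) stop("token stream too short")
  if (!identical(scorer_base$vocab, scorer_ft$vocab))
    stop("scorers must share a vocabulary")
  splits <- contiguous_kfold(length(tokens), folds)
  res <- lapply(splits, function(sp) {
    train_tok <- tokens[sp$train]
    test_tok <- tokens[sp$test]
    b <- train_lm(scorer_base, train_tok, epochs = epochs, lr = lr)
    f <- train_lm(scorer_ft, train_tok, epochs = epochs, lr = lr)
    c(loss_base = lm_loss(b, test_tok), loss_ft = lm_loss(f, test_tok))
  })
  per_fold <- data.frame(fold = seq_len(folds),
                         loss_base = vapply(res, `[[`, numeric(1), "loss_base"),
                         loss_ft = vapply(res, `[[`, numeric(1), "loss_ft"))
  structure(list(per_fold = per_fold,
                 avg_base = mean(per_fold$loss_base),
                 avg_ft = mean(per_fold$loss_ft),
                 difference = mean(per_fold$loss_ft) - mean(per_fold$loss_base)),
            class = "lm_loss_control")
}

#' @export
print.lm_loss_control <- function(x, ...) {
  cat(sprintf("LM-loss control: base %.4f, fine-tuned %.4f, difference %+.4f nats\n",
              x$avg_base, x$avg_ft, x$difference))
  invisible(x)
}
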