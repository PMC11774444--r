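# Proposer/verifier corpus-difference discovery.  A proposer backend drafts
# natural-language hypotheses about how corpus D0 differs from corpus D1; a
# verifier backend judges each hypothesis on individual held-out sentences.
# Validity is the difference in verified fractions (D0 minus D1), estimated
# across cross-validation folds, with label-permutation p-values.  LLM
# backends plug in through the same function contracts as the deterministic
# mocks shipped here.

#' Mock hypothesis proposer
#'
#' Returns a proposer backend: a function
#' `(samples_D0, samples_D1, n_hypotheses)` producing hypothesis strings of
#' the form `contain the word '<token>'` for the tokens whose
#' sentence-frequency in the D0 samples most exceeds that in the D1 samples
#' (ties broken lexicographically).  Deterministic.
#'
#' @return A proposer function.
#' @export
mock_proposer <- function() {
  function(samples_D0, samples_D1, n_hypotheses) {
    toks0 <- lapply(strsplit(samples_D0, " ", fixed = TRUE), unique)
    toks1 <- lapply(strsplit(samples_D1, " ", fixed = TRUE), unique)
    vocab <- sort(unique(c(unlist(toks0), unlist(toks1))))
    f0 <- vapply(vocab, function(tk)
      mean(vapply(toks0, function(s) tk %in% s, logical(1))), numeric(1))
    f1 <- vapply(vocab, function(tk)
      mean(vapply(toks1, function(s) tk %in% s, logical(1))), numeric(1))
    ord <- order(-(f0 - f1), vocab)
    sprintf("contain the word '%s'",
            vocab[ord][seq_len(min(n_hypotheses, length(vocab)))])
  }
}

#' Mock hypothesis verifier
#'
#' Returns a verifier backend: a function `(hypothesis_text, sentence)`
#' returning `TRUE` iff the token quoted in a
#' `contain the word '<token>'` hypothesis occurs in the sentence.
#' Deterministic.
#'
#' @return A verifier function.
#' @export
mock_verifier <- function() {
  function(hypothesis_text, sentence) {
    m <- regmatches(hypothesis_text,
                    regexec("'([^']+)'", hypothesis_text))[[1L]]
    if (length(m) < 2L) return(FALSE)
    m[2L] %in% strsplit(sentence, " ", fixed = TRUE)[[1L]]
  }
}

#' Random verifier (null backend)
#'
#' A verifier whose judgment of each (hypothesis, sentence) pair is an
#' independent coin flip, deterministic given the seed: useful for
#' calibration checks where validity should be null.
#'
#' @param seed Integer seed.
#' @param prob Probability of a `TRUE` judgment.
#' @return A verifier function.
#' @export
random_verifier <- function(seed, prob = 0.5) {
  force(seed); force(prob)
  function(hypothesis_text, sentence) {
    s <- substream_seed(seed, paste0(hypothesis_text, "\r", sentence))
    with_substream(s, "random_verifier", stats::runif(1)) < prob
  }
}

verify_all <- function(verifier, h, sentences) {
  vapply(sentences, function(s) isTRUE(verifier(h, s)), logical(1),
         USE.NAMES = FALSE)
}

#' Held-out validity of a hypothesis
#'
#' `validity = mean(verifier true on D0 held-out) - mean(verifier true on D1
#' held-out)`, in `[-1, 1]`: 1 for a perfect separator, 0 for an
#' uninformative hypothesis, negative when the hypothesis is more true of
#' the well-predicted corpus.
#'
#' @param verifier A verifier function (see [mock_verifier()]).
#' @param h Hypothesis text.
#' @param D0_held,D1_held Non-empty character vectors of held-out sentences.
#' @return Scalar validity.
#' @export
compute_validity <- function(verifier, h, D0_held, D1_held) {
  if (length(D0_held) == 0L || length(D1_held) == 0L)
    stop("held-out sets must be non-empty")
  mean(verify_all(verifier, h, D0_held)) - mean(verify_all(verifier, h, D1_held))
}

# Permutation p for a validity given pooled booleans; add-one estimator.
perm_pvalue_from_bools <- function(v0, v1, n_perm, seed, stream = "validity_perm") {
  obs <- mean(v0) - mean(v1)
  pool <- c(v0, v1)
  n0 <- length(v0); n <- length(pool)
  tot <- sum(pool)
  ge <- with_substream(seed, stream, {
    idx <- vapply(seq_len(n_perm), function(b) sample.int(n, n0),
                  integer(n0))
    s <- colSums(matrix(pool[idx], n0, n_perm))
    sum(s / n0 - (tot - s) / (n - n0) >= obs - 1e-12)
  })
  (1 + ge) / (n_perm + 1)
}

#' Permutation p-value for a hypothesis validity
#'
#' Permutes the corpus labels over the pooled held-out sentences and reports
#' the add-one empirical p-value
#' `(1 + #\{permuted validity >= observed\}) / (n_perm + 1)` (one-sided:
#' large validity means D0-specific).
#'
#' @inheritParams compute_validity
#' @param n_perm Number of permutations, at least 1.
#' @param seed Integer seed.
#' @return Scalar p-value in `(0, 1]`.
#' @export
validity_pvalue <- function(verifier, h, D0_held, D1_held, n_perm, seed) {
  if (n_perm < 1L) stop("'n_perm' must be >= 1")
  if (length(D0_held) == 0L || length(D1_held) == 0L)
    stop("held-out sets must be non-empty")
  v0 <- verify_all(verifier, h, D0_held)
  v1 <- verify_all(verifier, h, D1_held)
  perm_pvalue_from_bools(v0, v1, n_perm, seed)
}

#' Cross-validated hypothesis discovery
#'
#' Runs the proposer/verifier loop across contiguous cross-validation folds
#' of the contrast corpora: within each fold, hypotheses are proposed from
#' the proposal split and their validity is computed on that fold's held-out
#' split.  Hypotheses are deduplicated by exact text; the final validity is
#' the mean over the folds where a hypothesis was evaluated, and its p-value
#' comes from label permutations applied within each evaluated fold.
#' Ranking is by descending validity, ties by ascending p-value then
#' lexicographic text.  With `folds = 1` (degenerate mode) proposal and
#' validation both use the full corpora, reducing to [compute_validity()].
#'
#' @param proposer Proposer backend (see [mock_proposer()]).
#' @param verifier Verifier backend (see [mock_verifier()]).
#' @param corpora A `"contrast_corpora"` object, or a list with character
#'   vectors `D0` and `D1`.
#' @param folds Number of cross-validation folds (default 3).
#' @param n_hypotheses Hypotheses requested from the proposer per fold.
#' @param n_perm Label permutations for each p-value.
#' @param seed Integer seed.
#' @return A data frame of class `"hypothesis_ranking"` with columns `rank`,
#'   `hypothesis`, `validity`, `p_value`, `n_folds`, `fold_validities`
#'   (semicolon-joined).
#' @export
cross_validated_discovery <- function(proposer, verifier, corpora,
                                      folds = 3L, n_hypotheses = 10L,
                                      n_perm = 999L, seed = 1L) {
  d0 <- if (inherits(corpora, "contrast_corpora")) corpora$D0$text else corpora$D0
  d1 <- if (inherits(corpora, "contrast_corpora")) corpora$D1$text else corpora$D1
  if (folds > 1L && (length(d0) < folds || length(d1) < folds))
    stop("each corpus must contain at least 'folds' sentences")

  if (folds == 1L) {
    fold_sets <- list(list(h0 = d0, h1 = d1, p0 = d0, p1 = d1))
  } else {
    s0 <- contiguous_kfold(length(d0), folds)
    s1 <- contiguous_kfold(length(d1), folds)
    fold_sets <- lapply(seq_len(folds), function(f)
      list(h0 = d0[s0[[f]]$test], h1 = d1[s1[[f]]$test],
           p0 = d0[s0[[f]]$train], p1 = d1[s1[[f]]$train]))
  }

  # hypothesis -> list of per-fold boolean verdicts on held-out sentences
  evals <- list()
  any_proposed <- FALSE
  for (f in seq_along(fold_sets)) {
    fs <- fold_sets[[f]]
    hyps <- unique(proposer(fs$p0, fs$p1, n_hypotheses))
    hyps <- hyps[nzchar(hyps)]
    if (length(hyps) == 0L) next
    any_proposed <- TRUE
    for (h in hyps) {
      rec <- evals[[h]]
      if (is.null(rec)) rec <- list()
      rec[[length(rec) + 1L]] <- list(v0 = verify_all(verifier, h, fs$h0),
                                      v1 = verify_all(verifier, h, fs$h1))
      evals[[h]] <- rec
    }
  }
  if (!any_proposed) stop("proposer returned zero hypotheses in every fold")

  hyps <- names(evals)
  fold_vals <- lapply(evals, function(rec)
    vapply(rec, function(e) mean(e$v0) - mean(e$v1), numeric(1)))
  validity <- vapply(fold_vals, mean, numeric(1))
  p_value <- vapply(hyps, function(h) {
    rec <- evals[[h]]
    obs <- mean(vapply(rec, function(e) mean(e$v0) - mean(e$v1), numeric(1)))
    ge <- with_substream(substream_seed(seed, h), "discovery_perm", {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        pv <- vapply(rec, function(e) {
          pool <- c(e$v0, e$v1); n0 <- length(e$v0)
          idx <- sample.int(length(pool), n0)
          s <- sum(pool[idx])
          s / n0 - (sum(pool) - s) / (length(pool) - n0)
        }, numeric(1))
        if (mean(pv) >= obs) cnt <- cnt + 1L
      }
      cnt
    })
    (1 + ge) / (n_perm + 1)
  }, numeric(1))

  ord <- order(-validity, p_value, hyps)
  out <- data.frame(rank = seq_along(hyps),
                    hypothesis = hyps[ord],
                    validity = validity[ord],
                    p_value = p_value[ord],
                    n_folds = vapply(fold_vals, length, integer(1))[ord],
                    fold_validities = vapply(fold_vals, function(v)
                      paste(sprintf("%.4f", v), collapse = ";"), character(1))[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("hypothesis_ranking", "data.frame")
  out
}

#' @export
print.hypothesis_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("Hypothesis ranking (%d hypotheses)\n", nrow(x)))
  print.data.frame(utils::head(x[, c("rank", "hypothesis", "validity",
                                     "p_value")], n),
                   row.names = FALSE, digits = 3)
  invisible(x)
}
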