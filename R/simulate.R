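# Synthetic-data generator: a word stream partitioned into sentences, a
# context-dependent embedding for every word, and sensor responses produced by
# a known linear forward model plus Gaussian noise, with optional planted
# structure (a word category whose responses carry residual variance the
# embeddings cannot explain, marked by a keyword token so that corpus-level
# discovery has a recoverable ground truth).

#' Simulation configuration
#'
#' Bundles and validates every parameter of the synthetic dataset.  The
#' defaults mirror the analysis conditions of the pipeline: a 19-word
#' preceding context feeding each word's embedding, and a 0--500 ms response
#' epoch in 25 ms bins (20 bins).
#'
#' @param n_words Total number of word events.
#' @param n_sentences Number of contiguous sentences the stream is split into.
#' @param n_channels Number of sensor channels.
#' @param n_timebins Number of 25 ms response bins per word (default 20,
#'   i.e. 0--500 ms after word onset).
#' @param embed_dim Embedding dimensionality.
#' @param context_len Number of preceding words mixed into each word's
#'   embedding (default 19).
#' @param context_mix Weight of the decaying context sum relative to the
#'   word's own token vector (0 disables context dependence).
#' @param context_decay Geometric decay applied per step back in the context.
#' @param vocab_size Number of distinct synthetic tokens.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian sensor noise, in
#'   response units.
#' @param planted_effect Root-mean-square magnitude, in response units, of the
#'   structured residual added to planted-category words (0 disables it).
#' @param planted_fraction Fraction of sentences receiving the planted
#'   category, in `[0, 1]`.
#' @param n_repetitions Number of identically-stimulated recordings available
#'   for averaging.
#' @param seed Master seed; all randomness flows from it via named
#'   sub-streams (see [substream_seed()]).
#' @return An object of class `"sim_config"` (a validated list).
#' @seealso [generate_word_stream()], [generate_embeddings()],
#'   [generate_responses()]
#' @examples
#' cfg <- sim_config(n_words = 100, n_sentences = 10, seed = 1)
#' cfg$n_timebins
#' @export
sim_config <- function(n_words = 2000L, n_sentences = 250L, n_channels = 30L,
                       n_timebins = 20L, embed_dim = 20L, context_len = 19L,
                       context_mix = 0.5, context_decay = 0.7,
                       vocab_size = 50L, noise_sd = 1, planted_effect = 0,
                       planted_fraction = 0, n_repetitions = 1L, seed = 1L) {
  cfg <- list(n_words = as.integer(n_words),
              n_sentences = as.integer(n_sentences),
              n_channels = as.integer(n_channels),
              n_timebins = as.integer(n_timebins),
              embed_dim = as.integer(embed_dim),
              context_len = as.integer(context_len),
              context_mix = as.numeric(context_mix),
              context_decay = as.numeric(context_decay),
              vocab_size = as.integer(vocab_size),
              noise_sd = as.numeric(noise_sd),
              planted_effect = as.numeric(planted_effect),
              planted_fraction = as.numeric(planted_fraction),
              n_repetitions = as.integer(n_repetitions),
              seed = as.integer(seed))
  counts <- c("n_words", "n_sentences", "n_channels", "n_timebins",
              "embed_dim", "vocab_size", "n_repetitions")
  for (f in counts)
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(sprintf("'%s' must be a positive count", f))
  if (cfg$context_len < 0L) stop("'context_len' must be >= 0")
  if (cfg$n_sentences > cfg$n_words)
    stop("invalid config: n_sentences > n_words")
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1)
    stop("'planted_fraction' must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (cfg$planted_effect < 0) stop("'planted_effect' must be >= 0")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d words in %d sentences; %d channels x %d time bins\n",
              x$n_words, x$n_sentences, x$n_channels, x$n_timebins))
  cat(sprintf("  embed_dim %d, context %d words (mix %.2f, decay %.2f)\n",
              x$embed_dim, x$context_len, x$context_mix, x$context_decay))
  cat(sprintf("  noise_sd %.3g, planted_effect %.3g on %.0f%% of sentences, seed %d\n",
              x$noise_sd, x$planted_effect, 100 * x$planted_fraction, x$seed))
  invisible(x)
}

planted_keyword_token <- function() "wplanted"

#' Generate the synthetic word stream
#'
#' Partitions `n_words` events into `n_sentences` contiguous sentences
#' (sentence sizes differ by at most one, earlier sentences take the
#' remainder) and assigns each word a token from the synthetic vocabulary.
#' `floor(planted_fraction * n_sentences)` sentences are planted: one of
#' their words is replaced by the marker keyword and every word in them
#' carries the `"planted"` category flag.  Words independently receive
#' `"social"` and `"physical"` annotation flags at a fixed low rate so that
#' category-wise analyses have non-planted categories to work with.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `"word_events"` with columns `word_id`
#'   (consecutive from 0 in presentation order), `token`, `sentence_id`
#'   (0-based, non-decreasing), `position` (0-based position in sentence) and
#'   `categories` (comma-separated flags, possibly empty).
#' @examples
#' ev <- generate_word_stream(sim_config(n_words = 20, n_sentences = 4, seed = 1))
#' table(ev$sentence_id)
#' @export
generate_word_stream <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_words; ns <- config$n_sentences
  sizes <- rep(n %/% ns, ns)
  rem <- n %% ns
  if (rem > 0L) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sentence_id <- rep(seq_len(ns) - 1L, times = sizes)
  position <- unlist(lapply(sizes, function(s) seq_len(s) - 1L), use.names = FALSE)

  tok_idx <- with_substream(config$seed, "tokens",
                            sample.int(config$vocab_size, n, replace = TRUE))
  token <- sprintf("t%03d", tok_idx)

  n_planted <- floor(config$planted_fraction * ns)
  planted_sents <- integer(0)
  if (n_planted >= 1L) {
    planted_sents <- with_substream(config$seed, "planted",
                                    sort(sample.int(ns, n_planted)) - 1L)
    kw_pos <- with_substream(config$seed, "planted_keyword_pos",
                             vapply(sizes[planted_sents + 1L],
                                    function(s) sample.int(s, 1L), integer(1)))
    for (i in seq_along(planted_sents)) {
      rows <- which(sentence_id == planted_sents[i])
      token[rows[kw_pos[i]]] <- planted_keyword_token()
    }
  }

  soc <- with_substream(config$seed, "cat_social", stats::runif(n) < 0.15)
  phy <- with_substream(config$seed, "cat_physical", stats::runif(n) < 0.15)
  planted_flag <- sentence_id %in% planted_sents
  categories <- vapply(seq_len(n), function(i) {
    f <- c(if (soc[i]) "social", if (phy[i]) "physical",
           if (planted_flag[i]) "planted")
    paste(f, collapse = ",")
  }, character(1))

  structure(data.frame(word_id = seq_len(n) - 1L, token = token,
                       sentence_id = sentence_id, position = position,
                       categories = categories, stringsAsFactors = FALSE),
            class = c("word_events", "data.frame"))
}

# Token -> row index in the synthetic embedding vocabulary (keyword gets the
# extra final row).
token_indices <- function(tokens, vocab_size) {
  idx <- match(tokens, sprintf("t%03d", seq_len(vocab_size)))
  idx[tokens == planted_keyword_token()] <- vocab_size + 1L
  if (anyNA(idx)) stop("unknown token in word stream")
  idx
}

#' Generate context-dependent word embeddings
#'
#' Each word's embedding is its token vector plus a geometrically decaying
#' sum over the token vectors of the preceding `context_len` words, the
#' synthetic analogue of feeding a language model the current word together
#' with its preceding 19-word context.  Row `w` therefore depends only on
#' tokens `w - context_len ... w`; with `context_mix = 0` it reduces to the
#' token vector alone, and the first word of the stream depends on its own
#' token only.
#'
#' @param events A `"word_events"` data frame from [generate_word_stream()].
#' @param config The matching [sim_config()].
#' @param layer_index Integer tag stored on the result (synthetic "layer").
#'   Layers other than 1 draw different token vectors, emulating
#'   representations from different model depths.
#' @return A numeric matrix `n_words x embed_dim` with attribute
#'   `layer_index`.
#' @export
generate_embeddings <- function(events, config, layer_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(events) || nrow(events) == 0L)
    stop("'events' must be a non-empty word_events data frame")
  n <- nrow(events)
  vocab <- with_substream(config$seed, paste0("token_vectors_layer", layer_index),
                          matrix(stats::rnorm((config$vocab_size + 1L) * config$embed_dim),
                                 config$vocab_size + 1L, config$embed_dim))
  V <- vocab[token_indices(events$token, config$vocab_size), , drop = FALSE]
  L <- V
  if (config$context_mix != 0 && config$context_len > 0L) {
    for (j in seq_len(min(config$context_len, n - 1L))) {
      w <- config$context_mix * config$context_decay^j
      L[(j + 1L):n, ] <- L[(j + 1L):n, ] + w * V[1:(n - j), , drop = FALSE]
    }
  }
  attr(L, "layer_index") <- as.integer(layer_index)
  L
}

#' Ground truth of the synthetic forward model
#'
#' Draws the true linear map from embeddings to responses (weights and bias),
#' the spatial patterns of the planted residual, and records which word ids
#' are planted.  The planted residual for word `w` is
#' `planted_effect * (P1 + a_w * P2) / sqrt(2)` where `P1`, `P2` are fixed
#' unit-mean-square sensor/time patterns and `a_w ~ N(0, 1)` is a
#' word-specific amplitude, so its mean per-cell power equals
#' `planted_effect^2`: a category-mean component that a category-aware model
#' could in principle predict, plus structured variance that no function of
#' the embeddings can.
#'
#' @param config A [sim_config()].
#' @param events The matching word stream.
#' @return An object of class `"ground_truth"`: list with `true_weights`
#'   (array `embed_dim x n_channels x n_timebins`), `true_bias`
#'   (`n_channels x n_timebins`), `pattern_mean`, `pattern_var` (planted
#'   residual patterns), `planted_word_ids`, `planted_keyword`, `noise_sd`.
#' @export
make_ground_truth <- function(config, events) {
  stopifnot(inherits(config, "sim_config"))
  C <- config$n_channels; Tb <- config$n_timebins; d <- config$embed_dim
  W <- with_substream(config$seed, "weights",
                      array(stats::rnorm(d * C * Tb, sd = 1 / sqrt(d)), c(d, C, Tb)))
  b <- with_substream(config$seed, "bias",
                      matrix(stats::rnorm(C * Tb, sd = 0.1), C, Tb))
  unitize <- function(z) z / sqrt(mean(z^2))
  P1 <- with_substream(config$seed, "planted_pattern_mean",
                       unitize(matrix(stats::rnorm(C * Tb), C, Tb)))
  P2 <- with_substream(config$seed, "planted_pattern_var",
                       unitize(matrix(stats::rnorm(C * Tb), C, Tb)))
  planted <- events$word_id[grepl("(^|,)planted(,|$)", events$categories)]
  structure(list(true_weights = W, true_bias = b,
                 pattern_mean = P1, pattern_var = P2,
                 planted_word_ids = planted,
                 planted_keyword = planted_keyword_token(),
                 noise_sd = config$noise_sd),
            class = "ground_truth")
}

#' Generate sensor responses from the forward model
#'
#' Builds `M[w, c, t] = sum_d L[w, d] W[d, c, t] + b[c, t] + noise + planted
#' residual`, with i.i.d. `N(0, noise_sd^2)` noise.  Planted words (per the
#' ground truth) additionally receive the structured residual described in
#' [make_ground_truth()]; its word-specific amplitudes are stimulus-locked
#' (shared across repetitions) while noise is redrawn per repetition.
#'
#' @param embeddings Matrix from [generate_embeddings()].
#' @param truth A `"ground_truth"` object.
#' @param config The matching [sim_config()].
#' @param repetition Integer naming the noise sub-stream, so repeated
#'   recordings differ only in noise.
#' @return A numeric array `n_words x n_channels x n_timebins` of class
#'   `"response_tensor"` with attribute `bin_width = 25` (ms).
#' @export
generate_responses <- function(embeddings, truth, config, repetition = 1L) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  n <- nrow(embeddings)
  C <- config$n_channels; Tb <- config$n_timebins; d <- config$embed_dim
  if (ncol(embeddings) != d || dim(truth$true_weights)[1] != d)
    stop("dimension mismatch between embeddings and ground truth")
  Wmat <- matrix(truth$true_weights, d, C * Tb)
  M <- embeddings %*% Wmat
  M <- sweep(M, 2L, as.numeric(truth$true_bias), "+")
  if (config$noise_sd > 0)
    M <- M + with_substream(config$seed, paste0("noise_rep", repetition),
                            matrix(stats::rnorm(n * C * Tb, sd = config$noise_sd),
                                   n, C * Tb))
  if (config$planted_effect > 0 && length(truth$planted_word_ids) > 0L) {
    amp <- with_substream(config$seed, "planted_amplitude",
                          stats::rnorm(length(truth$planted_word_ids)))
    p1 <- as.numeric(truth$pattern_mean); p2 <- as.numeric(truth$pattern_var)
    rows <- truth$planted_word_ids + 1L
    M[rows, ] <- M[rows, ] +
      config$planted_effect / sqrt(2) * (rep(1, length(rows)) %o% p1 + amp %o% p2)
  }
  structure(array(M, c(n, C, Tb)), class = "response_tensor", bin_width = 25)
}

#' Average repeated recordings
#'
#' Element-wise mean of identically-shaped response tensors; with independent
#' noise across repetitions the noise variance of the result scales as
#' `1 / n_repetitions`, the standard SNR-enhancement step for repeated
#' presentations of the same stimulus.
#'
#' @param tensors Non-empty list of arrays of identical shape.
#' @return An array of the common shape (class `"response_tensor"`).
#' @export
average_repetitions <- function(tensors) {
  if (!is.list(tensors) || length(tensors) == 0L)
    stop("'tensors' must be a non-empty list")
  d1 <- dim(tensors[[1L]])
  for (x in tensors)
    if (!identical(dim(x), d1)) stop("shape mismatch across repetitions")
  out <- Reduce(`+`, tensors) / length(tensors)
  structure(out, class = "response_tensor",
            bin_width = attr(tensors[[1L]], "bin_width"))
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_word_stream()],
#' [generate_embeddings()], [make_ground_truth()] and [generate_responses()]
#' for `n_repetitions` recordings, returning the repetition-averaged tensor.
#'
#' @param config A [sim_config()].
#' @return List with `events`, `embeddings`, `truth`, `responses`
#'   (averaged), and `repetitions` (the individual tensors).
#' @export
simulate_dataset <- function(config) {
  events <- generate_word_stream(config)
  L <- generate_embeddings(events, config)
  truth <- make_ground_truth(config, events)
  reps <- lapply(seq_len(config$n_repetitions), function(r)
    generate_responses(L, truth, config, repetition = r))
  list(events = events, embeddings = L, truth = truth,
       responses = average_repetitions(reps), repetitions = reps)
}

#' Generate a toy multiple-choice dataset
#'
#' Items consist of a token context and `n_options` candidate continuations,
#' exactly one correct.  The planted rule makes correctness decidable from
#' token statistics alone: the correct option reuses the context by opening
#' with the context's final token, while distractor options open with a
#' different token.  A bigram-level scorer can therefore learn the task,
#' and a constant-choice baseline scores `1 / n_options` in expectation.
#' With `n_options = 2` the items mirror a physical-commonsense-style binary
#' format; with `n_options = 3` a social-reasoning-style ternary format.
#'
#' @param n_items Number of items (0 allowed).
#' @param n_options Number of options per item, at least 2.
#' @param seed Integer seed.
#' @param vocab_size Token vocabulary size.
#' @param context_len Context length in tokens (>= 1).
#' @param option_len Option length in tokens (>= 1).  The default of 1 keeps
#'   the planted rule fully expressible by a bigram scorer; longer options
#'   append rule-irrelevant tokens.
#' @return List of items, each a list with `context` (character vector),
#'   `options` (list of character vectors) and `correct_index` (0-based).
#' @export
generate_mc_dataset <- function(n_items, n_options, seed,
                                vocab_size = 25L, context_len = 5L,
                                option_len = 1L) {
  if (n_options < 2L) stop("'n_options' must be >= 2")
  if (n_items < 0L) stop("'n_items' must be >= 0")
  stopifnot(context_len >= 1L, option_len >= 1L, vocab_size >= 2L)
  toks <- sprintf("t%03d", seq_len(vocab_size))
  with_substream(seed, "mc_items", {
    lapply(seq_len(n_items), function(i) {
      ctx <- toks[sample.int(vocab_size, context_len, replace = TRUE)]
      last <- ctx[context_len]
      correct <- c(last,
                   if (option_len > 1L)
                     toks[sample.int(vocab_size, option_len - 1L, replace = TRUE)])
      opts <- vector("list", n_options)
      ci <- sample.int(n_options, 1L)
      for (j in seq_len(n_options)) {
        if (j == ci) { opts[[j]] <- correct; next }
        first <- toks[sample(setdiff(seq_len(vocab_size), match(last, toks)), 1L)]
        opts[[j]] <- c(first,
                       if (option_len > 1L)
                         toks[sample.int(vocab_size, option_len - 1L, replace = TRUE)])
      }
      list(context = ctx, options = opts, correct_index = ci - 1L)
    })
  })
}

#' Reconstruct sentence texts from a word stream
#'
#' @param events A `"word_events"` data frame.
#' @return Character vector of sentences (tokens joined by spaces), named by
#'   `sentence_id`.
#' @export
sentence_texts <- function(events) {
  sids <- sort(unique(events$sentence_id))
  out <- vapply(sids, function(s)
    paste(events$token[events$sentence_id == s], collapse = " "), character(1))
  names(out) <- as.character(sids)
  out
}
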