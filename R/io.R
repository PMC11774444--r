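# Format readers and writers.  Tables are UTF-8 TSV with a header line;
# sentence corpora are one sentence per line; multiple-choice items are
# JSON; arrays (embeddings, response tensors, weights) live in RDS
# containers, one hierarchical file per stage.

#' Write / read word events as TSV
#'
#' Columns: `word_id  token  sentence_id  position  categories` (categories
#' comma-separated, empty allowed).
#'
#' @param events A `"word_events"` data frame.
#' @param path Output file path.
#' @return `write_word_events` returns `path` invisibly; `read_word_events`
#'   returns the `"word_events"` data frame.
#' @export
write_word_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_word_events
#' @export
read_word_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character", "integer",
                                         "integer", "character"),
                          quote = "", na.strings = NULL,
                          fileEncoding = "UTF-8")
  df$categories[is.na(df$categories)] <- ""
  structure(df, class = c("word_events", "data.frame"))
}

#' Write / read an array container
#'
#' Stores one or more named numeric arrays (e.g. `embeddings`, `responses`,
#' `true_weights`) in a single RDS container file, row order following
#' word-id order.
#'
#' @param arrays Named list of arrays, or a single array.
#' @param path File path (conventionally `.rds`).
#' @return `write_arrays` returns `path` invisibly; `read_arrays` the named
#'   list.
#' @export
write_arrays <- function(arrays, path) {
  if (!is.list(arrays)) arrays <- list(values = arrays)
  saveRDS(arrays, path)
  invisible(path)
}

#' @rdname write_arrays
#' @export
read_arrays <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("not a readable array container: %s", path)))
  if (!is.list(x)) stop(sprintf("array container has unexpected layout: %s", path))
  x
}

#' Write / read multiple-choice items as JSON
#'
#' A JSON list of objects `{context, options, correct_index}` with 0-based
#' `correct_index`, matching [generate_mc_dataset()].
#'
#' @param items List of items.
#' @param path File path.
#' @export
write_mc_items <- function(items, path) {
  jsonlite::write_json(lapply(items, function(it)
    list(context = it$context, options = it$options,
         correct_index = it$correct_index)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_mc_items
#' @export
read_mc_items <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(it)
    list(context = unlist(it$context),
         options = lapply(it$options, unlist),
         correct_index = as.integer(it$correct_index)))
}

#' Write sentence corpora
#'
#' One sentence per line, UTF-8.
#'
#' @param sentences Character vector.
#' @param path File path.
#' @export
write_sentences <- function(sentences, path) {
  writeLines(sentences, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_sentences
#' @export
read_sentences <- function(path) readLines(path, encoding = "UTF-8")

default_config <- function() {
  list(seed = 1L,
       sim = list(n_words = 2000L, n_sentences = 250L, n_channels = 30L,
                  n_timebins = 20L, embed_dim = 20L, context_len = 19L,
                  context_mix = 0.5, context_decay = 0.7, vocab_size = 50L,
                  noise_sd = 1, planted_effect = 3, planted_fraction = 0.25,
                  n_repetitions = 1L),
       encoding = list(folds = 10L, lambda_grid = 10^(-4:4),
                       inner_folds = 5L, lambda_per_channel = FALSE),
       divergence = list(alpha = 0.001, top_n = 100L, pool = "cell"),
       discovery = list(enabled = TRUE, folds = 3L, n_hypotheses = 10L,
                        n_perm = 999L),
       comparison = list(enabled = TRUE, n_perm = 10000L, alpha = 0.05,
                         category = "planted", strength = 1,
                         score_mode = "logit"))
}

merge_validate <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop(sprintf("config block '%s' must be a mapping", path))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key(s): %s",
                 paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                        collapse = ", ")))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- merge_validate(defaults[[k]], user[[k]],
                                      paste0(path, ".", k))
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Assemble and validate a pipeline configuration
#'
#' Fills defaults for every stage block (encoding folds 10, divergence gate
#' alpha 0.001, top-100 corpora, 3 discovery folds, 10,000 comparison
#' permutations), validates all stage preconditions before any stage runs,
#' and rejects unknown keys.
#'
#' @param ... Named stage blocks (`seed`, `sim`, `encoding`, `divergence`,
#'   `discovery`, `comparison`), each a list of overrides.
#' @return A validated list of class `"pipeline_config"`.
#' @examples
#' cfg <- pipeline_config(seed = 7, sim = list(n_words = 400, n_sentences = 50))
#' cfg$encoding$folds
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  cfg <- merge_validate(default_config(), user)
  # type normalization
  cfg$seed <- as.integer(cfg$seed)
  for (f in c("n_words", "n_sentences", "n_channels", "n_timebins",
              "embed_dim", "context_len", "vocab_size", "n_repetitions"))
    cfg$sim[[f]] <- as.integer(cfg$sim[[f]])
  cfg$encoding$folds <- as.integer(cfg$encoding$folds)
  cfg$encoding$inner_folds <- as.integer(cfg$encoding$inner_folds)
  cfg$encoding$lambda_grid <- as.numeric(cfg$encoding$lambda_grid)
  cfg$divergence$top_n <- as.integer(cfg$divergence$top_n)
  cfg$discovery$folds <- as.integer(cfg$discovery$folds)
  cfg$discovery$n_hypotheses <- as.integer(cfg$discovery$n_hypotheses)
  cfg$discovery$n_perm <- as.integer(cfg$discovery$n_perm)
  cfg$comparison$n_perm <- as.integer(cfg$comparison$n_perm)
  # stage preconditions, checked up front
  do.call(sim_config, c(cfg$sim, list(seed = cfg$seed)))
  if (cfg$encoding$folds < 2L) stop("encoding folds must be >= 2")
  if (cfg$encoding$inner_folds < 2L) stop("encoding inner_folds must be >= 2")
  if (length(cfg$encoding$lambda_grid) == 0L ||
      any(cfg$encoding$lambda_grid < 0))
    stop("encoding lambda_grid must be non-empty with values >= 0")
  if (cfg$divergence$alpha <= 0 || cfg$divergence$alpha >= 1)
    stop("divergence alpha must be in (0, 1)")
  if (!cfg$divergence$pool %in% c("cell", "channel"))
    stop("divergence pool must be 'cell' or 'channel'")
  if (cfg$divergence$top_n < 1L) stop("divergence top_n must be >= 1")
  if (cfg$discovery$folds < 1L) stop("discovery folds must be >= 1")
  if (cfg$discovery$n_perm < 1L) stop("discovery n_perm must be >= 1")
  if (cfg$comparison$n_perm < 1L) stop("comparison n_perm must be >= 1")
  if (cfg$comparison$alpha <= 0 || cfg$comparison$alpha >= 1)
    stop("comparison alpha must be in (0, 1)")
  if (!cfg$comparison$score_mode %in% c("logit", "logprob"))
    stop("comparison score_mode must be 'logit' or 'logprob'")
  structure(cfg, class = "pipeline_config")
}

#' Load / save a pipeline configuration (YAML)
#'
#' `load_config` parses a YAML file, fills defaults, validates every stage
#' block and rejects unknown keys; `save_config` writes a configuration
#' back so that load -> save -> load round-trips identically.
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(pipeline_config, user)
}

#' @rdname load_config
#' @param config A `"pipeline_config"` to write.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}
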