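# Methods for the fitted encoding model.

#' @export
print.meg_encoding <- function(x, ...) {
  d <- x$dims
  cat("Time-resolved ridge encoding model\n")
  cat(sprintf("  %d words, %d channels x %d time bins, %d embedding dims\n",
              d["n_words"], d["n_channels"], d["n_timebins"], d["embed_dim"]))
  cat(sprintf("  %d contiguous folds, lambda grid [%g, %g]\n",
              length(x$splits), min(x$lambda_grid), max(x$lambda_grid)))
  cat(sprintf("  mean held-out correlation: %.4f\n",
              mean(x$correlations, na.rm = TRUE)))
  invisible(x)
}

#' Summarize a fitted encoding model
#'
#' @param object A `"meg_encoding"` fit.
#' @param ... Unused.
#' @return A `"summary.meg_encoding"` object: per-timebin mean held-out
#'   correlation, the range of selected penalties, and overall mean r.
#' @export
summary.meg_encoding <- function(object, ...) {
  per_bin <- colMeans(object$correlations, na.rm = TRUE)
  bw <- attr(object$predicted, "bin_width")
  if (is.null(bw)) bw <- 25
  structure(list(per_bin_r = per_bin,
                 bin_width = bw,
                 mean_r = mean(object$correlations, na.rm = TRUE),
                 lambda_range = range(object$chosen_lambdas),
                 dims = object$dims),
            class = "summary.meg_encoding")
}

#' @export
print.summary.meg_encoding <- function(x, ...) {
  cat("Encoding model summary\n")
  cat(sprintf("  mean held-out r: %.4f; selected lambda in [%g, %g]\n",
              x$mean_r, x$lambda_range[1], x$lambda_range[2]))
  df <- data.frame(time_ms = (seq_along(x$per_bin_r) - 1L) * x$bin_width,
                   mean_r = round(x$per_bin_r, 4))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Extract encoding weights
#'
#' Returns the ridge weights refitted on all words (one model per time bin),
#' as an array `embed_dim x n_channels x n_timebins`, or a single fold's
#' cross-validation weights.
#'
#' @param object A `"meg_encoding"` fit.
#' @param fold `NULL` for the all-data refit, or an outer-fold index.
#' @param ... Unused.
#' @export
coef.meg_encoding <- function(object, fold = NULL, ...) {
  d <- object$dims
  models <- if (is.null(fold)) object$final_models
            else object$fold_models[[fold]]
  out <- array(NA_real_, unname(c(d["embed_dim"], d["n_channels"],
                                  d["n_timebins"])))
  for (t in seq_len(d[["n_timebins"]])) {
    m <- models[[t]]
    out[, , t] <- if (inherits(m, "ridge_model")) m$weights
                  else do.call(cbind, lapply(m, `[[`, "weights"))
  }
  out
}

#' Predict responses from a fitted encoding model
#'
#' With `newdata = NULL` returns the concatenated held-out predictions (the
#' cross-validated prediction of every word by the fold that did not train
#' on it).  With new embeddings, predicts using the per-timebin all-data
#' refits.
#'
#' @param object A `"meg_encoding"` fit.
#' @param newdata Optional embedding matrix with `embed_dim` columns.
#' @param ... Unused.
#' @return A response array `n x n_channels x n_timebins`.
#' @export
predict.meg_encoding <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$predicted)
  X <- as.matrix(newdata)
  d <- object$dims
  if (ncol(X) != d["embed_dim"]) stop("newdata has wrong embedding dimension")
  out <- array(NA_real_, unname(c(nrow(X), d["n_channels"], d["n_timebins"])))
  for (t in seq_len(d[["n_timebins"]]))
    out[, , t] <- predict(object$final_models[[t]], X)
  structure(out, class = "response_tensor",
            bin_width = attr(object$predicted, "bin_width"))
}

#' @export
fitted.meg_encoding <- function(object, ...) object$predicted

#' @export
residuals.meg_encoding <- function(object, ...) {
  structure(unclass(object$responses) - unclass(object$predicted),
            class = "response_tensor",
            bin_width = attr(object$predicted, "bin_width"))
}

#' Plot the held-out correlation profile
#'
#' Draws the mean held-out Pearson correlation per time bin (line) over an
#' image of the full channel-by-time correlation map.
#'
#' @param x A `"meg_encoding"` fit.
#' @param which `"profile"` for the per-bin mean line, `"map"` for the
#'   channel x time image.
#' @param ... Passed to the underlying base-graphics call.
#' @export
plot.meg_encoding <- function(x, which = c("profile", "map"), ...) {
  which <- match.arg(which)
  bw <- attr(x$predicted, "bin_width"); if (is.null(bw)) bw <- 25
  tt <- (seq_len(ncol(x$correlations)) - 1L) * bw
  if (which == "profile") {
    graphics::plot(tt, colMeans(x$correlations, na.rm = TRUE), type = "b",
                   xlab = "time after word onset (ms)",
                   ylab = "mean held-out Pearson r", ...)
    graphics::abline(h = 0, lty = 3)
  } else {
    graphics::image(tt, seq_len(nrow(x$correlations)), t(x$correlations),
                    xlab = "time after word onset (ms)", ylab = "channel", ...)
  }
  invisible(x)
}
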