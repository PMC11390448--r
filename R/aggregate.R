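#' Aggregator configuration
#'
#' The patient-level aggregator is a one-hidden-layer perceptron (18 neurons
#' by default) with a logistic output. Bags carry variable numbers of
#' instances, so the instance-probability list is first encoded as a
#' fixed-length, permutation- and duplication-invariant summary; the default
#' is a `summary_bins`-bin normalized histogram on `[0, 1]`. Mean/max and
#' top-k summaries are available behind `summary`.
#'
#' @param summary_bins number of histogram bins B (default 10, >= 2).
#' @param hidden_units hidden-layer width (default 18).
#' @param summary `"histogram"` (default), `"meanmax"` (mean, max, instance
#'   count fraction), or `"topk"` (the k largest probabilities, padded).
#' @param top_k k for `summary = "topk"`.
#' @return an object of class `aggregator_config`.
#' @export
aggregator_config <- function(summary_bins = 10, hidden_units = 18,
                              summary = c("histogram", "meanmax", "topk"),
                              top_k = 3) {
  summary <- match.arg(summary)
  if (!is.numeric(summary_bins) || summary_bins < 2) stop_config("summary_bins", "must be >= 2")
  if (!is.numeric(hidden_units) || hidden_units < 1) stop_config("hidden_units", "must be >= 1")
  structure(list(summary_bins = as.integer(summary_bins),
                 hidden_units = as.integer(hidden_units),
                 summary = summary, top_k = as.integer(top_k)),
            class = "aggregator_config")
}

#' Summarize a bag's instance probabilities into a fixed-length vector
#'
#' Normalized histogram over `bins` equal-width bins on `[0, 1]`; every bin is
#' right-open except the last, which is right-closed so that `p = 1` lands in
#' the top bin. Components sum to 1, and the encoding is invariant both to
#' instance order and to duplicating every instance.
#'
#' @param probs numeric vector of instance probabilities in `[0, 1]`
#'   (non-empty).
#' @param bins number of bins B (default 10).
#' @return numeric vector of length `bins` summing to 1.
#' @export
summarize_probs <- function(probs, bins = 10) {
  if (length(probs) < 1L) stop("empty instance-probability list", call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < 0 | probs > 1)) {
    stop("instance probabilities must lie in [0, 1]", call. = FALSE)
  }
  bins <- as.integer(bins)
  if (bins < 2L) stop_config("bins", "must be >= 2")
  b <- pmin(floor(probs * bins) + 1L, bins)
  tabulate(b, nbins = bins) / length(probs)
}

bag_summary <- function(probs, config) {
  switch(config$summary,
    histogram = summarize_probs(probs, config$summary_bins),
    meanmax = c(mean(probs), max(probs), min(1, length(probs) / 100)),
    topk = {
      k <- config$top_k
      s <- sort(probs, decreasing = TRUE)
      c(s, rep(0, max(0, k - length(s))))[seq_len(k)]
    }
  )
}

#' Train the patient-level aggregation network
#'
#' Fits the one-hidden-layer perceptron mapping bag summaries to a cancer
#' probability (logistic output, binary cross-entropy, full-batch Adam).
#' When a validation set is supplied, the parameters of the epoch minimizing
#' validation loss are kept — model selection is frozen on the validation
#' split, never on test data.
#'
#' @param summaries numeric matrix, one row per bag ([summarize_probs()] /
#'   `bag_summary()` rows).
#' @param labels bag labels in \{0, 1\} (both classes required).
#' @param config an [aggregator_config()].
#' @param seed integer seed.
#' @param epochs,lr optimizer settings.
#' @param validation optional list with `summaries` and `labels` for epoch
#'   selection.
#' @return object of class `mil_aggregator`.
#' @export
train_aggregator <- function(summaries, labels, config = aggregator_config(),
                             seed = 1, epochs = 400, lr = 1e-2,
                             validation = NULL) {
  x <- as.matrix(summaries)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x)) stop("summaries/labels length mismatch", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("aggregator training requires both classes", call. = FALSE)
  }
  Xv <- NULL; Yv <- NULL
  if (!is.null(validation)) {
    Xv <- as.matrix(validation$summaries)
    Yv <- matrix(as.numeric(validation$labels), ncol = 1)
  }
  net <- mlp_train(x, matrix(as.numeric(labels), ncol = 1),
                   hidden = config$hidden_units, output = "sigmoid",
                   dropout = 0, epochs = epochs, lr = lr, seed = seed,
                   X_val = Xv, Y_val = Yv)
  structure(list(net = net, config = config), class = "mil_aggregator")
}

#' Aggregate a bag's instance probabilities to a patient prediction
#'
#' @param aggregator a trained `mil_aggregator`.
#' @param probs the bag's instance probabilities (non-empty, in `[0, 1]`), or
#'   a precomputed summary row when `summarized = TRUE`.
#' @param threshold decision threshold tau (default 0.5); decision is 1 iff
#'   probability >= tau.
#' @param patient_id optional identifier.
#' @param summarized set `TRUE` if `probs` is already a summary vector.
#' @return object of class `patient_prediction`: `patient_id`, `probability`,
#'   `decision`, `threshold`.
#' @export
predict_patient <- function(aggregator, probs, threshold = 0.5,
                            patient_id = NA_character_, summarized = FALSE) {
  stopifnot(inherits(aggregator, "mil_aggregator"))
  s <- if (summarized) as.numeric(probs) else bag_summary(probs, aggregator$config)
  p <- as.numeric(mlp_predict(aggregator$net, matrix(s, nrow = 1)))
  structure(list(patient_id = as.character(patient_id),
                 probability = p,
                 decision = as.integer(p >= threshold),
                 threshold = threshold),
            class = "patient_prediction")
}

#' @export
print.patient_prediction <- function(x, ...) {
  cat(sprintf("<patient_prediction> %s: P(cancer) = %.4f -> %d (tau = %g)\n",
              x$patient_id, x$probability, x$decision, x$threshold))
  invisible(x)
}
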