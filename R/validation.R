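#' Random holdout split of the analysis data
#'
#' Reserves a random fraction (default 10%) of the children with an
#' observed treatment response as a validation set; the remaining children
#' form the training set used for fitting. When a `survey` column is
#' present the split is stratified so each survey contributes its own
#' share. Children without an observed response always stay in the
#' training set (they carry no validation signal).
#'
#' @param children tibble with a `response` column (0/1/NA).
#' @param fraction holdout fraction in (0, 1).
#' @param seed integer seed.
#' @return A list with tibbles `train` and `test`; together they partition
#'   `children`.
#' @export
holdout_split <- function(children, fraction = 0.10, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  observed <- which(!is.na(children$response))
  if (length(observed) < 10)
    stop("need at least 10 observed responses to split", call. = FALSE)
  strata <- if ("survey" %in% names(children))
    children$survey[observed] else rep("all", length(observed))
  with_seed(seed, {
    test_idx <- unlist(lapply(split(observed, strata), function(idx) {
      n_test <- round(fraction * length(idx))
      if (n_test == 0) integer(0) else sample(idx, n_test)
    }), use.names = FALSE)
    list(train = children[setdiff(seq_len(nrow(children)), test_idx), , drop = FALSE],
         test = children[sort(test_idx), , drop = FALSE])
  })
}

#' Posterior predicted probabilities for holdout children
#'
#' Draw-wise evaluation of the response probability at each child's travel
#' time and residence, summarised by the posterior median across draws
#' (or the posterior mean with `summary = "mean"`).
#'
#' @param samples a `fever_draws` or `fever_irt_fit`.
#' @param test tibble with columns `travel_time_min`, `urban`, optionally
#'   `item`.
#' @param summary `"median"` (default) or `"mean"`.
#' @return Numeric vector of probabilities, one per row of `test`.
#' @export
predict_holdout <- function(samples, test, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  if (anyNA(test$travel_time_min) || anyNA(test$urban)) {
    bad <- which(is.na(test$travel_time_min) | is.na(test$urban))
    ids <- if ("child_id" %in% names(test)) test$child_id[bad] else bad
    stop("missing covariates for child ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  items <- if (inherits(samples, "fever_irt_fit")) samples$items else samples$items
  it <- if ("item" %in% names(test)) test$item else rep(items[1], nrow(test))
  it[is.na(it)] <- items[1]
  out <- numeric(nrow(test))
  stat <- if (summary == "median") stats::median else mean
  for (lab in unique(it)) {
    sel <- which(it == lab)
    m <- item_draw_matrix(samples, lab)
    for (start in seq(1, length(sel), by = 512)) {
      ss <- sel[start:min(start + 511, length(sel))]
      theta <- m[, "alpha"] + outer(m[, "beta_time"], test$travel_time_min[ss]) +
        outer(m[, "beta_urban"], test$urban[ss])
      pm <- m[, "c"] + (1 - m[, "c"]) * stats::plogis(m[, "a"] * theta - m[, "b"])
      out[ss] <- apply(pm, 2, stat)
    }
  }
  out
}

#' Misclassification error of binarised predictions
#'
#' Fraction of observations whose prediction, binarised at `cutoff`
#' (prediction `>= cutoff` counts as positive), differs from the observed
#' 0/1 outcome.
#'
#' @param predictions numeric probabilities.
#' @param observed 0/1 outcomes of the same length.
#' @param cutoff binarisation threshold.
#' @return Error rate in `[0, 1]`.
#' @export
misclassification <- function(predictions, observed, cutoff = 0.5) {
  if (length(predictions) == 0) stop("empty input", call. = FALSE)
  if (length(predictions) != length(observed))
    stop("predictions and observed must have equal length", call. = FALSE)
  if (!all(observed %in% c(0, 1))) stop("observed must be 0/1", call. = FALSE)
  mean((predictions >= cutoff) != (observed == 1))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique prediction scores and
#' records the false-positive and true-positive rates; the area under the
#' curve is computed by the trapezoidal rule, which equals the
#' Mann-Whitney statistic `P(score_1 > score_0) + P(tie)/2` including under
#' ties.
#'
#' @inheritParams misclassification
#' @return A list of class `fever_roc`: `points` (tibble `threshold`,
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(predictions, observed) {
  if (length(predictions) != length(observed))
    stop("predictions and observed must have equal length", call. = FALSE)
  if (!all(observed %in% c(0, 1))) stop("observed must be 0/1", call. = FALSE)
  n_pos <- sum(observed == 1); n_neg <- sum(observed == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both outcome classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(predictions), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(predictions >= t & observed == 1) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(predictions >= t & observed == 0) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "fever_roc")
}

#' @export
print.fever_roc <- function(x, ...) {
  cat(sprintf("<fever_roc> AUC = %.4f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @method autoplot fever_roc
#' @export
autoplot.fever_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::labs(x = "false positive rate (1 - specificity)",
                  y = "true positive rate (sensitivity)",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' End-to-end holdout validation
#'
#' Applies a fitted model to a validation set: draw-wise predicted
#' probabilities, binarised misclassification error and the ROC curve.
#'
#' @param fit a `fever_irt_fit`.
#' @param test holdout tibble (rows with missing responses are dropped).
#' @param cutoff binarisation threshold for the error rate.
#' @return A list of class `validation_report`: `n_test`,
#'   `misclassification`, `roc` (a `fever_roc`), `cutoff`, `predictions`.
#' @export
validate_holdout <- function(fit, test, cutoff = 0.5) {
  test <- test[!is.na(test$response), , drop = FALSE]
  if (nrow(test) == 0) stop("no observed responses in the test set", call. = FALSE)
  preds <- predict_holdout(fit, test)
  structure(list(n_test = nrow(test),
                 misclassification = misclassification(preds, test$response, cutoff),
                 roc = roc_curve(preds, test$response),
                 cutoff = cutoff, predictions = preds),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Holdout validation: n = %d, misclassification = %.3f (cutoff %.2f), AUC = %.3f\n",
              x$n_test, x$misclassification, x$cutoff, x$roc$auc))
  invisible(x)
}
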