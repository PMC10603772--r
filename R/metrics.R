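#' Binary classification metrics for spectrum quality
#'
#' Metrics are defined with `"good"` as the positive class.
#' `average_precision()` is the step-wise summation of the
#' precision–recall curve, \eqn{AP = \sum_n (R_n - R_{n-1}) P_n}, evaluated
#' at every distinct score threshold. `log_loss()` is the negative mean
#' log-likelihood with probabilities clipped to `[eps, 1 - eps]`.
#' ROC AUC is delegated to [pROC::auc()].
#'
#' @param labels character/factor vector of `"good"`/`"poor"` truth labels.
#' @param prob numeric vector of predicted probabilities of `"good"`.
#' @return A single number.
#' @name ms2_metrics
NULL

as_good <- function(labels) {
  l <- as.character(labels)
  if (!all(l %in% c("good", "poor"))) stop("labels must be 'good'/'poor'")
  l == "good"
}

#' @rdname ms2_metrics
#' @export
average_precision <- function(labels, prob) {
  y <- as_good(labels)
  pos <- sum(y)
  if (pos == 0 || pos == length(y)) stop("both classes required")
  ord <- order(prob, decreasing = TRUE)
  y <- y[ord]; s <- prob[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  precision <- (tp / (tp + fp))[last_of_tie]
  recall <- (tp / pos)[last_of_tie]
  sum(diff(c(0, recall)) * precision)
}

#' @rdname ms2_metrics
#' @export
roc_auc <- function(labels, prob) {
  as.numeric(pROC::auc(pROC::roc(response = as_good(labels), predictor = prob,
                                 levels = c(FALSE, TRUE), direction = "<",
                                 quiet = TRUE)))
}

#' @rdname ms2_metrics
#' @param eps clipping bound for probabilities.
#' @export
log_loss <- function(labels, prob, eps = 1e-15) {
  y <- as_good(labels)
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Confusion matrix and thresholded metrics
#'
#' @inheritParams ms2_metrics
#' @param threshold probability cutoff; predicted good iff `prob >= threshold`.
#' @return List with `confusion` (named counts tp/fp/tn/fn), `accuracy`,
#'   `precision`, `recall` (precision is `NA` when nothing is predicted
#'   good).
#' @export
thresholded_metrics <- function(labels, prob, threshold = 0.5) {
  y <- as_good(labels)
  pred <- prob >= threshold
  tp <- sum(pred & y); fp <- sum(pred & !y)
  tn <- sum(!pred & !y); fn <- sum(!pred & y)
  list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
       accuracy = (tp + tn) / length(y),
       precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_)
}

#' F-beta score
#'
#' \eqn{F_\beta = (1+\beta^2) P R / (\beta^2 P + R)}; `beta = 0.5` weights
#' precision twice as heavily as recall. Returns 0 when no positives are
#' predicted or none recovered.
#'
#' @param precision,recall precision and recall on the positive class.
#' @param beta precision/recall trade-off parameter (> 0).
#' @export
f_beta_score <- function(precision, recall, beta = 0.5) {
  if (is.na(precision) || is.na(recall)) return(0)
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  if (den == 0) 0 else num / den
}
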