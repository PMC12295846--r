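# Video-level evaluation: multi-segment aggregation, confusion-matrix
# metrics, ROC/AUC, and the paired significance tests used in the
# attention ablation.  The positive class is "upper" (the minority class).

#' Confusion matrix for two-class video prediction
#'
#' @param predicted,truth character vectors of `"upper"` / `"lower"`
#'   labels.
#' @param positive the positive class.
#' @return an object of class `confusion_matrix` with integer fields `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(predicted, truth, positive = "upper") {
  stopifnot(length(predicted) == length(truth))
  p <- predicted == positive
  t <- truth == positive
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t),
                 positive = positive),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (positive =", x$positive, "):\n")
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("pos", "neg"),
                              predicted = c("pos", "neg")))
  print(t(m))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and F1 `2 * precision * recall / (precision + recall)`.
#' A ratio with zero denominator is reported as 0 and flagged in
#' `undefined`, so multi-run aggregation never aborts.
#'
#' @param cm a [confusion_matrix()].
#' @param auc optional AUC to carry along (computed separately from
#'   scores, see [roc_auc()]).
#' @return an object of class `metrics_report` with fields `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`, `undefined`.
#' @export
compute_metrics <- function(cm, auc = NA_real_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$TP + cm$TN + cm$FP + cm$FN
  if (total == 0) stop("empty confusion matrix")
  undefined <- character(0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      if (num > 0) warning("undefined ", what, " (zero denominator); reported as 0")
      0
    } else num / den
  }
  accuracy <- (cm$TP + cm$TN) / total
  precision <- ratio(cm$TP, cm$TP + cm$FP, "precision")
  recall <- ratio(cm$TP, cm$TP + cm$FN, "recall")
  f1 <- ratio(2 * recall * precision, recall + precision, "f1")
  structure(list(accuracy = accuracy, precision = precision,
                 recall = recall, f1 = f1, auc = auc,
                 undefined = undefined),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  v <- c(accuracy = x$accuracy, precision = x$precision,
         recall = x$recall, f1 = x$f1, auc = x$auc)
  print(round(v, digits))
  if (length(x$undefined))
    cat("undefined (zero denominator):", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC over all score thresholds (trapezoidal rule), equal to the
#' Mann-Whitney concordance probability; computed with pROC.
#'
#' @param scores positive-class scores in `[0, 1]`.
#' @param labels `"upper"` / `"lower"` truth labels; both classes must be
#'   present.
#' @param positive the positive class.
#' @return list with `auc` and a data frame `roc` of
#'   (`threshold`, `fpr`, `tpr`) points.
#' @export
roc_auc <- function(scores, labels, positive = "upper") {
  stopifnot(length(scores) == length(labels))
  neg <- setdiff(unique(labels), positive)
  if (!any(labels == positive) || !length(neg))
    stop("both classes must be present to compute a ROC curve")
  r <- pROC::roc(response = factor(labels, levels = c(neg[1], positive)),
                 predictor = scores, levels = c(neg[1], positive),
                 direction = "<", quiet = TRUE)
  co <- pROC::coords(r, x = "all", ret = c("threshold", "specificity",
                                           "sensitivity"),
                     transpose = FALSE)
  list(auc = as.numeric(pROC::auc(r)),
       roc = data.frame(threshold = co$threshold,
                        fpr = 1 - co$specificity,
                        tpr = co$sensitivity))
}

#' Predict the class of one video
#'
#' Runs the model on up to `max_segments` randomly selected segments,
#' converts logits to class probabilities with a softmax, and aggregates by
#' the mean positive-class probability across segments.  The predicted
#' label is the class with the larger mean probability; an exact tie goes
#' to the positive class.
#'
#' @param model a trained `rpanet_model`.
#' @param video a [video_record()].
#' @param config a [segment_config()].
#' @param max_segments inference segment cap (default 10).
#' @param seed optional integer seed for segment selection.
#' @param positive the positive class.
#' @return list with `score` (mean positive-class probability), `label`,
#'   and `n_segments` actually used.
#' @export
predict_video <- function(model, video, config, max_segments = 10L,
                          seed = NULL, positive = "upper") {
  segs <- select_inference_segments(video, config, max_segments, seed)
  x <- array(0, c(length(segs), dim(segs[[1]]$data)))
  for (i in seq_along(segs)) x[i, , , , ] <- segs[[i]]$data
  logits <- .model_fwd(model, x)$logits
  prob <- .softmax(logits)
  # class 1 = positive ("upper"), class 2 = negative ("lower")
  mean_prob <- colMeans(prob)
  score <- mean_prob[1]
  label <- if (mean_prob[1] >= mean_prob[2]) positive else "lower"
  list(score = as.numeric(score), label = label, n_segments = length(segs))
}

#' Paired significance tests between two matched metric series
#'
#' Runs a two-sided paired t-test and a Wilcoxon signed-rank test on
#' per-run metric values from two configurations evaluated on the same
#' run subsets/splits/seeds.  Zero differences are dropped for the
#' Wilcoxon test and tied absolute differences receive mid-ranks; the
#' exact null distribution is used for up to 25 nonzero pairs, the
#' tie-corrected normal approximation beyond that.
#'
#' If every difference is zero the result degenerates: `t = 0`,
#' `t_pvalue = 1`, Wilcoxon `NA`, with a warning (no error, so multi-run
#' comparisons never abort).
#'
#' @param metric_with,metric_without equal-length (>= 2) numeric vectors,
#'   matched by run.
#' @return an object of class `paired_test_result` with fields
#'   `t_statistic`, `t_pvalue`, `w_statistic`, `w_pvalue`, `n_pairs`.
#' @export
paired_tests <- function(metric_with, metric_without) {
  if (length(metric_with) != length(metric_without))
    stop("the two series must be matched by run (equal length)")
  n <- length(metric_with)
  if (n < 2) stop("need at least two paired runs")
  d <- metric_with - metric_without
  if (all(d == 0)) {
    warning("all paired differences are zero; tests are degenerate")
    return(structure(list(t_statistic = 0, t_pvalue = 1,
                          w_statistic = NA_real_, w_pvalue = NA_real_,
                          n_pairs = n),
                     class = "paired_test_result"))
  }
  if (stats::sd(d) <= 1e-10 * abs(mean(d))) {
    # (numerically) constant nonzero shift: the t statistic degenerates
    # to +/- infinity
    t_stat <- sign(mean(d)) * Inf
    t_p <- 0
  } else {
    tt <- stats::t.test(metric_with, metric_without, paired = TRUE)
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  w <- .signed_rank_test(d)
  structure(list(t_statistic = t_stat, t_pvalue = t_p,
                 w_statistic = w$statistic, w_pvalue = w$p.value,
                 n_pairs = n),
            class = "paired_test_result")
}

# Wilcoxon signed-rank test with zero differences dropped and mid-rank
# ties.  Exact null distribution (computed by the generating-function
# recursion over doubled ranks, which handles tied mid-ranks) for up to 25
# nonzero pairs; normal approximation with tie-corrected variance and
# continuity correction beyond that.  stats::wilcox.test is not used
# because it cannot combine an exact null with mid-rank ties.
.signed_rank_test <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))       # doubled ranks are integers
    # distribution of sum of a random subset of r2: polynomial product
    coef <- c(1, rep(0, sum(r2)))
    for (ri in r2) {
      shifted <- c(rep(0, ri), coef[seq_len(length(coef) - ri)])
      coef <- coef + shifted
    }
    probs <- coef / 2^n
    support <- (seq_along(coef) - 1) / 2  # back to the half-integer scale
    p <- sum(probs[abs(support - mu) >= abs(v - mu) - 1e-9])
  } else {
    tie_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- (abs(v - mu) - 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-max(z, 0))
  }
  list(statistic = v, p.value = min(p, 1))
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("paired t-test: t = %.3f, p = %.4f\n", x$t_statistic, x$t_pvalue))
  cat(sprintf("Wilcoxon signed-rank: W = %s, p = %s (n = %d pairs)\n",
              format(x$w_statistic), format(x$w_pvalue), x$n_pairs))
  invisible(x)
}
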