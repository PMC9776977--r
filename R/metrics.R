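# Classifier performance reporting: confusion counts, sensitivity,
# specificity, informedness (Youden's J), predictive values, and the
# empirical ROC with a bootstrap AUC confidence interval.

.round_pct <- function(x) floor(x * 100 + 0.5)   # round half up, percent

#' Informedness (Youden's J) of binary predictions
#' @param labels true classes (logical / 0-1).
#' @param predictions predicted classes (logical / 0-1).
#' @return SN + SP - 1, a value in [-1, 1].
#' @export
informedness <- function(labels, predictions) {
  labels <- as.logical(labels); predictions <- as.logical(predictions)
  sn <- sum(predictions & labels) / sum(labels)
  sp <- sum(!predictions & !labels) / sum(!labels)
  sn + sp - 1
}

#' Rank-based AUC (Mann-Whitney formulation, ties averaged)
#' @param scores numeric scores, larger means more positive.
#' @param labels true classes.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve with AUC and a bootstrap confidence interval
#'
#' The ROC is the empirical curve over all score thresholds; the AUC is the
#' trapezoidal area, which with mid-rank tie handling equals the rank-sum
#' (Mann-Whitney) formulation. The confidence interval is a stratified
#' percentile bootstrap (resampling within each class).
#'
#' @param scores numeric scores.
#' @param labels true classes (both must be present).
#' @param n_boot bootstrap replicates (default 2000).
#' @param conf confidence level (default 0.95).
#' @param seed optional RNG seed for the bootstrap.
#' @return list with `roc` (data.frame fpr/tpr/threshold), `auc`, `ci`
#'   (length 2), `conf`, `n_boot`.
#' @export
roc_with_ci <- function(scores, labels, n_boot = 2000, conf = 0.95,
                        seed = NULL) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (!is.null(seed)) set.seed(seed)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  auc <- auc_rank(scores, labels)
  pos <- which(labels); neg <- which(!labels)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auc_rank(scores[i], labels[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc,
       ci = as.numeric(quantile(boot, c(a, 1 - a), na.rm = TRUE)),
       conf = conf, n_boot = n_boot)
}

#' Confusion-matrix performance report
#'
#' Counts and the derived metrics: sensitivity SN = TP/(TP+FN), specificity
#' SP = TN/(TN+FP), informedness I = SN + SP - 1, PPV and NPV. Percentages
#' are additionally rounded to integers (round half up) and I to two
#' decimals for reporting. When `scores` are supplied the empirical ROC,
#' AUC and its bootstrap CI, and the waterfall data (per-sample score and
#' label) are attached.
#'
#' @param labels true classes (logical / 0-1).
#' @param predictions predicted classes.
#' @param scores optional numeric scores for ROC/AUC/waterfall.
#' @param n_boot,conf,seed passed to [roc_with_ci()].
#' @return Object of class `metrics_report`.
#' @export
confusion_metrics <- function(labels, predictions, scores = NULL,
                              n_boot = 2000, conf = 0.95, seed = NULL) {
  labels <- as.logical(labels); predictions <- as.logical(predictions)
  stopifnot(length(labels) == length(predictions))
  tp <- sum(predictions & labels); fn <- sum(!predictions & labels)
  tn <- sum(!predictions & !labels); fp <- sum(predictions & !labels)
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sn <- frac(tp, tp + fn); sp <- frac(tn, tn + fp)
  ppv <- frac(tp, tp + fp); npv <- frac(tn, tn + fn)
  i <- if (is.na(sn) || is.na(sp)) NA_real_ else sn + sp - 1
  rep <- list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    SN = sn, SP = sp, PPV = ppv, NPV = npv, I = i,
    SN_pct = .round_pct(sn), SP_pct = .round_pct(sp),
    PPV_pct = .round_pct(ppv), NPV_pct = .round_pct(npv),
    I_2dp = round(i, 2), n = length(labels)
  )
  if (!is.null(scores)) {
    rep$roc <- roc_with_ci(scores, labels, n_boot = n_boot, conf = conf,
                           seed = seed)
    rep$auc <- rep$roc$auc
    rep$auc_ci <- rep$roc$ci
    rep$waterfall <- data.frame(score = scores, label = labels)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> n=%d  TP=%d FP=%d TN=%d FN=%d\n  SN=%s%% SP=%s%% I=%s  PPV=%s%% NPV=%s%%%s\n",
    x$n, x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"],
    x$SN_pct, x$SP_pct, format(x$I_2dp), x$PPV_pct, x$NPV_pct,
    if (!is.null(x$auc)) sprintf("  AUC=%.2f (%.0f%% CI %.2f-%.2f)",
                                 x$auc, 100 * x$roc$conf, x$auc_ci[1],
                                 x$auc_ci[2]) else ""))
  invisible(x)
}

.metrics_json <- function(x) {
  out <- list(counts = as.list(x$counts),
              SN = x$SN, SP = x$SP, PPV = x$PPV, NPV = x$NPV, I = x$I,
              SN_pct = x$SN_pct, SP_pct = x$SP_pct, PPV_pct = x$PPV_pct,
              NPV_pct = x$NPV_pct, I_2dp = x$I_2dp, n = x$n)
  if (!is.null(x$auc)) {
    out$AUC <- x$auc
    out$AUC_ci <- x$auc_ci
  }
  out
}
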