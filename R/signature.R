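# Training, calibration and evaluation of the 4-feature linear-SVM radiomic
# signature. Training repeats stratified 3-fold cross-validation (default
# 100 runs); in each run the (C, gamma) pair is chosen by Bayesian
# (GP expected-improvement) optimization of the mean validation AUC, fold
# models that score a higher AUC on their validation fold than on their own
# training folds are discarded as overfitting-prone, and the best surviving
# fold model of each run is kept. Survivors are re-scored on the full
# training set, ranked by (AUC, informedness), and the top model's decision
# values are calibrated to (0,1) radiomic scores with a binomial-logit
# (sigmoid) fit.

#' SVM training configuration
#'
#' @param C_range,gamma_range log-uniform search ranges (default 1e-4..1e3).
#' @param cv_runs repeated-CV runs (default 100).
#' @param cv_folds folds per run (default 3).
#' @param bayes_opt_iters expected-improvement iterations per run
#'   (default 30).
#' @param bayes_opt_init initial random design points per run.
#' @param seed RNG seed.
#' @return list of class `svm_config`.
#' @export
svm_config <- function(C_range = c(1e-4, 1e3), gamma_range = c(1e-4, 1e3),
                       cv_runs = 100, cv_folds = 3, bayes_opt_iters = 30,
                       bayes_opt_init = 6, seed = NULL) {
  stopifnot(all(C_range > 0), all(gamma_range > 0), cv_folds >= 2)
  structure(list(C_range = C_range, gamma_range = gamma_range,
                 cv_runs = cv_runs, cv_folds = cv_folds,
                 bayes_opt_iters = bayes_opt_iters,
                 bayes_opt_init = bayes_opt_init, seed = seed),
            class = "svm_config")
}

.stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

#' Train the radiomic signature on a training split
#'
#' @param split a [split_augmented()] result (its `train` part is used), or
#'   a list with `x` and `labels`.
#' @param cfg an [svm_config()].
#' @param feature_names names of the 4 features (defaults to the column
#'   names of the training matrix).
#' @return Object of class `signature_model`: `feature_names`, `weights`,
#'   `intercept`, `calibration` (A, B, fallback flag; score =
#'   plogis(A * decision + B)), chosen `C`/`gamma`, and CV diagnostics.
#' @export
train_signature <- function(split, cfg = svm_config(),
                            feature_names = NULL) {
  tr <- if (inherits(split, "split_set")) split$train else split
  x <- as.matrix(tr$x); y <- as.logical(tr$labels)
  if (is.null(feature_names)) feature_names <- colnames(x)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  lb <- log10(c(cfg$C_range[1], cfg$gamma_range[1]))
  ub <- log10(c(cfg$C_range[2], cfg$gamma_range[2]))
  survivors <- list()
  for (run in seq_len(cfg$cv_runs)) {
    foldid <- .stratified_folds(y, cfg$cv_folds)
    fold_models <- function(par) {
      C <- 10^par[1]; gamma <- 10^par[2]
      lapply(seq_len(cfg$cv_folds), function(f) {
        tr_i <- foldid != f
        fit <- tryCatch(
          svm_linear_fit(x[tr_i, , drop = FALSE], y[tr_i], C = C,
                         gamma = gamma),
          error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        list(fit = fit,
             train_auc = auc_rank(predict(fit, x[tr_i, , drop = FALSE]),
                                  y[tr_i]),
             val_auc = auc_rank(predict(fit, x[!tr_i, , drop = FALSE]),
                                y[!tr_i]))
      })
    }
    objective <- function(par) {
      ms <- fold_models(par)
      ok <- !vapply(ms, is.null, logical(1))
      if (!any(ok)) return(0)
      mean(vapply(ms[ok], function(m) m$val_auc, numeric(1)))
    }
    opt <- bayes_opt(objective, lb, ub, n_init = cfg$bayes_opt_init,
                     n_iter = cfg$bayes_opt_iters)
    ms <- fold_models(opt$par)
    ms <- ms[!vapply(ms, is.null, logical(1))]
    # overfitting filter: validation AUC must not exceed training AUC
    keep <- vapply(ms, function(m) m$val_auc <= m$train_auc, logical(1))
    ms <- ms[keep]
    if (length(ms) == 0) next
    best <- ms[[which.max(vapply(ms, function(m) m$val_auc, numeric(1)))]]
    survivors[[length(survivors) + 1]] <- c(best, list(
      C = 10^opt$par[1], gamma = 10^opt$par[2], run = run))
  }
  relaxed <- FALSE
  if (length(survivors) == 0) {
    warning("all CV models were discarded by the overfitting filter; ",
            "relaxing it for one unfiltered run")
    relaxed <- TRUE
    foldid <- .stratified_folds(y, cfg$cv_folds)
    fit <- svm_linear_fit(x[foldid != 1, , drop = FALSE], y[foldid != 1])
    survivors[[1]] <- list(fit = fit, train_auc = NA, val_auc = NA,
                           C = fit$C, gamma = fit$gamma, run = NA)
  }
  # re-score every surviving model on the entire training set
  full <- lapply(survivors, function(s) {
    d <- predict(s$fit, x)
    c(s, list(full_auc = auc_rank(d, y), full_inf = informedness(y, d > 0)))
  })
  ord <- order(-vapply(full, `[[`, numeric(1), "full_auc"),
               -vapply(full, `[[`, numeric(1), "full_inf"))
  top <- full[[ord[1]]]
  d_train <- predict(top$fit, x)
  calib <- .fit_logit_calibration(d_train, y)
  structure(
    list(feature_names = feature_names, weights = setNames(
           top$fit$weights, feature_names), intercept = top$fit$intercept,
         calibration = calib, C = top$C, gamma = top$gamma,
         config = cfg,
         diagnostics = list(
           n_runs = cfg$cv_runs, n_survivors = length(survivors),
           relaxed_filter = relaxed, run = top$run,
           cv_train_auc = top$train_auc, cv_val_auc = top$val_auc,
           train_auc = top$full_auc, train_informedness = top$full_inf)),
    class = "signature_model"
  )
}

# Binomial-logit (sigmoid) calibration of decision values to scores in (0,1);
# falls back to the unscaled logistic (A=1, B=0) when the fit does not
# converge or is non-monotone.
.fit_logit_calibration <- function(d, y) {
  fit <- suppressWarnings(tryCatch(
    glm(y ~ d, family = binomial()), error = function(e) NULL))
  if (is.null(fit) || !fit$converged || coef(fit)[2] <= 0 ||
      !all(is.finite(coef(fit)))) {
    return(list(A = 1, B = 0, fallback = TRUE))
  }
  list(A = unname(coef(fit)[2]), B = unname(coef(fit)[1]), fallback = FALSE)
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %s\n  C=%.4g gamma=%.4g  train AUC=%.2f I=%.2f (%d survivors/%d runs)\n",
              paste(sprintf("%+.3f*%s", x$weights, x$feature_names),
                    collapse = " "),
              x$C, x$gamma, x$diagnostics$train_auc,
              x$diagnostics$train_informedness, x$diagnostics$n_survivors,
              x$diagnostics$n_runs))
  invisible(x)
}

#' Radiomic score of feature rows under a trained signature
#'
#' The score is the sigmoid-calibrated decision value, a number in (0, 1);
#' the classification threshold is 0.5 (equivalently, decision value 0 when
#' the calibration is the identity logistic).
#'
#' @param model a `signature_model`.
#' @param rows named numeric vector, matrix or data.frame holding the
#'   model's 4 features (on the model's normalized scale).
#' @return Numeric vector of scores.
#' @export
radiomic_score <- function(model, rows) {
  x <- .rows_to_matrix(rows, model$feature_names)
  d <- drop(x %*% model$weights) + model$intercept
  plogis(model$calibration$A * d + model$calibration$B)
}

#' Decision values of a trained signature
#' @param model a `signature_model`.
#' @param rows as in [radiomic_score()].
#' @return Numeric vector of (uncalibrated) decision values.
#' @export
signature_decision <- function(model, rows) {
  x <- .rows_to_matrix(rows, model$feature_names)
  drop(x %*% model$weights) + model$intercept
}

.rows_to_matrix <- function(rows, feats) {
  if (is.null(dim(rows))) rows <- t(as.matrix(rows))
  rows <- as.data.frame(as.matrix(rows), check.names = FALSE)
  miss <- setdiff(feats, names(rows))
  if (length(miss)) {
    stop("missing feature(s): ", paste(miss, collapse = ", "))
  }
  as.matrix(rows[, feats, drop = FALSE])
}

#' The published radiomic signature
#'
#' The linear signature reported by the reference study:
#' g(x) = -0.04 + 1.67 cv-m + 0.96 mu-u + 0.22 s-s - 1.12 sigma-IQR,
#' where cv-m is the median of the local coefficient of variation, mu-u the
#' uniformity of the local mean, s-s the skewness of the local skewness and
#' sigma-IQR the IQR of the local standard deviation (all min-max
#' normalized).
#'
#' @return list with `intercept` and named `weights`.
#' @export
published_signature <- function() {
  list(intercept = -0.04,
       weights = c("cv-m" = 1.67, "mu-u" = 0.96, "s-s" = 0.22,
                   "sigma-IQR" = -1.12))
}

#' Evaluate the published signature on feature rows
#'
#' @param rows named vector, matrix or data.frame with columns `cv-m`,
#'   `mu-u`, `s-s`, `sigma-IQR` (normalized scale).
#' @return Numeric vector of g(x) values.
#' @export
evaluate_published_signature <- function(rows) {
  sig <- published_signature()
  x <- .rows_to_matrix(rows, names(sig$weights))
  drop(x %*% sig$weights) + sig$intercept
}

#' Evaluate a trained signature on a labelled set
#'
#' Scores the rows, classifies at 0.5 and assembles the full
#' [confusion_metrics()] report including ROC/AUC and waterfall data.
#'
#' @param model a `signature_model`.
#' @param x feature rows.
#' @param labels true classes.
#' @param ... passed to [confusion_metrics()] (bootstrap settings).
#' @return A `metrics_report`.
#' @export
evaluate_signature <- function(model, x, labels, ...) {
  s <- radiomic_score(model, x)
  confusion_metrics(labels, s > 0.5, scores = s, ...)
}

#' Waterfall plot of radiomic scores
#'
#' Per-sample sorted bars of `score - 0.5`, coloured by true class.
#' @param scores numeric scores in (0, 1).
#' @param labels true classes.
#' @param path optional PNG/SVG destination.
#' @return ggplot object (invisibly when written).
#' @export
waterfall_plot <- function(scores, labels, path = NULL) {
  o <- order(scores, decreasing = TRUE)
  df <- data.frame(rank = seq_along(scores), value = scores[o] - 0.5,
                   class = factor(ifelse(as.logical(labels[o]), "GG>=3",
                                         "GG<3")))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$value,
                                        fill = .data$class)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "sample (sorted)", y = "radiomic score - 0.5") +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 6, height = 3.5, dpi = 150)
  invisible(p)
}

#' ROC plot of a metrics report
#' @param report a `metrics_report` holding ROC data.
#' @param path optional destination.
#' @return ggplot object (invisibly when written).
#' @export
roc_plot <- function(report, path = NULL) {
  stopifnot(!is.null(report$roc))
  p <- ggplot2::ggplot(report$roc$roc,
                       ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::annotate("text", x = 0.7, y = 0.1, label = sprintf(
      "AUC = %.2f (%.2f-%.2f)", report$auc, report$auc_ci[1],
      report$auc_ci[2])) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 4, height = 4, dpi = 150)
  invisible(p)
}

#' Persist a signature model as JSON
#' @param model a `signature_model`.
#' @param path JSON destination.
#' @param normalization optional normalization parameters stored alongside.
#' @return `path`, invisibly.
#' @export
write_signature_model <- function(model, path, normalization = NULL) {
  out <- list(feature_names = model$feature_names,
              weights = as.list(model$weights),
              intercept = model$intercept,
              calibration = model$calibration,
              C = model$C, gamma = model$gamma,
              diagnostics = model$diagnostics[c(
                "n_runs", "n_survivors", "relaxed_filter", "train_auc",
                "train_informedness")])
  if (!is.null(normalization)) {
    out$normalization <- list(min = as.list(normalization$min),
                              max = as.list(normalization$max))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
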