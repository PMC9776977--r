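# Two-stage feature selection: a class-weighted binomial LASSO screen at the
# minimum cross-validation error, then an exhaustive search over all
# 4-feature combinations, each scored by a linear SVM, ranked by Wilcoxon
# rank-sum significance of its decision values (Holm-Bonferroni corrected at
# alpha = 1e-3) and, among the significant ones, by informedness.

#' Fit or apply a linear min-max feature normalization
#'
#' Fitted features are mapped to [0, 1]; the transform is reusable on new
#' rows, whose values may fall outside [0, 1] (no clipping). Zero-range
#' features cannot be normalized and are dropped with a log entry.
#'
#' @param x numeric matrix (samples x features) or a `feature_table`.
#' @param params optional previously fitted parameters; when given, they are
#'   applied instead of fitting.
#' @return list with `x` (normalized matrix) and `params` (list with `min`,
#'   `max`, `features`, `dropped`).
#' @export
minmax_normalize <- function(x, params = NULL) {
  if (inherits(x, "feature_table")) x <- feature_matrix(x)
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  if (is.null(params)) {
    mn <- apply(x, 2, min); mx <- apply(x, 2, max)
    keep <- mx > mn
    dropped <- colnames(x)[!keep]
    for (d in dropped) .adc_log("dropping constant feature '%s'", d)
    params <- list(min = mn[keep], max = mx[keep],
                   features = colnames(x)[keep], dropped = dropped)
  }
  x <- x[, params$features, drop = FALSE]
  xn <- sweep(sweep(x, 2, params$min, "-"), 2,
              params$max - params$min, "/")
  list(x = xn, params = params)
}

#' LASSO screening of candidate features
#'
#' Binomial (logistic) LASSO over a 100-point lambda path with stratified
#' 10-fold cross-validation at the minimum CV deviance, each sample weighted
#' by its class (`"balanced"`: inverse class frequency, the default;
#' `"prior"`: the literal class prior probability). Returns the features
#' with nonzero coefficients at lambda.min, ordered by decreasing
#' coefficient magnitude.
#'
#' @param x normalized feature matrix (samples x features, named columns).
#' @param labels binary class labels.
#' @param folds CV folds (default 10).
#' @param seed RNG seed controlling the fold assignment.
#' @param weighting `"balanced"` or `"prior"`.
#' @return Character vector of screened feature names (possibly empty, with
#'   a warning).
#' @export
lasso_screen <- function(x, labels, folds = 10, seed = NULL,
                         weighting = c("balanced", "prior")) {
  weighting <- match.arg(weighting)
  x <- as.matrix(x)
  y <- as.numeric(as.logical(labels))
  n <- nrow(x)
  if (n < folds) stop("need at least as many samples as folds")
  if (!is.null(seed)) set.seed(seed)
  prior <- mean(y)
  w <- if (weighting == "balanced") {
    ifelse(y == 1, 0.5 / prior, 0.5 / (1 - prior))
  } else {
    ifelse(y == 1, prior, 1 - prior)
  }
  foldid <- integer(n)   # stratified folds: both classes in every fold
  for (cls in c(0, 1)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fit <- glmnet::cv.glmnet(x, y, family = "binomial", weights = w,
                           foldid = foldid, type.measure = "deviance",
                           nlambda = 100, standardize = FALSE)
  co <- as.matrix(coef(fit, s = "lambda.min"))[-1, 1]
  nz <- co[co != 0]
  if (length(nz) == 0) {
    warning("LASSO screen is degenerate: all coefficients are zero")
    return(character(0))
  }
  names(sort(abs(nz), decreasing = TRUE))
}

#' Holm-Bonferroni step-down decisions
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param alpha family-wise error level.
#' @return Logical vector of rejections, in the input order; monotone
#'   (rejecting a p-value implies rejecting all smaller ones).
#' @export
holm_bonferroni <- function(p_values, alpha) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  o <- order(p_values)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[o[i]] <= alpha / (m - i + 1)) {
      reject[o[i]] <- TRUE
    } else break
  }
  reject
}

#' Exhaustive 4-feature linear-SVM search
#'
#' Trains one linear SVM per 4-combination of the screened features, tests
#' the separation of its decision values between the classes with a
#' two-sided Wilcoxon rank-sum test, applies Holm-Bonferroni over all
#' combinations at `alpha`, and among the significant combinations selects
#' the one with the highest informedness at the SVM's native zero threshold
#' (ties: smaller p, then lexicographic feature names).
#'
#' @param x normalized feature matrix restricted to the screened features.
#' @param labels binary class labels.
#' @param alpha significance level after correction (default 1e-3).
#' @param C,gamma SVM hyperparameters for the search stage.
#' @return Object of class `selection_result`: `combos` (data.frame with
#'   features, p, informedness, significance) and `chosen` (the winning
#'   4 feature names).
#' @export
exhaustive_quadruple_search <- function(x, labels, alpha = 1e-3, C = 1,
                                        gamma = 1) {
  x <- as.matrix(x)
  y <- as.logical(labels)
  k <- ncol(x)
  if (k < 4) stop("need at least 4 screened features, got ", k)
  combos <- combn(colnames(x), 4)
  n_combo <- ncol(combos)
  p <- numeric(n_combo); inf <- numeric(n_combo)
  for (j in seq_len(n_combo)) {
    fit <- svm_linear_fit(x[, combos[, j], drop = FALSE], y, C = C,
                          gamma = gamma)
    d <- predict(fit, x[, combos[, j], drop = FALSE])
    p[j] <- wilcoxon_rank_sum(d[y], d[!y], tail = "two.sided")
    inf[j] <- informedness(y, d > 0)
  }
  sig <- holm_bonferroni(p, alpha)
  combo_names <- apply(combos, 2, paste, collapse = "+")
  tab <- data.frame(features = combo_names, p = p, significant = sig,
                    informedness = inf, stringsAsFactors = FALSE)
  if (!any(sig)) {
    stop(sprintf(
      "no combination is significant after Holm-Bonferroni at alpha=%g (best p = %.3g)",
      alpha, min(p)))
  }
  cand <- which(sig)
  cand <- cand[order(-inf[cand], p[cand], combo_names[cand])]
  chosen <- combos[, cand[1]]
  structure(
    list(combos = tab, chosen = chosen, alpha = alpha,
         n_combos = n_combo, n_significant = sum(sig)),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "<selection_result> %d combos, %d significant (alpha=%g)\n  chosen: %s (I=%.2f, p=%.3g)\n",
    x$n_combos, x$n_significant, x$alpha, paste(x$chosen, collapse = ", "),
    max(x$combos$informedness[x$combos$significant]),
    x$combos$p[match(paste(x$chosen, collapse = "+"), x$combos$features)]))
  invisible(x)
}

#' Two-stage feature selection on a feature table
#'
#' Min-max normalization (fitted on the full selection cohort, mirroring
#' normalization-before-selection; pass `leakage_safe_params` from a training
#' subset for the leakage-safe variant), LASSO screen, then the exhaustive
#' quadruple search. The screened set can be capped at `max_screened`
#' features (by coefficient magnitude) to bound the combinatorial stage.
#'
#' @param table a `feature_table` (or matrix of features).
#' @param labels binary labels; defaults to the table's `cspca` column.
#' @param folds,seed,weighting passed to [lasso_screen()].
#' @param alpha,C,gamma passed to [exhaustive_quadruple_search()].
#' @param max_screened optional cap on the screened-set size.
#' @param leakage_safe_params optional pre-fitted normalization parameters.
#' @return list with `normalization`, `lasso_subset`, and `result` (a
#'   `selection_result`).
#' @export
select_features <- function(table, labels = NULL, folds = 10, seed = NULL,
                            weighting = "balanced", alpha = 1e-3, C = 1,
                            gamma = 1, max_screened = Inf,
                            leakage_safe_params = NULL) {
  if (is.null(labels)) {
    stopifnot(inherits(table, "feature_table"))
    labels <- table$cspca
  }
  norm <- minmax_normalize(table, params = leakage_safe_params)
  subset <- lasso_screen(norm$x, labels, folds = folds, seed = seed,
                         weighting = weighting)
  if (length(subset) > max_screened) {
    .adc_log("capping screened set at %d of %d features", max_screened,
             length(subset))
    subset <- subset[seq_len(max_screened)]
  }
  if (length(subset) < 4) {
    stop("LASSO screen kept fewer than 4 features (", length(subset), ")")
  }
  res <- exhaustive_quadruple_search(norm$x[, subset, drop = FALSE], labels,
                                     alpha = alpha, C = C, gamma = gamma)
  list(normalization = norm$params, lasso_subset = subset, result = res)
}

#' Persist a selection result as JSON (+ full combo table CSV)
#' @param selection output of [select_features()] or a `selection_result`.
#' @param path JSON destination; the combo table lands at `<path>.combos.csv`.
#' @param top combos kept in the JSON (by p), default 100.
#' @return `path`, invisibly.
#' @export
write_selection <- function(selection, path, top = 100) {
  res <- if (inherits(selection, "selection_result")) selection
    else selection$result
  combos <- res$combos[order(res$combos$p), ]
  out <- list(chosen = res$chosen, alpha = res$alpha,
              n_combos = res$n_combos, n_significant = res$n_significant,
              lasso_subset = selection$lasso_subset,
              combos = head(combos, top))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  write.csv(res$combos, paste0(path, ".combos.csv"), row.names = FALSE)
  invisible(path)
}
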