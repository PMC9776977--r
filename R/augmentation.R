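# Feature-space oversampling of the 4 selected features to a balanced
# dataset (default 200 samples, 100 per class) and the stratified 75/25
# train/test split. Synthetic rows are within-class linear interpolations
# between an original row and one of its k nearest same-class neighbours
# (SMOTE-like), with the mixing weight bounded away from 0 and 1 so no
# original row is ever duplicated.

#' Oversample a 4-feature dataset to a balanced target size
#'
#' @param x numeric matrix (rows = lesions, columns = the 4 selected
#'   features, normalized scale).
#' @param labels binary class labels.
#' @param n_target total size after augmentation (default 200; half per
#'   class).
#' @param seed RNG seed.
#' @param method `"interpolate"` (SMOTE-like, default) or `"jitter"`
#'   (Gaussian noise around originals).
#' @param k nearest same-class neighbours considered (default 5).
#' @param lambda_range mixing-weight bounds for interpolation.
#' @param jitter_sd noise SD (fraction of the per-feature SD) for
#'   `"jitter"`.
#' @return Object of class `augmented_set`: `x`, `labels`, `provenance`
#'   (data.frame: origin, parent row indices, lambda), `seed`, `method`.
#' @export
augment <- function(x, labels, n_target = 200, seed = NULL,
                    method = c("interpolate", "jitter"), k = 5,
                    lambda_range = c(0.05, 0.95), jitter_sd = 0.05) {
  method <- match.arg(method)
  x <- as.matrix(x)
  y <- as.logical(labels)
  stopifnot(nrow(x) == length(y))
  if (n_target < nrow(x)) stop("n_target smaller than the original size")
  per_class <- n_target / 2
  if (per_class != floor(per_class)) stop("n_target must be even")
  if (!is.null(seed)) set.seed(seed)
  out_x <- list(); out_y <- logical(0); prov <- list()
  for (cls in c(FALSE, TRUE)) {
    idx <- which(y == cls)
    n_c <- length(idx)
    if (n_c < 2) stop("each class needs at least 2 rows")
    if (method == "interpolate" && n_c < 5) {
      stop("interpolation augmentation needs at least 5 rows per class")
    }
    if (n_c > per_class) stop("class larger than the per-class target")
    xc <- x[idx, , drop = FALSE]
    n_new <- per_class - n_c
    prov[[length(prov) + 1]] <- data.frame(
      origin = "original", parent_a = idx, parent_b = NA_integer_,
      lambda = NA_real_)
    synth <- NULL
    if (n_new > 0) {
      if (method == "interpolate") {
        dd <- as.matrix(dist(xc))
        diag(dd) <- Inf
        kk <- min(k, n_c - 1)
        nn <- apply(dd, 1, function(r) order(r)[seq_len(kk)])
        nn <- matrix(nn, nrow = kk)   # kk x n_c
        i <- sample.int(n_c, n_new, replace = TRUE)
        j <- vapply(i, function(ii) nn[sample.int(kk, 1), ii], integer(1))
        lam <- runif(n_new, lambda_range[1], lambda_range[2])
        synth <- xc[i, , drop = FALSE] +
          lam * (xc[j, , drop = FALSE] - xc[i, , drop = FALSE])
        prov[[length(prov) + 1]] <- data.frame(
          origin = "synthetic", parent_a = idx[i], parent_b = idx[j],
          lambda = lam)
      } else {
        sds <- apply(xc, 2, sd)
        i <- sample.int(n_c, n_new, replace = TRUE)
        synth <- xc[i, , drop = FALSE] +
          matrix(rnorm(n_new * ncol(x), sd = jitter_sd * rep(sds,
                 each = n_new)), n_new, ncol(x))
        prov[[length(prov) + 1]] <- data.frame(
          origin = "synthetic", parent_a = idx[i], parent_b = NA_integer_,
          lambda = NA_real_)
      }
    }
    out_x[[length(out_x) + 1]] <- rbind(xc, synth)
    out_y <- c(out_y, rep(cls, per_class))
  }
  structure(
    list(x = do.call(rbind, out_x), labels = out_y,
         provenance = do.call(rbind, prov), seed = seed, method = method,
         n_original = nrow(x)),
    class = "augmented_set"
  )
}

#' @export
print.augmented_set <- function(x, ...) {
  cat(sprintf("<augmented_set> %d samples (%d original), %s, balanced %d/%d\n",
              nrow(x$x), x$n_original, x$method, sum(x$labels),
              sum(!x$labels)))
  invisible(x)
}

#' Stratified train/test split of an augmented set
#'
#' Default rule is a stratified random split. The `"margin"` rule fits a
#' pilot linear SVM on all samples and fills the training quota of each
#' class with the samples nearest the decision boundary (smallest absolute
#' decision value), so margin-adjacent samples always land in training.
#'
#' @param aug an [augment()] result, or a list with `x` and `labels`.
#' @param train_frac training fraction (default 0.75).
#' @param rule `"random"` or `"margin"`.
#' @param seed RNG seed (used by the random rule).
#' @return Object of class `split_set`: `train`/`test` (each with `x`,
#'   `labels`, `idx`), `rule`, `seed`.
#' @export
split_augmented <- function(aug, train_frac = 0.75,
                            rule = c("random", "margin"), seed = NULL) {
  rule <- match.arg(rule)
  x <- as.matrix(aug$x); y <- as.logical(aug$labels)
  if (!is.null(seed)) set.seed(seed)
  train_idx <- integer(0)
  pilot <- if (rule == "margin") svm_linear_fit(x, y) else NULL
  for (cls in c(FALSE, TRUE)) {
    idx <- which(y == cls)
    n_tr <- train_frac * length(idx)
    if (n_tr != round(n_tr)) {
      n_tr <- round(n_tr)
      warning(sprintf(
        "train fraction incompatible with exact stratification; using %d of %d",
        n_tr, length(idx)))
    }
    picked <- if (rule == "random") {
      sample(idx, n_tr)
    } else {
      idx[order(abs(predict(pilot, x[idx, , drop = FALSE])))][seq_len(n_tr)]
    }
    train_idx <- c(train_idx, picked)
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(x)), train_idx)
  structure(
    list(train = list(x = x[train_idx, , drop = FALSE],
                      labels = y[train_idx], idx = train_idx),
         test = list(x = x[test_idx, , drop = FALSE],
                     labels = y[test_idx], idx = test_idx),
         rule = rule, seed = seed, train_frac = train_frac),
    class = "split_set"
  )
}

#' @export
print.split_set <- function(x, ...) {
  cat(sprintf("<split_set> rule=%s  train %d (%dP/%dN)  test %d (%dP/%dN)\n",
              x$rule, length(x$train$labels), sum(x$train$labels),
              sum(!x$train$labels), length(x$test$labels),
              sum(x$test$labels), sum(!x$test$labels)))
  invisible(x)
}
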