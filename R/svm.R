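# Soft-margin linear SVM solved as the primal QP with quadprog. No SVM
# package ships with this R installation, so the classifier is implemented
# directly: minimise 1/2 ||w||^2 + C sum(xi) subject to
# y_i (w . x_i + b) >= 1 - xi_i, xi_i >= 0, on inputs divided by the kernel
# scale gamma (mirroring the two-parameter C/gamma search of the reference
# procedure). The primal is preferred over the dual because the linear
# kernel matrix is rank-deficient (rank <= p + 1), which forces a
# solution-distorting ridge on the dual; the primal only needs a negligible
# (1e-8) curvature on b and xi to satisfy the solver's positive-definiteness
# requirement.

#' Fit a linear support vector machine
#'
#' @param x numeric matrix, samples x features.
#' @param y labels: logical, 0/1 or -1/+1 (TRUE/1 is the positive class).
#' @param C misclassification cost (> 0).
#' @param gamma linear kernel scale dividing the inputs (> 0); equivalent to
#'   rescaling C but kept explicit.
#' @return Object of class `linear_svm` with `weights` (original input
#'   scale), `intercept`, the slack variables `xi`, and the hyperparameters.
#' @export
svm_linear_fit <- function(x, y, C = 1, gamma = 1) {
  x <- as.matrix(x)
  y <- .to_pm1(y)
  stopifnot(nrow(x) == length(y), C > 0, gamma > 0)
  if (length(unique(y)) < 2) stop("both classes are required to fit an SVM")
  n <- nrow(x)
  p <- ncol(x)
  xs <- x / gamma
  eps <- 1e-8
  # variables z = (w [p], b, xi [n])
  Dmat <- diag(c(rep(1, p), eps, rep(eps, n)))
  dvec <- c(rep(0, p + 1), rep(-C, n))
  # margin constraints y_i (w . x_i + b) + xi_i >= 1, then xi_i >= 0
  Amat <- cbind(rbind(t(xs * y), y, diag(n)),
                rbind(matrix(0, p + 1, n), diag(n)))
  bvec <- c(rep(1, n), rep(0, n))
  sol <- tryCatch(quadprog::solve.QP(Dmat, dvec, Amat, bvec),
                  error = function(e) {
                    stop("SVM primal QP failed for C=", C, ", gamma=", gamma,
                         ": ", conditionMessage(e))
                  })
  w_s <- sol$solution[seq_len(p)]
  b <- sol$solution[p + 1]
  f0 <- drop(xs %*% w_s) + b
  structure(
    list(weights = w_s / gamma, intercept = b,
         xi = pmax(sol$solution[-seq_len(p + 1)], 0), C = C, gamma = gamma,
         n_sv = sum(y * f0 < 1 + 1e-6)),
    class = "linear_svm"
  )
}

#' Decision values of a linear SVM
#' @param object a `linear_svm`.
#' @param newdata matrix or vector of inputs on the original feature scale.
#' @param ... unused.
#' @return Numeric vector of signed distances (decision values); the class
#'   prediction is `decision > 0`.
#' @export
predict.linear_svm <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  drop(as.matrix(newdata) %*% object$weights) + object$intercept
}

#' @export
print.linear_svm <- function(x, ...) {
  cat(sprintf("<linear_svm> %d features, C=%g, gamma=%g, %d SVs\n",
              length(x$weights), x$C, x$gamma, x$n_sv))
  invisible(x)
}

.to_pm1 <- function(y) {
  if (is.logical(y)) return(ifelse(y, 1, -1))
  u <- sort(unique(y))
  if (identical(u, c(-1, 1))) return(as.numeric(y))
  if (identical(as.numeric(u), c(0, 1))) return(ifelse(y == 1, 1, -1))
  stop("labels must be logical, 0/1 or -1/+1")
}
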