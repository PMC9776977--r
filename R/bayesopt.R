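# Small Gaussian-process expected-improvement optimizer used for the SVM
# hyperparameter search over (log10 C, log10 gamma). The search contract is
# what matters here (noisy objective, box constraints, a few dozen
# evaluations); the GP uses a squared-exponential kernel with a fixed length
# scale on [0,1]-normalised inputs.

#' Maximise a noisy function by Gaussian-process expected improvement
#'
#' @param fn function of one numeric vector (length `d`) returning a scalar
#'   to maximise.
#' @param lower,upper numeric bounds of the box (length d).
#' @param n_init random initial design points (default 8).
#' @param n_iter expected-improvement iterations after the design
#'   (default 30).
#' @param length_scale GP kernel length scale on the unit cube.
#' @param noise observation noise variance (relative to the signal).
#' @return list with `par` (best input), `value` (best observed objective),
#'   and the evaluation `history` data.frame.
#' @export
bayes_opt <- function(fn, lower, upper, n_init = 8, n_iter = 30,
                      length_scale = 0.25, noise = 1e-3) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  unscale <- function(u) lower + u * (upper - lower)
  X <- matrix(runif(n_init * d), ncol = d)
  y <- apply(X, 1, function(u) fn(unscale(u)))
  kern <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * length_scale^2))
  }
  for (it in seq_len(n_iter)) {
    s2 <- max(stats::var(y), 1e-10)
    Kxx <- s2 * kern(X, X) + diag(s2 * noise + 1e-8, nrow(X))
    L <- chol(Kxx)
    ymu <- mean(y)
    alpha <- backsolve(L, backsolve(L, y - ymu, transpose = TRUE))
    cand <- matrix(runif(256 * d), ncol = d)
    Ks <- s2 * kern(cand, X)
    mu <- drop(Ks %*% alpha) + ymu
    v <- backsolve(L, t(Ks), transpose = TRUE)
    sig2 <- pmax(s2 - colSums(v^2), 1e-12)
    sig <- sqrt(sig2)
    best <- max(y)
    z <- (mu - best) / sig
    ei <- (mu - best) * stats::pnorm(z) + sig * stats::dnorm(z)
    u_next <- cand[which.max(ei), , drop = FALSE]
    y <- c(y, fn(unscale(drop(u_next))))
    X <- rbind(X, u_next)
  }
  i <- which.max(y)
  hist <- as.data.frame(sweep(sweep(X, 2, upper - lower, "*"), 2, lower, "+"))
  names(hist) <- paste0("x", seq_len(d))
  hist$y <- y
  list(par = unscale(drop(X[i, ])), value = y[i], history = hist)
}
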