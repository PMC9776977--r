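# Independent oracles: direct-formula implementations kept deliberately
# separate from the package's code paths.

# first-order statistics by direct formula evaluation
oracle_stat <- function(x, stat, n_bins = 32, bin_range = range(x)) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  hist_p <- function() {
    if (bin_range[2] <= bin_range[1]) return(1)
    br <- seq(bin_range[1], bin_range[2], length.out = n_bins + 1)
    idx <- pmin(pmax(findInterval(x, br, rightmost.closed = TRUE), 1), n_bins)
    tabulate(idx, n_bins) / n
  }
  switch(stat,
    mean = mu,
    median = unname(quantile(x, 0.5, type = 7)),
    kurtosis = if (m2 > 0) m4 / m2^2 else 3,
    skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    entropy = { p <- hist_p(); p <- p[p > 0]; -sum(p * log2(p)) },
    uniformity = { p <- hist_p(); sum(p^2) },
    iqr = unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)),
    cv = if (mu != 0) sqrt(m2) / mu else 0,
    std = sqrt(m2),
    mad = unname(quantile(abs(x - quantile(x, 0.5, type = 7)), 0.5,
                          type = 7)))
}

# naive O(N w^2) double-loop sliding-window maps
oracle_local_map <- function(img, gland, stat, window = 9, min_frac = 0.5,
                             n_bins = 32) {
  nr <- nrow(img); nc <- ncol(img)
  h <- window %/% 2
  rng <- range(img[gland])
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!gland[i, j]) next
    vals <- c()
    for (di in -h:h) for (dj in -h:h) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && gland[ii, jj]) {
        vals <- c(vals, img[ii, jj])
      }
    }
    if (length(vals) >= min_frac * window^2 && length(vals) >= 2) {
      out[i, j] <- oracle_stat(vals, stat, n_bins = n_bins, bin_range = rng)
    }
  }
  out
}

# exact Wilcoxon rank-sum p by enumeration of all rank assignments
oracle_wilcoxon_exact <- function(a, b, tail = "two.sided") {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(m)])
  combos <- combn(m + n, m)
  ws <- colSums(matrix(r[combos], nrow = m))
  switch(tail,
    greater = mean(ws >= w_obs),
    less = mean(ws <= w_obs),
    two.sided = min(1, 2 * min(mean(ws >= w_obs), mean(ws <= w_obs))))
}

# Kruskal-Wallis tie-corrected statistic by direct formula
oracle_kw_stat <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), 0)) - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Ansari-Bradley statistic by direct rank scoring
oracle_ab_stat <- function(a, b) {
  x <- c(a, b)
  N <- length(x)
  r <- rank(x)
  score <- pmin(r, N + 1 - r)
  sum(score[seq_along(a)])
}

# AUC by all-pairs comparison with tie credit 1/2
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Holm-Bonferroni step-down by the textbook recipe
oracle_holm <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  rej <- logical(m)
  for (k in seq_len(m)) {
    if (p[o[k]] > alpha / (m - k + 1)) break
    rej[o[k]] <- TRUE
  }
  rej
}

# small helper: a flat test image + full gland
flat_image <- function(value = 1000, nr = 20, nc = 20, spacing = c(1, 1)) {
  adc_image(matrix(value, nr, nc), spacing)
}

full_gland <- function(nr = 20, nc = 20) {
  roi_mask(matrix(TRUE, nr, nc), role = "gland")
}

python_ok <- function() nzchar(Sys.which("python"))
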