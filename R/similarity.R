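# Gleason-group similarity analysis on radiomic scores: Kruskal-Wallis
# omnibus tests, one-tail Wilcoxon rank-sum pairwise comparisons (alternative:
# the higher Gleason group has larger scores), and Ansari-Bradley dispersion
# tests after per-group median removal.

#' Wilcoxon rank-sum test p-value
#'
#' Exact when both samples are small and tie-free, otherwise the normal
#' approximation with continuity and tie correction. `tail` states the
#' alternative for the first sample: `"greater"` means `a` tends larger
#' than `b`.
#'
#' @param a,b numeric samples (each >= 2 observations).
#' @param tail `"two.sided"`, `"greater"` or `"less"`.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, tail = c("two.sided", "greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(a) >= 2, length(b) >= 2)
  suppressWarnings(
    wilcox.test(a, b, alternative = tail, correct = TRUE)$p.value
  )
}

#' Kruskal-Wallis omnibus test p-value
#'
#' Chi-square approximation with tie correction; identical groups give
#' H = 0 and p = 1.
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return p-value.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) return(1)    # zero statistic path
  kruskal.test(x, g)$p.value
}

#' Ansari-Bradley dispersion test after median removal
#'
#' Each sample's median is subtracted before the test, so a pure location
#' shift does not register as a dispersion difference. Exact for small
#' tie-free samples, otherwise the normal approximation. A constant group
#' makes the test undefined and `NA` is returned.
#'
#' @param a,b numeric samples (each >= 2 observations).
#' @return p-value, or `NA` when undefined.
#' @export
ansari_bradley <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  a <- a - median(a); b <- b - median(b)
  if (length(unique(a)) == 1 || length(unique(b)) == 1) return(NA_real_)
  suppressWarnings(ansari.test(a, b)$p.value)
}

#' Gleason-group similarity report on radiomic scores
#'
#' Runs the omnibus Kruskal-Wallis tests (GG1/GG2/GG3; GG1/GG2/GG>=3; and
#' among GG>=3, i.e. GG3/GG4/GG5), the pairwise one-tail Wilcoxon rank-sum
#' tests with the alternative that the higher group has larger scores, and
#' pairwise Ansari-Bradley dispersion tests after median removal. Location
#' tests are judged at alpha = 1e-3, dispersion tests at alpha = 0.05.
#' Groups with fewer than 2 members are skipped and recorded.
#'
#' @param scores numeric radiomic scores, one per lesion.
#' @param gg integer Gleason Grade group labels (1-5).
#' @param alpha_location,alpha_dispersion significance levels.
#' @return Object of class `gg_similarity`: group summaries, omnibus,
#'   pairwise location and dispersion p-values, and the alphas.
#' @export
gg_similarity_report <- function(scores, gg, alpha_location = 1e-3,
                                 alpha_dispersion = 0.05) {
  stopifnot(length(scores) == length(gg), all(gg %in% 1:5))
  pools <- list("1" = scores[gg == 1], "2" = scores[gg == 2],
                "3" = scores[gg == 3], "4" = scores[gg == 4],
                "5" = scores[gg == 5], "ge3" = scores[gg >= 3])
  usable <- names(pools)[lengths(pools) >= 2]
  skipped <- setdiff(names(pools), usable)
  for (s in skipped) .adc_log("group GG=%s has < 2 lesions, skipped", s)
  summaries <- data.frame(
    group = usable,
    n = vapply(pools[usable], length, integer(1)),
    median = vapply(pools[usable], median, numeric(1)),
    variance = vapply(pools[usable], stats::var, numeric(1))
  )
  kw <- function(gs) {
    gs <- gs[gs %in% usable]
    if (length(gs) < 2) return(NA_real_)
    kruskal_wallis(pools[gs])
  }
  omnibus <- c(gg1_gg2_gg3 = kw(c("1", "2", "3")),
               gg1_gg2_ge3 = kw(c("1", "2", "ge3")),
               among_ge3 = kw(c("3", "4", "5")))
  pairs <- list(c("1", "2"), c("1", "3"), c("2", "3"),
                c("1", "ge3"), c("2", "ge3"))
  pair_name <- vapply(pairs, paste, character(1), collapse = "_vs_")
  loc <- dis <- setNames(rep(NA_real_, length(pairs)), pair_name)
  for (k in seq_along(pairs)) {
    lo <- pairs[[k]][1]; hi <- pairs[[k]][2]
    if (!(lo %in% usable) || !(hi %in% usable)) next
    # one-tail: the higher Gleason group tends to larger scores
    loc[k] <- wilcoxon_rank_sum(pools[[hi]], pools[[lo]], tail = "greater")
    dis[k] <- ansari_bradley(pools[[lo]], pools[[hi]])
  }
  structure(
    list(summaries = summaries, omnibus = omnibus, pairwise_location = loc,
         pairwise_dispersion = dis, alpha_location = alpha_location,
         alpha_dispersion = alpha_dispersion, skipped = skipped),
    class = "gg_similarity"
  )
}

#' @export
print.gg_similarity <- function(x, ...) {
  cat("<gg_similarity>\n")
  print(x$summaries, row.names = FALSE)
  cat("omnibus p:", paste(names(x$omnibus),
                          signif(x$omnibus, 3), collapse = "  "), "\n")
  cat("pairwise one-tail Wilcoxon p (alpha", x$alpha_location, "):\n")
  print(signif(x$pairwise_location, 3))
  cat("pairwise Ansari-Bradley p (alpha", x$alpha_dispersion, "):\n")
  print(signif(x$pairwise_dispersion, 3))
  invisible(x)
}

#' Boxplot of radiomic scores by Gleason group
#'
#' Groups GG1, GG2 and the combined GG>=3, mirroring the similarity
#' analysis.
#' @param scores,gg as in [gg_similarity_report()].
#' @param path optional PNG/SVG destination; when `NULL` the ggplot object
#'   is returned.
#' @return The ggplot object (invisibly when written to `path`).
#' @export
gg_similarity_boxplot <- function(scores, gg, path = NULL) {
  grp <- factor(ifelse(gg >= 3, "GG>=3", paste0("GG", gg)),
                levels = c("GG1", "GG2", "GG>=3"))
  df <- data.frame(score = scores, group = grp)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "radiomic score") +
    ggplot2::theme_minimal()
  if (is.null(path)) return(p)
  ggplot2::ggsave(path, p, width = 4, height = 4, dpi = 150)
  invisible(p)
}
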