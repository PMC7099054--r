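#' Nonparametric group comparison
#'
#' Two independent groups are compared with the Mann-Whitney U test, two
#' paired groups with the Wilcoxon signed-rank test, and three or more
#' groups with the Kruskal-Wallis test followed by Dunn's post-hoc pairwise
#' comparisons with Holm-Sidak adjustment. All p-values are two-tailed.
#'
#' @param values_by_group named list of numeric vectors of per-donor
#'   summaries.
#' @param design `"independent"` or `"paired"` (paired requires exactly two
#'   equal-length groups).
#' @return list of class `group_comparison`: `test`, `statistic`, `p_value`,
#'   and for >= 3 groups `posthoc` (data frame of pairwise Dunn z and
#'   adjusted p).
#' @export
compare_groups <- function(values_by_group,
                           design = c("independent", "paired")) {
  design <- match.arg(design)
  k <- length(values_by_group)
  if (k < 2L) stop("need at least two groups")
  ns <- vapply(values_by_group, length, 0L)
  if (any(ns < 2L)) {
    stop("insufficient observations in group: ",
         paste(names(values_by_group)[ns < 2L], collapse = ", "))
  }
  nm <- names(values_by_group)
  if (k == 2L) {
    if (design == "paired") {
      if (ns[1L] != ns[2L]) stop("paired design requires equal group sizes")
      ht <- stats::wilcox.test(values_by_group[[1L]], values_by_group[[2L]],
                               paired = TRUE, exact = FALSE, correct = TRUE)
      test <- "wilcoxon_signed_rank"
    } else {
      ht <- stats::wilcox.test(values_by_group[[1L]], values_by_group[[2L]],
                               exact = (sum(ns) <= 30), correct = TRUE)
      test <- "mann_whitney_u"
    }
    out <- list(test = test, groups = nm, statistic = unname(ht$statistic),
                p_value = ht$p.value)
  } else {
    x <- unlist(values_by_group, use.names = FALSE)
    g <- factor(rep(nm, ns), levels = nm)
    ht <- stats::kruskal.test(x, g)
    out <- list(test = "kruskal_wallis", groups = nm,
                statistic = unname(ht$statistic), p_value = ht$p.value,
                posthoc = dunn_posthoc(x, g))
  }
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, two-tailed p = %.4g\n",
              x$test, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("Dunn post-hoc (Holm-Sidak adjusted):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}

# Dunn's z statistics on the joint ranks with tie correction; two-tailed
# p-values, Holm-Sidak adjusted
dunn_posthoc <- function(x, g) {
  r <- rank(x)
  N <- length(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  lev <- levels(g)
  pairs <- utils::combn(lev, 2L)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], z = z,
             p_value = p, p_adjusted = adjust_pvalues(p),
             stringsAsFactors = FALSE)
}

#' Holm-Sidak step-down p-value adjustment
#'
#' With the m p-values sorted ascending, the i-th adjusted value is
#' max over j <= i of 1 - (1 - p_j)^(m - j + 1), clipped to 1; adjusted
#' values are monotone nondecreasing in rank and never smaller than raw.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
adjust_pvalues <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals)
  sidak <- 1 - (1 - pvals[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(sidak), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Squared Pearson correlation of paired summaries
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return R squared (`NA` with a warning when either input has zero
#'   variance).
#' @export
paired_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("paired correlation needs equal lengths >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}
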