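# Concordance and known-groups analytics computed directly from the compact
# forms a published report provides: an ordinal contingency table and group
# summary statistics (n, M, SD).  Both are algebraically identical to the
# raw-data computations when the inputs are exact, which the tests verify.

#' Construct an ordinal contingency table
#'
#' @param counts Non-negative integer matrix, rows and columns ordered
#'   least to most severe.
#' @param row_labels,col_labels Ordered category labels.
#' @return Object of class `contingency_table` (a matrix with dimnames and
#'   an `n` attribute).
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  if (is.null(row_labels)) row_labels <- paste0("row", seq_len(nrow(counts)))
  if (is.null(col_labels)) col_labels <- paste0("col", seq_len(ncol(counts)))
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts, n = sum(counts), class = c("contingency_table", "matrix"))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x); attr(m, "n") <- NULL
  m <- cbind(m, Total = rowSums(m))
  m <- rbind(m, Total = colSums(m))
  print(m)
  invisible(x)
}

#' Read a contingency table from CSV
#'
#' First column = row labels, remaining columns = counts per column
#' category.
#'
#' @param path CSV file path.
#' @export
read_contingency_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  contingency_table(as.matrix(df[-1L]), row_labels = df[[1L]])
}

#' Cross-tabulate two paired level assignments
#'
#' @param levels_a,levels_b Factors (or vectors coercible to factors) of
#'   equal length; pairs with a missing value in either vector are dropped.
#' @return A [contingency_table()] whose counts exhaustively partition the
#'   complete pairs.
#' @export
crosstab <- function(levels_a, levels_b) {
  if (length(levels_a) != length(levels_b))
    stop("'levels_a' and 'levels_b' must have equal length", call. = FALSE)
  if (!is.factor(levels_a)) levels_a <- factor(levels_a)
  if (!is.factor(levels_b)) levels_b <- factor(levels_b)
  tab <- table(levels_a, levels_b)
  contingency_table(matrix(as.integer(tab), nrow = nlevels(levels_a),
                           dimnames = NULL),
                    row_labels = levels(levels_a),
                    col_labels = levels(levels_b))
}

#' Tie-corrected (midrank) Spearman correlation from a contingency table
#'
#' The Spearman rank correlation of the two ordinal margins computed
#' directly from the cell counts using midranks, exactly equal to expanding
#' the table into unit records, midranking, and taking the Pearson
#' correlation of the ranks.
#'
#' @param tab A [contingency_table()] with both axes ordered.
#' @return Numeric rho in \[-1, 1\], with attributes `p_value` (large-sample
#'   t approximation, reported for orientation only) and `n`.
#' @export
spearman_from_table <- function(tab) {
  stopifnot(inherits(tab, "contingency_table"))
  n <- sum(tab)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (sum(rs > 0) < 2L || sum(cs > 0) < 2L)
    stop("degenerate margin: all mass in one row or column; Spearman undefined",
         call. = FALSE)
  midrank <- function(m) cumsum(m) - m / 2 + 0.5  # midrank of each category
  r <- midrank(rs); c <- midrank(cs)
  rbar <- (n + 1) / 2
  num <- sum(tab * outer(r - rbar, c - rbar))
  den <- sqrt(sum(rs * (r - rbar)^2) * sum(cs * (c - rbar)^2))
  rho <- num / den
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  structure(rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Group summary statistics
#'
#' @param label Group labels.
#' @param n Group sizes (each at least 2).
#' @param mean,sd Group means and standard deviations (sd >= 0).
#' @return Data frame of class `group_summaries`.
#' @export
group_summaries <- function(label, n, mean, sd) {
  n <- as.integer(n)
  if (any(n < 2L)) stop("each group needs n >= 2", call. = FALSE)
  if (any(sd < 0)) stop("standard deviations must be non-negative",
                        call. = FALSE)
  df <- data.frame(label = as.character(label), n = n,
                   mean = as.numeric(mean), sd = as.numeric(sd),
                   stringsAsFactors = FALSE)
  class(df) <- c("group_summaries", "data.frame")
  df
}

#' Read group summaries from CSV (columns label, n, mean, sd)
#' @param path CSV file path.
#' @export
read_group_summaries <- function(path) {
  df <- utils::read.csv(path)
  group_summaries(df$label, df$n, df$mean, df$sd)
}

#' One-way ANOVA from group summary statistics
#'
#' Between-group sum of squares from the group sizes and means, within-group
#' sum of squares from `(n - 1) * sd^2`; identical to raw-data one-way ANOVA
#' when the summaries are exact.
#'
#' @param groups A [group_summaries()] data frame (>= 2 groups, each
#'   n >= 2).
#' @return Object of class `anova_summary` with `F`, `df_between`,
#'   `df_within`, `p`, `eta_squared`, `ms_within`, plus the sums of squares.
#'   `F` is `Inf` when the within-group mean square is zero and the means
#'   differ.
#' @export
anova_from_summaries <- function(groups) {
  stopifnot(inherits(groups, "group_summaries"))
  g <- nrow(groups)
  if (g < 2L) stop("need at least 2 groups", call. = FALSE)
  N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1L) * groups$sd^2)
  dfb <- g - 1L; dfw <- N - g
  msb <- ssb / dfb; msw <- ssw / dfw
  Fstat <- if (msw == 0) { if (ssb > 0) Inf else 0 } else msb / msw
  structure(list(F = Fstat, df_between = dfb, df_within = dfw,
                 p = stats::pf(Fstat, dfb, dfw, lower.tail = FALSE),
                 eta_squared = if (ssb + ssw > 0) ssb / (ssb + ssw) else 0,
                 ms_within = msw, ss_between = ssb, ss_within = ssw,
                 grand_mean = grand, groups = groups),
            class = "anova_summary")
}

#' @export
print.anova_summary <- function(x, ...) {
  cat(sprintf("One-way ANOVA from summaries: F(%d, %d) = %.3f, p = %.3g, eta^2 = %.3f\n",
              x$df_between, x$df_within, x$F, x$p, x$eta_squared))
  invisible(x)
}

#' Bonferroni post-hoc pairwise comparisons from group summaries
#'
#' For each pair (i, j): difference of means, pooled standard error
#' `sqrt(MSW * (1/n_i + 1/n_j))`, t with `N - g` degrees of freedom,
#' Bonferroni-adjusted p (`min(1, m * p_raw)`), and the Bonferroni-adjusted
#' confidence interval `diff +/- t_{df, alpha/(2m)} * se` (the adjusted
#' critical value is what published tables of this kind use: half-width /
#' SE is about 2.66, not the unadjusted 1.97).
#'
#' @param groups A [group_summaries()] data frame.
#' @param alpha Family significance level (default 0.05).
#' @param m Number of comparisons for the correction; defaults to all
#'   `g * (g - 1) / 2` pairs.
#' @return Data frame with one row per pair: `pair`, `mean_difference`,
#'   `se`, `ci_low`, `ci_high`, `t`, `p_raw`, `p_adjusted`.
#' @export
bonferroni_posthoc <- function(groups, alpha = 0.05,
                               m = nrow(groups) * (nrow(groups) - 1L) / 2L) {
  stopifnot(inherits(groups, "group_summaries"))
  a <- anova_from_summaries(groups)
  msw <- a$ms_within; dfw <- a$df_within
  crit <- stats::qt(1 - alpha / (2 * m), df = dfw)
  g <- nrow(groups)
  pairs <- utils::combn(g, 2L)
  out <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    diff <- groups$mean[i] - groups$mean[j]
    se <- sqrt(msw * (1 / groups$n[i] + 1 / groups$n[j]))
    tstat <- if (se > 0) diff / se else 0
    p_raw <- 2 * stats::pt(-abs(tstat), df = dfw)
    data.frame(pair = sprintf("%s vs %s", groups$label[i], groups$label[j]),
               mean_difference = diff, se = se,
               ci_low = diff - crit * se, ci_high = diff + crit * se,
               t = tstat, p_raw = p_raw,
               p_adjusted = min(1, m * p_raw),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
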