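## Group-comparison statistics: two-sided Wilcoxon rank-sum tests (exact
## enumeration for small tie-free samples, normal approximation with tie and
## continuity corrections otherwise), Benjamini-Hochberg step-up adjustment,
## Spearman correlations, and the feature-comparison bookkeeping
## ("initially significant" p < 0.05 vs "FDR-significant" q < 0.05).

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact p by full enumeration of rank assignments when the pooled sample size
#' is at most 12 and there are no ties; otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return Two-sided p-value.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6)) # 0.1
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) {
    stop("both groups must contain at least one observation", call. = FALSE)
  }
  pooled <- c(x, y)
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(pooled)
  w <- sum(r[seq_len(nx)])
  ties <- any(duplicated(pooled))
  if (n <= 12L && !ties) {
    # exact: enumerate all C(n, nx) assignments of ranks to group x
    sums <- utils::combn(n, nx, FUN = sum)
    p_le <- mean(sums <= w)
    p_ge <- mean(sums >= w)
    return(min(1, 2 * min(p_le, p_ge)))
  }
  mu <- nx * (n + 1) / 2
  tie_tab <- table(pooled)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * stats::pnorm(-z))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_i = min over j with p_(j) >= p_(i) of m p_(j) / j, capped at 1, mapped
#' back to input order.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / seq(m, 1) * p[o]))[ro]
}

#' Spearman rank correlation with p-value
#'
#' rho is the Pearson correlation of mid-ranks. The p-value uses the
#' t-approximation, or exact permutation enumeration for n <= 8.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return list(rho, p).
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
  }
  list(rho = rho, p = p)
}

# all permutations of 1..n as a matrix (n! rows); n is small (<= 8)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (first in seq_len(n)) {
    remaining <- sub + (sub >= first) # map 1..n-1 onto {1..n} \ {first}
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, remaining[r, ])
      row <- row + 1L
    }
  }
  out
}

#' Compare features between groups with BH correction
#'
#' Two-group mode: one two-sided Wilcoxon rank-sum test per feature; BH across
#' all features of the family. Time-course mode: all pairwise time-point tests
#' per feature with BH across the pooled feature x pair family (a feature is
#' then significant if any pair is). Constant features are skipped with p = 1.
#'
#' @param features Numeric matrix, samples x features (rownames = sample ids).
#' @param metadata data.frame with a `sample` column and the grouping columns.
#' @param grouping A list: `type` (`"two_group"` or `"time_course"`), `column`
#'   (metadata column), `groups` (two labels, two-group mode), and optional
#'   `at` (named list of metadata filters applied first, e.g.
#'   `list(time_point = "5 days")`).
#' @return data.frame(feature, group1, group2, median_g1, median_g2, direction,
#'   p, q, initially_significant, fdr_significant); one row per feature
#'   (two-group) or per feature x time-point pair (time-course).
#' @export
compare_features <- function(features, metadata, grouping) {
  stopifnot(is.matrix(features), !is.null(rownames(features)))
  md <- metadata
  if (!is.null(grouping$at)) {
    for (key in names(grouping$at)) {
      if (!key %in% names(md)) {
        stop(sprintf("unknown grouping key '%s'", key), call. = FALSE)
      }
      md <- md[md[[key]] %in% grouping$at[[key]], , drop = FALSE]
    }
  }
  if (!grouping$column %in% names(md)) {
    stop(sprintf("unknown grouping key '%s'", grouping$column), call. = FALSE)
  }
  md <- md[md$sample %in% rownames(features), , drop = FALSE]
  type <- grouping$type %||% "two_group"
  pairs <- if (type == "two_group") {
    if (length(grouping$groups) != 2L) {
      stop("two-group mode needs exactly two group labels", call. = FALSE)
    }
    list(grouping$groups)
  } else {
    lv <- sort(unique(md[[grouping$column]]))
    if (length(lv) < 2L) stop("time-course mode needs >= 2 levels", call. = FALSE)
    utils::combn(lv, 2, simplify = FALSE)
  }
  rows <- list()
  for (pr in pairs) {
    s1 <- md$sample[md[[grouping$column]] == pr[1]]
    s2 <- md$sample[md[[grouping$column]] == pr[2]]
    if (length(s1) < 2L || length(s2) < 2L) {
      stop(sprintf("grouping '%s' vs '%s' needs >= 2 samples per group",
                   pr[1], pr[2]), call. = FALSE)
    }
    for (f in colnames(features)) {
      v1 <- features[s1, f]; v2 <- features[s2, f]
      constant <- length(unique(c(v1, v2))) == 1L
      p <- if (constant) 1 else rank_sum_test(v1, v2)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group1 = pr[1], group2 = pr[2],
        median_g1 = stats::median(v1), median_g2 = stats::median(v2),
        direction = sign(stats::median(v1) - stats::median(v2)),
        p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$initially_significant <- out$p < 0.05
  out$fdr_significant <- out$q < 0.05
  rownames(out) <- NULL
  out
}

#' Any-pair feature significance summary for a time-course comparison
#' @param comparison Output of [compare_features()] (time-course mode).
#' @return data.frame(feature, initially_significant, fdr_significant): a
#'   feature is flagged if any of its time-point pairs is.
#' @export
feature_significance <- function(comparison) {
  agg <- stats::aggregate(
    cbind(initially_significant, fdr_significant) ~ feature,
    data = comparison, FUN = any)
  agg[order(agg$feature), , drop = FALSE]
}
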