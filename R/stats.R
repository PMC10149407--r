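# Rank-based and proportion tests used by the TF-candidate cascade.
# Implemented from first principles; base R equivalents serve as
# cross-check oracles in the test suite.

test_result <- function(statistic, p, method, sides, n_per_group) {
  structure(list(statistic = statistic, p = min(max(p, 0), 1),
                 method = method, sides = sides, n_per_group = n_per_group),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s (%s-sided): statistic = %.6g, p = %.4g, n = %s\n",
              x$method, x$sides, x$statistic, x$p,
              paste(x$n_per_group, collapse = "+")))
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with mid-ranks and the standard tie correction; p-value
#' from the chi-square approximation with k-1 degrees of freedom. Fully
#' tied data (zero tie-correction denominator) return p = 1.
#'
#' @param groups List of >= 2 numeric vectors, each non-empty.
#' @return A `test_result`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  if (n < 3L) stop("need total N >= 3")
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)                              # mid-ranks
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  cf <- 1 - sum(ties^3 - ties) / (n^3 - n)  # tie correction factor
  if (cf <= 0) {
    return(test_result(0, 1, "Kruskal-Wallis", "two", lengths(groups)))
  }
  h <- h / cf
  p <- stats::pchisq(h, df = length(groups) - 1L, lower.tail = FALSE)
  test_result(h, p, "Kruskal-Wallis", "two", lengths(groups))
}

# all rank-sum values of the first-group under H0, by enumeration
ranksum_enumeration <- function(nx, ny) {
  idx <- utils::combn(nx + ny, nx)
  colSums(matrix(seq_len(nx + ny)[idx], nrow = nx))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact by complete enumeration of rank assignments when the combined
#' sample size is at most `exact_limit` and the data are tie-free;
#' otherwise the normal approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors.
#' @param exact_limit Combined-n crossover to the normal approximation.
#' @return A `test_result`.
#' @export
wilcoxon_ranksum <- function(x, y, exact_limit = 12L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y); n <- nx + ny
  all_ranks <- rank(c(x, y))
  w <- sum(all_ranks[seq_len(nx)])
  has_ties <- anyDuplicated(c(x, y)) > 0L
  mu <- nx * (n + 1) / 2
  if (!has_ties && n <= exact_limit) {
    ws <- ranksum_enumeration(nx, ny)
    p <- 2 * min(mean(ws <= w), mean(ws >= w))
    return(test_result(w, min(p, 1), "Wilcoxon rank-sum (exact)", "two", c(nx, ny)))
  }
  ties <- table(c(x, y))
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(test_result(w, 1, "Wilcoxon rank-sum (normal approx)", "two", c(nx, ny)))
  }
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)  # continuity correction
  p <- 2 * stats::pnorm(-abs(z))
  test_result(w, min(p, 1), "Wilcoxon rank-sum (normal approx)", "two", c(nx, ny))
}

#' One-sided two-proportion test (greater)
#'
#' Pooled-proportion z test of H1: x1/n1 > x2/n2, upper-tail normal
#' p-value, with a Yates-style continuity correction on by default.
#'
#' @param x1,n1 Successes and trials in the focal group.
#' @param x2,n2 Successes and trials in the background group.
#' @param correct Apply the continuity correction.
#' @return A `test_result`.
#' @export
two_proportion_greater <- function(x1, n1, x2, n2, correct = TRUE) {
  stopifnot(n1 >= 1L, n2 >= 1L, x1 >= 0L, x2 >= 0L, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  delta <- p1 - p2
  if (correct) {
    h <- min(0.5 * (1 / n1 + 1 / n2), abs(delta))
    delta <- delta - sign(delta) * h
  }
  if (se == 0) {
    # pooled proportion 0 or 1: both groups identical in rate
    return(test_result(0, 0.5, "two-proportion z (pooled)", "one", c(n1, n2)))
  }
  z <- delta / se
  test_result(z, stats::pnorm(z, lower.tail = FALSE),
              "two-proportion z (pooled)", "one", c(n1, n2))
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' X counts marked items in a size-`n` draw without replacement from a
#' population of `N` items of which `K` are marked. Terms are accumulated
#' in log space via `lchoose`.
#'
#' @param k Observed overlap.
#' @param K Marked items in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return P(X >= k), a single number in \[0, 1\].
#' @export
hypergeometric_ge <- function(k, K, n, N) {
  stopifnot(k >= 0, K >= 0, n >= 0, K <= N, n <= N, k <= min(K, n))
  if (k == 0) return(1)
  i <- k:min(K, n)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(logp)
  min(1, exp(m) * sum(exp(logp - m)))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (`min(1, m p)`) or Benjamini-Hochberg step-up with
#' monotonicity enforcement. Input order is preserved.
#'
#' @param ps Numeric vector of p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `ps`.
#' @export
adjust_p <- function(ps, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (length(ps) == 0L) return(numeric(0))
  if (any(!is.finite(ps)) || any(ps < 0) || any(ps > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(ps)
  if (method == "bonferroni") return(pmin(1, m * ps))
  o <- order(ps, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * ps[o]))[ro]
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. A constant input vector has no
#' defined rank correlation and returns NA with a warning.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\], or NA.
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    warning("constant vector: rank correlation undefined")
    return(NA_real_)
  }
  stats::cor(rank(x), rank(y))
}

#' Complete-linkage hierarchical clustering
#'
#' Naive agglomeration over an explicit distance matrix; at every step the
#' closest active pair merges, ties broken by the smallest pair of cluster
#' indices. Returns an object in the layout of [stats::hclust()].
#'
#' @param D Symmetric distance matrix with zero diagonal (matrix or `dist`).
#' @param labels Optional leaf labels; defaults to `rownames(D)`.
#' @return Object of class `hclust` (merge, height, order, labels).
#' @export
hclust_complete <- function(D, labels = NULL) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(abs(diag(D)) > 1e-12)) {
    stop("D must be symmetric with zero diagonal")
  }
  n <- nrow(D)
  stopifnot(n >= 2L)
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  # cluster ids: negative = singleton leaf, positive = merge step index
  active <- as.list(-seq_len(n))
  names(active) <- NULL
  d <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  idx <- seq_len(n)   # row/col of d corresponding to each active cluster
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (d[i, j] < best[1] - 1e-15) best <- c(d[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    merge[step, ] <- sort(c(active[[i]], active[[j]]))
    height[step] <- best[1]
    # complete linkage: new distance = max of the two
    newd <- pmax(d[i, ], d[j, ])[-c(i, j)]
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], newd), c(newd, 0))
    active <- c(active[keep], list(step))
  }
  ord <- hclust_leaf_order(merge)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labels, method = "complete",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

hclust_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}
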