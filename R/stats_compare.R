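# Comparative statistics across region classes / species: Pearson
# correlation with two-sided p, one-way ANOVA F-test, Tukey HSD (Tukey-Kramer
# for unbalanced groups). Implemented from the textbook formulas; base R's
# fitted-model machinery serves as the independent reference in the tests.

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, function(g) any(!is.finite(g)), logical(1))))
    stop("groups contain non-finite values", call. = FALSE)
  groups
}

#' Pearson correlation with two-sided p-value
#'
#' Sample correlation r with p from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), each with nonzero
#'   variance.
#' @return list of class `tr_test` with `statistic` (r), `p_value`, `df`.
#' @examples
#' pearson_test(c(1, 2, 3, 4), c(2, 1, 4, 3))
#' @export
pearson_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  sx <- sum((x - mean(x))^2); sy <- sum((y - mean(y))^2)
  if (sx == 0 || sy == 0)
    stop("correlation undefined: constant vector", call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) / sqrt(sx * sy)
  df <- n - 2L
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * pt(abs(t), df, lower.tail = FALSE)
  }
  structure(list(method = "pearson", statistic = r, p_value = p, df = df),
            class = "tr_test")
}

#' One-way ANOVA F-test
#'
#' `F = MS_between / MS_within` with p from the F distribution on
#' (k - 1, N - k) degrees of freedom.
#'
#' @param groups named list of numeric vectors (>= 2 groups, total n > k).
#' @return list of class `tr_test` with `statistic` (F), `p_value`, `df`
#'   (df1, df2), and the mean squares.
#' @export
anova_oneway <- function(groups) {
  groups <- .check_groups(groups)
  k <- length(groups)
  n <- lengths(groups)
  N <- sum(n)
  if (N <= k) stop("need total n > number of groups", call. = FALSE)
  gm <- sum(unlist(groups)) / N
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  if (msw == 0 && msb == 0)
    stop("degenerate data: no variance within or between groups",
         call. = FALSE)
  f <- if (msw == 0) Inf else msb / msw
  p <- pf(f, k - 1, N - k, lower.tail = FALSE)
  structure(list(method = "anova", statistic = f, p_value = p,
                 df = c(df1 = k - 1, df2 = N - k), ms_between = msb,
                 ms_within = msw, group_means = means),
            class = "tr_test")
}

#' Tukey honestly-significant-difference test
#'
#' Pairwise studentized-range statistics after one-way ANOVA,
#' `q = |m_i - m_j| / sqrt(MS_within / 2 * (1/n_i + 1/n_j))` (the
#' Tukey-Kramer form for unbalanced groups), with family-wise adjusted
#' p-values from the studentized range distribution on (k, N - k).
#'
#' @param groups named list of numeric vectors; every group needs n >= 2.
#' @param alpha family-wise significance level in (0, 1).
#' @return list of class `tr_test`; `pairwise` is a data frame with one row
#'   per group pair: `q`, `diff`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- .check_groups(groups)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (any(lengths(groups) < 2L))
    stop("insufficient replication: every group needs n >= 2", call. = FALSE)
  a <- anova_oneway(groups)
  k <- length(groups)
  N <- sum(lengths(groups))
  msw <- a$ms_within
  if (msw == 0) stop("degenerate data: zero within-group variance",
                     call. = FALSE)
  pairs <- utils::combn(names(groups), 2)
  rows <- apply(pairs, 2, function(pr) {
    gi <- groups[[pr[1]]]; gj <- groups[[pr[2]]]
    d <- mean(gj) - mean(gi)
    se <- sqrt(msw / 2 * (1 / length(gi) + 1 / length(gj)))
    q <- abs(d) / se
    p <- ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
    data.frame(group_i = pr[1], group_j = pr[2], diff = d, q = q, p_adj = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  pairwise <- do.call(rbind, rows)
  rownames(pairwise) <- NULL
  structure(list(method = "tukey_hsd", statistic = max(pairwise$q),
                 p_value = min(pairwise$p_adj), df = c(k = k, df = N - k),
                 alpha = alpha, pairwise = pairwise),
            class = "tr_test")
}

#' @export
print.tr_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}
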