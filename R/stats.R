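#' Two-sided Student's t-test (pooled variance)
#'
#' Two-sample t-test with pooled variance and `df = n_a + n_b - 2`, the
#' classical Student form used throughout screen scoring here. No
#' multiplicity adjustment is applied at this level.
#'
#' When the pooled variance is exactly zero the usual statistic is
#' undefined; a documented convention is used instead so that
#' noise-free fixtures stay deterministic: if the group means are equal
#' the result is `t = 0, p = 1`, otherwise `t = +/-Inf, p = 0`, with a
#' warning either way.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with elements `t` (statistic, sign of `mean(a) -
#'   mean(b)`) and `p` (two-sided p-value).
#' @export
t_test_two_sided <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("t_test_two_sided requires at least 2 values per group (got ",
         length(a), " and ", length(b), ")")
  if (anyNA(a) || anyNA(b)) stop("missing values in t-test input")
  n1 <- length(a); n2 <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2L)
  if (sp2 == 0) {
    warning("zero pooled variance; applying degenerate convention")
    if (mean(a) == mean(b)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  fit <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value)
}

# Vectorized pooled two-sample t over matrix rows (same math as
# t_test_two_sided, including the degenerate convention, minus the
# warning -- callers log the affected rows instead).
row_t_test <- function(xa, xb) {
  n1 <- ncol(xa); n2 <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  sp2 <- (ssa + ssb) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2L)
  deg <- sp2 == 0
  if (any(deg)) {
    eq <- deg & (ma == mb)
    t[eq] <- 0; p[eq] <- 1
    ne <- deg & (ma != mb)
    t[ne] <- sign(ma[ne] - mb[ne]) * Inf; p[ne] <- 0
  }
  list(t = t, p = p, degenerate = deg)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR control. Thin validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`; adjusted values are
#' order-preserving, each at least its raw p-value, and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA`s propagate.
#' @return numeric vector of adjusted values (q-values), same length.
#' @export
benjamini_hochberg <- function(p) {
  p <- as.numeric(p)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Area under the ROC curve for a score against binary labels
#'
#' Rank-based (Mann-Whitney) AUROC used to evaluate how well a score
#' separates planted-positive elements from the rest in synthetic
#' screens. Ties are handled by midranks.
#'
#' @param score numeric vector; larger = more positive-like.
#' @param label logical (or 0/1) vector of the same length.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0L || n0 == 0L)
    stop("auroc needs both positive and negative labels")
  r <- rank(score)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Pearson correlation p-value via the exact t-distribution transform,
# vectorized over features (cor.test does the same arithmetic one
# feature at a time).
pearson_p <- function(r, n) {
  t <- r * sqrt(pmax(n - 2, 0)) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[n < 3] <- NA_real_
  pmin(p, 1)
}
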