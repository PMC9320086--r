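#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' U statistics are computed from midranks (ties share their average rank),
#' so `u1 + u2 = n1 * n2` always. The reported statistic is the conventional
#' `min(u1, u2)`; both are returned.
#'
#' The two-sided p-value is exact — the tail mass of the null permutation
#' distribution of U — whenever there are no ties and `n1 + n2 <= 25`;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. `exact` overrides the default rule (exact is refused
#' in the presence of ties).
#'
#' @param x,y Numeric samples, each non-empty.
#' @param exact Logical or NULL (auto rule above).
#' @return Object of class `mwu`: list with `u1`, `u2`, `u_reported`,
#'   `p_two_sided`, `method` (`"exact"` or `"normal_tie_corrected"`),
#'   `n1`, `n2`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("samples must not contain NA")
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- !ties && (n1 + n2) <= 25
  if (exact && ties) {
    warn("ties present; falling back to the tie-corrected normal approximation")
    exact <- FALSE
  }

  if (exact) {
    # tail mass of the exact null distribution of U
    p <- if (u1 > n1 * n2 / 2) {
      2 * stats::pwilcox(u1 - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u1, n1, n2)
    }
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- u1 - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_tie_corrected"
  }
  structure(
    list(
      u1 = u1, u2 = u2, u_reported = min(u1, u2),
      p_two_sided = min(1, p), method = method,
      n1 = n1, n2 = n2
    ),
    class = "mwu"
  )
}

#' @export
print.mwu <- function(x, ...) {
  cat(
    "Mann-Whitney U: u = ", format(x$u_reported),
    " (u1 = ", format(x$u1), ", u2 = ", format(x$u2), ")",
    ", n = ", x$n1, "/", x$n2,
    ", two-sided p = ", format.pval(x$p_two_sided, digits = 4),
    " [", x$method, "]\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy a Mann-Whitney result
#' @param x An `mwu` object.
#' @param ... Unused.
#' @return One-row tibble: u1, u2, u_reported, p_two_sided, method, n1, n2.
#' @method tidy mwu
#' @export
tidy.mwu <- function(x, ...) {
  tibble(
    u1 = x$u1, u2 = x$u2, u_reported = x$u_reported,
    p_two_sided = x$p_two_sided, method = x$method,
    n1 = x$n1, n2 = x$n2
  )
}

#' @rdname tidy.mwu
#' @method glance mwu
#' @export
glance.mwu <- function(x, ...) tidy.mwu(x)

#' Pearson correlation with two-sided p
#'
#' Pearson's r with the usual t transform on n - 2 degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, non-degenerate variance.
#' @return One-row tibble: r, p_raw, n, df.
#' @export
pearson_r <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) abort("samples must have equal length")
  if (length(x) < 3L) abort("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("degenerate variance")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(
    r = unname(ct$estimate),
    p_raw = ct$p.value,
    n = length(x),
    df = unname(ct$parameter)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: monotone-enforced, capped at 1,
#' input order preserved. Rejecting hypotheses with adjusted p <= q is the
#' classical BH rule at level q.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
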