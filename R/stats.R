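#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum test used for every two-group comparison in the pipeline
#' (expression, methylation, Ka/Ks). U is computed from midranks. When the
#' combined sample size is at most `exact_limit` and there are no ties, the
#' exact two-sided p-value is computed from the null permutation distribution
#' of U; otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used. When every value in both samples is
#' identical the p-value is 1.
#'
#' @param a,b numeric samples.
#' @param alternative only `"two_sided"` is implemented.
#' @param exact_limit combined-size threshold for the exact branch
#'   (default 12).
#' @return list of class `mwu_result`: `u_statistic` (U of sample `a`),
#'   `p_value`, `n_a`, `n_b`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(a, b, alternative = "two_sided",
                           exact_limit = 12L) {
  stopifnot(alternative == "two_sided")
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  n <- na + nb
  ties <- table(c(a, b))
  has_ties <- any(ties > 1L)
  if (n <= exact_limit && !has_ties) {
    method <- "exact"
    # exact two-sided p from the null distribution of U
    pl <- stats::pwilcox(u_a, na, nb)
    pu <- 1 - stats::pwilcox(u_a - 1, na, nb)
    p <- min(1, 2 * min(pl, pu))
  } else {
    method <- "normal_approx"
    mu <- na * nb / 2
    tie_term <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(u_a - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  structure(list(u_statistic = u_a, p_value = p, n_a = na, n_b = nb,
                 method = method),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (n = %d, %d), p = %.4g [%s]\n",
              x$u_statistic, x$n_a, x$n_b, x$p_value, x$method))
  invisible(x)
}

#' Significance stars for a p-value
#'
#' `p < 0.01` -> `"**"`, `p < 0.05` -> `"*"`, otherwise `"ns"` (strict
#' inequalities).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return character vector of `"ns"`, `"*"`, `"**"`.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))
}

# Helper building one row of the pipeline comparison table.
.comparison_row <- function(label, a, b, extra = list()) {
  res <- mann_whitney_u(a, b)
  data.frame(comparison = label, n_a = res$n_a, n_b = res$n_b,
             median_a = stats::median(a), median_b = stats::median(b),
             u = res$u_statistic, p = res$p_value,
             stars = significance_stars(res$p_value),
             stringsAsFactors = FALSE)
}
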