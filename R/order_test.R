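#' Chi-square upper-tail probability
#'
#' Thin, argument-checked survival function used by the order-effect test.
#'
#' @param x Nonnegative statistic value.
#' @param df Positive degrees of freedom.
#' @return `P(Chi2_df >= x)`.
#' @examples
#' chi2_upper_tail(110.19, 80) # 0.0143
#' @export
chi2_upper_tail <- function(x, df) {
  if (any(!is.finite(x)) || any(x < 0)) stop("'x' must be nonnegative")
  if (any(df <= 0)) stop("'df' must be positive")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test for question-order effects
#'
#' Compares the saturated multinomial model (a free probability for every
#' cell of every order's table) against the restricted model that forces a
#' single joint distribution on both question orders.  The restricted
#' maximum-likelihood estimate is the pooled cell proportion; the statistic
#' is `G2 = -2 [lnL(restricted) - lnL(saturated)]`, with cells of zero
#' observed count contributing nothing and no continuity correction.  For
#' two 9 x 9 tables the saturated model has `9*9*2 - 2 = 160` free
#' parameters and the restricted one `9*9 - 1 = 80`, so the reference
#' distribution is chi-square with 80 degrees of freedom -- valid only under
#' the (acknowledged) assumption that pooled trials are independent.
#'
#' @param t1,t2 Count-kind (or relative-frequency with sample size)
#'   [joint_table()]s for the two question orders.
#' @return An object of class `"order_test"` with elements `g2`, `df`,
#'   `p_value`, `n1`, `n2`.
#' @examples
#' obs <- psa_tables()
#' order_effect_test(obs$self_first, obs$other_first)
#' @export
order_effect_test <- function(t1, t2) {
  stopifnot(inherits(t1, "joint_table"), inherits(t2, "joint_table"))
  c1 <- as_counts(t1)
  c2 <- as_counts(t2)
  if (!identical(dim(c1), dim(c2))) stop("tables disagree in size")
  n1 <- sum(c1); n2 <- sum(c2)
  if (n1 <= 0 || n2 <= 0) stop("both tables need a positive total count")
  pooled <- (c1 + c2) / (n1 + n2)
  term <- function(cnt, n) {
    pos <- cnt > 0
    2 * sum(cnt[pos] * log((cnt[pos] / n) / pooled[pos]))
  }
  g2 <- term(c1, n1) + term(c2, n2)
  ncell <- length(c1)
  df <- (2L * ncell - 2L) - (ncell - 1L)
  res <- list(g2 = g2, df = df, p_value = chi2_upper_tail(g2, df),
              n1 = n1, n2 = n2,
              orders = c(table_order(t1), table_order(t2)))
  class(res) <- "order_test"
  res
}

#' @export
print.order_test <- function(x, ...) {
  cat("Question-order effect test (saturated vs. single joint distribution)\n")
  cat(sprintf("  G2 = %.2f, df = %d, p = %.4f  (n = %g and %g trials)\n",
              x$g2, x$df, x$p_value, x$n1, x$n2))
  cat("  Reference: chi-square, assuming pooled trials are independent.\n")
  invisible(x)
}
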