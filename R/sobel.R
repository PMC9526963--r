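#' Sobel (first-order delta) test of the indirect effect
#'
#' Tests H0: a*b3 = 0 with the first-order delta-method standard error
#' \deqn{SE_{ab} = \sqrt{\hat a^2 SE_b^2 + \hat b^2 SE_a^2},\qquad
#'       z = \hat a \hat b / SE_{ab}.}
#' Both the 2-sided decision (|z| at the \eqn{1-\alpha/2} normal quantile)
#' and the 1-sided decision in a hypothesized direction (z at the
#' \eqn{1-\alpha} quantile) are returned; a z exactly at the critical value
#' counts as a rejection. The statistic is invariant to rescaling of M and
#' Y. The test is asymptotic (no df correction) and slightly conservative
#' relative to resampling-based indirect-effect tests.
#'
#' @param a Estimated X-to-M path, or a `mediation_fit` object (in which
#'   case the `a` and `b3` paths and their standard errors are extracted and
#'   the remaining estimate arguments are ignored).
#' @param se_a,b,se_b Estimates and standard errors of the two paths
#'   (standard errors must be positive).
#' @param alpha Test level, in (0, 1). Default 0.05.
#' @param direction +1 or -1, the hypothesized sign of the indirect effect
#'   for the 1-sided test. Default +1.
#' @return A one-row tibble: `ab_hat`, `se_ab`, `z`, `p_two`, `p_one`,
#'   `reject_two`, `reject_one`, `alpha`, `direction`.
#' @examples
#' sobel_test(0.264, 0.08, 0.59, 0.15)  # z = 2.53, 2-sided rejection
#' @export
sobel_test <- function(a, se_a = NULL, b = NULL, se_b = NULL,
                       alpha = 0.05, direction = 1) {
  if (inherits(a, "mediation_fit")) {
    p <- a$paths
    se_a <- p$std.error[p$term == "a"]
    b <- p$estimate[p$term == "b3"]
    se_b <- p$std.error[p$term == "b3"]
    a <- p$estimate[p$term == "a"]
  }
  if (any(se_a <= 0) || any(se_b <= 0)) abort("standard errors must be positive")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)")
  if (!direction %in% c(-1, 1)) abort("direction must be +1 or -1")
  ab <- a * b
  se_ab <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  z <- ab / se_ab
  p_two <- 2 * pnorm(-abs(z))
  p_one <- pnorm(direction * z, lower.tail = FALSE)
  tibble::tibble(
    ab_hat = ab, se_ab = se_ab, z = z,
    p_two = p_two, p_one = p_one,
    reject_two = abs(z) >= qnorm(1 - alpha / 2),
    reject_one = one_sided_from_two(z, direction, alpha),
    alpha = alpha, direction = direction
  )
}

#' One-sided decision recovered from a stored 2-sided z statistic
#'
#' A 1-sided Sobel decision needs no refitting: it is the algebraic
#' transformation `direction * z >= qnorm(1 - alpha)` of the z statistic
#' already computed for the 2-sided test. An extreme z in the wrong
#' direction rejects 2-sided but never 1-sided.
#'
#' @param z Sobel z statistic(s).
#' @inheritParams sobel_test
#' @return Logical vector of 1-sided rejections.
#' @examples
#' one_sided_from_two(c(1.70, -2.5), direction = 1)  # TRUE, FALSE
#' @export
one_sided_from_two <- function(z, direction = 1, alpha = 0.05) {
  if (!direction %in% c(-1, 1)) abort("direction must be +1 or -1")
  direction * z >= qnorm(1 - alpha)
}
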