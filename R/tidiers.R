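#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted mediation model
#'
#' @param x A `mediation_fit` from [fit_mvm()] or [fit_msem()].
#' @param ... Unused.
#' @return One row per path (`a`, `b3`, `b2`, `c_prime`) with `estimate`,
#'   `std.error`, `statistic` (Wald z), and `p.value`.
#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, ...) {
  x$paths |>
    dplyr::mutate(statistic = .data$estimate / .data$std.error,
                  p.value = 2 * pnorm(-abs(.data$statistic)))
}

#' Glance at a fitted mediation model
#'
#' @inheritParams tidy.mediation_fit
#' @return A one-row tibble: `estimator`, `logLik`, `converged`,
#'   `truncated` (any variance component truncated at zero), `n3`, `n2`,
#'   `n1`.
#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(
    estimator = x$estimator,
    logLik = x$loglik,
    converged = x$converged,
    truncated = x$truncated,
    n3 = x$dims[["n3"]], n2 = x$dims[["n2"]], n1 = x$dims[["n1"]]
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("<mediation_fit> %s estimator (n3=%d, n2=%d, n1=%d)%s\n",
              x$estimator, x$dims[["n3"]], x$dims[["n2"]], x$dims[["n1"]],
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(tidy(x))
  cat("Variance components:\n")
  print(x$varcomp)
  if (is.finite(x$loglik)) cat(sprintf("logLik: %.3f\n", x$loglik))
  invisible(x)
}
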