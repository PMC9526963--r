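#' Map standardized designs to raw coefficients and variance components
#'
#' Translates each design's standardized paths and ICCs into the raw
#' regression coefficients and variance components of the generating
#' three-level Gaussian model, with the total variances of M and Y normalized
#' to 1 and the treatment coded X in \{-1, +1\} with exact 50/50 allocation
#' (so var(X) = 1).
#'
#' The level-3 paths `a3`, `b3`, `c3p` are standardized *between-level*
#' coefficients (the latent level-3 components of M and Y are scaled to unit
#' variance), and `b2` is standardized at level 2. With total-variance
#' standardization instead, a large `a3` would demand more level-3 variance
#' than a small `icc_m3` provides and much of the reference grid would be
#' infeasible; the between-level convention keeps every reference cell
#' feasible and matches multilevel-SEM practice. The mapping is
#' \deqn{a = a_3\sqrt{ICC_{m3}},\quad
#'       \sigma^2_{u} = ICC_{m3}(1-a_3^2),\quad
#'       \sigma^2_{w} = 1-ICC_{m3},}
#' \deqn{b_3^{raw} = b_3\sqrt{ICC_{y3}/ICC_{m3}},\quad
#'       c^{raw} = c'_3\sqrt{ICC_{y3}},\quad
#'       \sigma^2_{v} = ICC_{y3}(1-R^2_B),}
#' \deqn{b_2^{raw} = b_2\sqrt{ICC_{y2}/(1-ICC_{m3})},\quad
#'       \sigma^2_{s} = ICC_{y2}(1-b_2^2),\quad
#'       \sigma^2_{e} = 1-ICC_{y2}-ICC_{y3},}
#' where \eqn{R^2_B = b_3^2 + c_3'^2 + 2 a_3 b_3 c'_3} is the explained
#' fraction of the level-3 outcome variance.
#'
#' @inheritParams validate_designs
#' @return The input tibble with columns `a_raw`, `b3_raw`, `b2_raw`,
#'   `c_raw`, `var_mB_resid`, `var_mW`, `var_yB_resid`, `var_y2_resid`,
#'   `var_y1` appended.
#' @examples
#' derive_components(design_grid(a3 = 0.59, b3 = 0.59, c3p = 0.39,
#'                               icc_m3 = 0.2, icc_y2 = 0.1, icc_y3 = 0.2,
#'                               n3 = 40, n2 = 5, n1 = 6))
#' @export
derive_components <- function(designs) {
  validate_designs(designs)
  d <- designs
  r2b <- d$b3^2 + d$c3p^2 + 2 * d$a3 * d$b3 * d$c3p
  out <- dplyr::mutate(
    d,
    a_raw = .data$a3 * sqrt(.data$icc_m3),
    b3_raw = .data$b3 * sqrt(.data$icc_y3 / .data$icc_m3),
    b2_raw = .data$b2 * sqrt(.data$icc_y2 / (1 - .data$icc_m3)),
    c_raw = .data$c3p * sqrt(.data$icc_y3),
    var_mB_resid = .data$icc_m3 * (1 - .data$a3^2),
    var_mW = 1 - .data$icc_m3,
    var_yB_resid = .data$icc_y3 * (1 - r2b),
    var_y2_resid = .data$icc_y2 * (1 - .data$b2^2),
    var_y1 = 1 - .data$icc_y2 - .data$icc_y3
  )
  bad <- c(
    var_mB_resid = any(out$var_mB_resid < 0),
    var_yB_resid = any(out$var_yB_resid < 0),
    var_y2_resid = any(out$var_y2_resid < 0),
    var_y1 = any(out$var_y1 < 0)
  )
  if (any(bad)) {
    why <- switch(names(bad)[bad][1],
      var_mB_resid = "a3^2 >= 1 leaves negative level-3 mediator residual variance",
      var_yB_resid = "b3^2 + c3p^2 + 2*a3*b3*c3p >= 1 (level-3 R^2 of Y >= 1)",
      var_y2_resid = "b2^2 >= 1 leaves negative level-2 outcome residual variance",
      var_y1 = "icc_y2 + icc_y3 >= 1 leaves negative level-1 variance"
    )
    abort(paste0("infeasible standardized parameterization: ", why))
  }
  out
}
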