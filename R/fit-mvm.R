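#' Centered-within-context decomposition of the mediator
#'
#' Splits M into its observed cluster mean (`m_mean3`, the level-3 manifest
#' component, "means reintroduced") and the within-cluster deviation
#' (`m_dev`), which sums to zero inside every cluster. The outcome model
#' enters `m_mean3` at level 3 and `m_dev` at level 2.
#'
#' @param data A long-format dataset (see [simulate_mediation()]).
#' @return The input with columns `m_mean3` and `m_dev` appended.
#' @examples
#' d <- design_grid(n3 = 10, n2 = 5, n1 = 3)
#' decompose_cwc(simulate_mediation(d, seed = 1))
#' @export
decompose_cwc <- function(data) {
  units <- dplyr::distinct(data, .data$cluster_id, .data$unit_id, .data$m)
  means <- units |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(m_mean3 = mean(.data$m), .groups = "drop")
  data |>
    dplyr::select(-dplyr::any_of(c("m_mean3", "m_dev"))) |>
    dplyr::left_join(means, by = "cluster_id") |>
    dplyr::mutate(m_dev = .data$m - .data$m_mean3)
}

# Closed-form ML for the two MVM models on balanced data, vectorized across
# replications. Exploits the orthogonal decomposition of a balanced nested
# design into (i) level-1 deviations from unit means, (ii) within-cluster
# contrasts of unit means, (iii) cluster means: the likelihood factors into
# independent Gaussian blocks with one variance parameter each, and GLS fixed
# effects reduce to blockwise OLS. Interior ML estimates are therefore
# available in closed form; boundary cases (a negative implied variance
# component) are handled by pooling the adjacent blocks, which is the
# constrained ML solution, and flagged.
#
# x: length-n3 cluster-level covariate; m_units, ybar_units: (n3*n2) x R
# matrices of unit-level M and unit-mean Y, units nested in cluster by row;
# ss1: length-R level-1 residual sums of squares.
mvm_core <- function(x, m_units, ybar_units, ss1, n3, n2, n1) {
  R <- ncol(m_units)
  cl <- rep(seq_len(n3), each = n2)
  xc <- x - mean(x)
  sxx <- sum(xc^2)

  ## ---- M-model: 2-level random intercept, cluster-level predictor ----
  mbar <- rowsum(m_units, cl, reorder = FALSE) / n2          # n3 x R
  ssw_m <- colSums(m_units^2) - n2 * colSums(mbar^2)
  mu_m <- colMeans(mbar)
  a_hat <- colSums(xc * mbar) / sxx
  ssb_m <- colSums(mbar^2) - n3 * mu_m^2 - a_hat^2 * sxx
  ssb_m <- pmax(ssb_m, 0)
  sigw_m <- ssw_m / (n3 * (n2 - 1))
  lam_m <- n2 * ssb_m / n3                                    # var of sqrt(n2)*mbar
  trunc_m3 <- lam_m < sigw_m
  pooled_m <- (ssw_m + n2 * ssb_m) / (n3 * n2)
  sigw_m <- ifelse(trunc_m3, pooled_m, sigw_m)
  lam_m <- ifelse(trunc_m3, pooled_m, lam_m)
  tau_m <- (lam_m - sigw_m) / n2
  se_a <- sqrt(lam_m / (n2 * sxx))
  ll_m <- -0.5 * (n3 * n2 * log(2 * pi) +
                    n3 * (n2 - 1) * log(pmax(sigw_m, .Machine$double.xmin)) +
                    ssw_m / sigw_m +
                    n3 * log(pmax(lam_m, .Machine$double.xmin)) +
                    n2 * ssb_m / lam_m)

  ## ---- Y-model: 3-level random intercept, CWC(M) predictors ----
  ybarc <- rowsum(ybar_units, cl, reorder = FALSE) / n2       # n3 x R
  m_dev <- m_units - mbar[cl, , drop = FALSE]
  y_dev <- ybar_units - ybarc[cl, , drop = FALSE]
  sxx_w <- colSums(m_dev^2)
  # centering residue on within-constant M must count as zero variance
  sxx_w[sxx_w <= 1e-12 * colSums(m_units^2)] <- 0
  sxy_w <- colSums(m_dev * y_dev)
  # zero within-cluster M variance leaves b2 undefined but the rest estimable
  b2_hat <- ifelse(sxx_w > 0, sxy_w / ifelse(sxx_w > 0, sxx_w, 1), NA_real_)
  ssr2 <- pmax(colSums(y_dev^2) -
                 ifelse(is.na(b2_hat), 0, b2_hat^2 * sxx_w), 0)
  omega <- ssr2 / (n3 * (n2 - 1))                             # var of unit-mean dev

  sm <- colSums(mbar); smm <- colSums(mbar^2)
  smx <- colSums(xc * mbar)
  sy <- colSums(ybarc); syy <- colSums(ybarc^2)
  sym <- colSums(ybarc * mbar); syx <- colSums(xc * ybarc)
  mbar_m <- sm / n3; ybar_m <- sy / n3
  smm_c <- pmax(smm - n3 * mbar_m^2, 0)
  sym_c <- sym - n3 * mbar_m * ybar_m
  syy_c <- pmax(syy - n3 * ybar_m^2, 0)
  det2 <- smm_c * sxx - smx^2
  singular <- !(det2 > 1e-12 * (1 + smm_c * sxx))
  det2s <- ifelse(singular, NA_real_, det2)
  b3_hat <- (sym_c * sxx - smx * syx) / det2s
  c_hat <- (smm_c * syx - smx * sym_c) / det2s
  ssr3 <- pmax(syy_c - b3_hat * sym_c - c_hat * syx, 0)
  kappa <- ssr3 / n3                                          # var of cluster-mean resid

  df1 <- n3 * n2 * (n1 - 1)
  sig1 <- if (n1 > 1) ss1 / df1 else rep(0, R)
  sig2_y <- omega - sig1 / n1
  trunc_y2 <- n1 > 1 & sig2_y < 0
  sig1 <- ifelse(trunc_y2, (ss1 + n1 * ssr2) / (df1 + n3 * (n2 - 1)), sig1)
  omega <- ifelse(trunc_y2, sig1 / n1, omega)
  sig2_y <- pmax(ifelse(trunc_y2, 0, sig2_y), 0)
  sig3_y <- kappa - omega / n2
  trunc_y3 <- !is.na(sig3_y) & sig3_y < 0
  omega_p <- (ssr2 + n2 * ssr3) / (n3 * (n2 - 1) + n3)
  omega <- ifelse(trunc_y3, omega_p, omega)
  kappa <- ifelse(trunc_y3, omega_p / n2, kappa)
  sig3_y <- pmax(ifelse(trunc_y3, 0, sig3_y), 0)

  se_b2 <- ifelse(sxx_w > 0, sqrt(omega / ifelse(sxx_w > 0, sxx_w, 1)), NA_real_)
  se_b3 <- sqrt(kappa * sxx / det2s)
  se_c <- sqrt(kappa * smm_c / det2s)
  ll_y <- -0.5 * (n3 * n2 * n1 * log(2 * pi) +
                    (if (n1 > 1) df1 * log(pmax(sig1, .Machine$double.xmin)) +
                       ss1 / pmax(sig1, .Machine$double.xmin) else 0) +
                    n3 * (n2 - 1) * log(pmax(n1 * omega, .Machine$double.xmin)) +
                    ssr2 / omega +
                    n3 * log(pmax(n1 * n2 * kappa, .Machine$double.xmin)) +
                    ssr3 / kappa)

  list(
    a_hat = a_hat, se_a = se_a,
    b3_hat = b3_hat, se_b3 = se_b3,
    b2_hat = b2_hat, se_b2 = se_b2,
    c_hat = c_hat, se_c = se_c,
    icpt_m = mu_m - a_hat * mean(x),
    icpt_y = ybar_m - b3_hat * mbar_m - c_hat * mean(x),
    tau_m3 = tau_m, sig_m2 = sigw_m,
    tau_y3 = sig3_y, tau_y2 = sig2_y, sig_y1 = sig1,
    loglik_m = ll_m, loglik_y = ll_y,
    converged = !singular & is.finite(a_hat),
    truncated = trunc_m3 | trunc_y2 | trunc_y3
  )
}

# Collapse a long dataset to the balanced unit-level summary the fitters use:
# per level-2 unit its M, its mean Y, and the pooled level-1 residual SS.
unit_summary <- function(data) {
  units <- data |>
    dplyr::group_by(.data$cluster_id, .data$unit_id) |>
    dplyr::summarise(
      x = .data$x[1], m = .data$m[1],
      ybar = mean(.data$y),
      ss1 = sum((.data$y - mean(.data$y))^2),
      n1 = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cluster_id, .data$unit_id)
  n3 <- dplyr::n_distinct(units$cluster_id)
  n2 <- nrow(units) / n3
  if (n2 %% 1 != 0 || dplyr::n_distinct(table(units$cluster_id)) != 1) {
    abort("dataset is unbalanced: every cluster must have the same number of level-2 units")
  }
  if (dplyr::n_distinct(units$n1) != 1) {
    abort("dataset is unbalanced: every level-2 unit must have the same number of observations")
  }
  list(units = units, n3 = n3, n2 = as.integer(n2), n1 = units$n1[1],
       x = units$x[seq(1, nrow(units), by = n2)])
}

new_mediation_fit <- function(core, i, estimator, n3, n2, n1, extra = list()) {
  pick <- function(v) if (length(v) >= i) v[[i]] else v[[1]]
  structure(c(list(
    estimator = estimator,
    paths = tibble::tibble(
      term = c("a", "b3", "b2", "c_prime"),
      estimate = c(pick(core$a_hat), pick(core$b3_hat),
                   pick(core$b2_hat), pick(core$c_hat)),
      std.error = c(pick(core$se_a), pick(core$se_b3),
                    pick(core$se_b2), pick(core$se_c))
    ),
    varcomp = tibble::tibble(
      variable = c("m", "m", "y", "y", "y"),
      level = c(3L, 2L, 3L, 2L, 1L),
      estimate = c(pick(core$tau_m3), pick(core$sig_m2),
                   pick(core$tau_y3), pick(core$tau_y2), pick(core$sig_y1))
    ),
    loglik = pick(core$loglik_m) + pick(core$loglik_y),
    loglik_m = pick(core$loglik_m),
    loglik_y = pick(core$loglik_y),
    converged = pick(core$converged),
    truncated = pick(core$truncated),
    dims = c(n3 = n3, n2 = n2, n1 = n1)
  ), extra), class = "mediation_fit")
}

#' Fit the manifest-variable multilevel (MVM) mediation models
#'
#' Maximum-likelihood fit of the two conventional multilevel regressions on
#' observed variables: a 2-level random-intercept model for the mediator
#' (`m ~ x` with a cluster intercept) and a 3-level random-intercept model
#' for the outcome using the centered-within-context decomposition
#' (`y ~ m_mean3 + m_dev + x` with cluster and unit intercepts). Standard
#' errors are model-based (inverse information at the ML solution); variance
#' components are ML (no REML correction) and truncated at zero when the
#' unconstrained solution is negative, with the truncation flagged.
#'
#' On balanced data the ML solution is available in closed form through the
#' orthogonal between/within decomposition of the design; the same code path
#' drives the Monte Carlo power engine.
#'
#' @param data A long-format balanced dataset (see [simulate_mediation()]).
#' @return An object of class `mediation_fit`: path estimates with standard
#'   errors (`a`, `b3`, `b2`, `c_prime`), variance components per variable
#'   and level, log-likelihood, and a convergence flag. Use [tidy()] /
#'   [glance()] to extract tibbles, and [sobel_test()] to test the indirect
#'   effect. A dataset whose cluster means of M are constant (rank-deficient
#'   outcome model) yields `converged = FALSE` rather than an error.
#' @examples
#' d <- design_grid(a3 = 0.59, b3 = 0.59, c3p = 0.39, icc_m3 = 0.2,
#'                  icc_y2 = 0.1, icc_y3 = 0.2, n3 = 20, n2 = 5, n1 = 3)
#' fit <- fit_mvm(simulate_mediation(d, seed = 1))
#' tidy(fit)
#' @export
fit_mvm <- function(data) {
  us <- unit_summary(data)
  if (us$n2 < 2) abort("fit_mvm() needs n2 >= 2 so within-cluster deviations exist")
  core <- mvm_core(us$x,
                   matrix(us$units$m, ncol = 1),
                   matrix(us$units$ybar, ncol = 1),
                   sum(us$units$ss1),
                   us$n3, us$n2, us$n1)
  new_mediation_fit(core, 1L, "MVM", us$n3, us$n2, us$n1)
}
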