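# Per-cluster sufficient statistics, vectorized across replications.
# m_units / ybar_units are (n3*n2) x R; ss1_units holds per-unit level-1
# residual SS ((n3*n2) x R). Everything downstream (point estimates and the
# cluster bootstrap) consumes only these n3 x R summaries.
cluster_stats <- function(x, m_units, ybar_units, ss1_units, n3, n2) {
  cl <- rep(seq_len(n3), each = n2)
  sm <- rowsum(m_units, cl, reorder = FALSE)
  sy <- rowsum(ybar_units, cl, reorder = FALSE)
  mbar <- sm / n2
  ybar <- sy / n2
  list(
    x = x,
    mbar = mbar,
    ybar = ybar,
    swm = rowsum(m_units^2, cl, reorder = FALSE) - n2 * mbar^2,
    swy = rowsum(ybar_units^2, cl, reorder = FALSE) - n2 * ybar^2,
    swmy = rowsum(m_units * ybar_units, cl, reorder = FALSE) - n2 * mbar * ybar,
    ss1 = rowsum(ss1_units, cl, reorder = FALSE)
  )
}

# Method-of-moments latent decomposition from cluster statistics.
# Level-2 (co)variances come from pooled within-cluster mean squares, with
# the level-1 contribution var_y1/n1 removed from the Y level-2 variance.
# Latent level-3 (co)variances are between-cluster-mean (co)variances minus
# (within mean square)/n2; covariances with the observed X need no
# correction. Returns R-vectors.
msem_point <- function(st, n3, n2, n1) {
  dfw <- n3 * (n2 - 1)
  msw_m <- colSums(st$swm) / dfw
  msw_y <- colSums(st$swy) / dfw
  msw_my <- colSums(st$swmy) / dfw
  sig1 <- if (n1 > 1) colSums(st$ss1) / (n3 * n2 * (n1 - 1)) else rep(0, ncol(st$mbar))

  xc <- st$x - mean(st$x)
  cxx <- sum(xc^2) / (n3 - 1)
  mm <- colMeans(st$mbar); ym <- colMeans(st$ybar)
  cxm <- colSums(xc * st$mbar) / (n3 - 1)
  cxy <- colSums(xc * st$ybar) / (n3 - 1)
  cmm <- (colSums(st$mbar^2) - n3 * mm^2) / (n3 - 1)
  cyy <- (colSums(st$ybar^2) - n3 * ym^2) / (n3 - 1)
  cmy <- (colSums(st$mbar * st$ybar) - n3 * mm * ym) / (n3 - 1)

  v_mb <- cmm - msw_m / n2
  v_yb <- cyy - msw_y / n2
  c_mby <- cmy - msw_my / n2
  var_y2 <- msw_y - sig1 / n1

  a_hat <- cxm / cxx
  det <- v_mb * cxx - cxm^2
  ok <- v_mb > 0 & det > 1e-12 * (1 + abs(v_mb) * cxx)
  dets <- ifelse(ok, det, NA_real_)
  b3_hat <- (c_mby * cxx - cxm * cxy) / dets
  c_hat <- (v_mb * cxy - cxm * c_mby) / dets
  b2_hat <- msw_my / msw_m

  list(a_hat = a_hat, b3_hat = b3_hat, b2_hat = b2_hat, c_hat = c_hat,
       v_mb = v_mb, var_mw = msw_m, v_yb = v_yb, var_y2 = var_y2,
       sig1 = sig1, converged = ok & is.finite(a_hat))
}

#' Latent between/within covariance decomposition
#'
#' Moment estimates of the latent level-3 covariance matrix of
#' (X, M_B, Y_B) — the sampling error that observed cluster means carry from
#' lower levels is subtracted — together with the level-2 covariance matrix
#' of the within-cluster components (M_w, Y_w2) and the level-1 variance of
#' Y. These are the building blocks of the MSEM-style estimator: regressions
#' among the latent components are free of the attenuation that affects
#' manifest cluster means.
#'
#' @param data A long-format balanced dataset (see [simulate_mediation()]).
#' @return A list with `between` (3x3 matrix, rows/cols `x`, `m_b`, `y_b`),
#'   `within` (2x2 matrix, `m_w`, `y_w2`), and `sigma1` (level-1 Y variance).
#' @export
latent_between_cov <- function(data) {
  us <- unit_summary(data)
  if (us$n2 < 2) abort("latent_between_cov() needs n2 >= 2")
  st <- cluster_stats(us$x, matrix(us$units$m, ncol = 1),
                      matrix(us$units$ybar, ncol = 1),
                      matrix(us$units$ss1, ncol = 1), us$n3, us$n2)
  pt <- msem_point(st, us$n3, us$n2, us$n1)
  xc <- st$x - mean(st$x)
  n3 <- us$n3
  cxx <- sum(xc^2) / (n3 - 1)
  cxm <- sum(xc * st$mbar) / (n3 - 1)
  cxy <- sum(xc * st$ybar) / (n3 - 1)
  dfw <- n3 * (us$n2 - 1)
  msw_my <- sum(st$swmy) / dfw
  cmy_latent <- (sum(st$mbar * st$ybar) - n3 * mean(st$mbar) * mean(st$ybar)) /
    (n3 - 1) - msw_my / us$n2
  between <- matrix(c(cxx, cxm, cxy,
                      cxm, pt$v_mb, cmy_latent,
                      cxy, cmy_latent, pt$v_yb), 3, 3,
                    dimnames = list(c("x", "m_b", "y_b"), c("x", "m_b", "y_b")))
  within <- matrix(c(pt$var_mw, msw_my, msw_my, pt$var_y2), 2, 2,
                   dimnames = list(c("m_w", "y_w2"), c("m_w", "y_w2")))
  list(between = between, within = within, sigma1 = pt$sig1)
}

# Stratified cluster bootstrap of the latent-decomposition estimator for one
# replication. st1: per-cluster stats as length-n3 vectors; returns SEs of
# the four paths computed over the draws where the moment estimator is
# well-defined (positive latent M variance).
msem_boot <- function(st1, n3, n2, n1, reps) {
  arms <- split(seq_len(n3), st1$x)
  idx <- do.call(cbind, lapply(arms, function(a) {
    matrix(a[sample.int(length(a), reps * length(a), replace = TRUE)], nrow = reps)
  }))
  take <- function(v) matrix(v[idx], nrow = reps)
  bst <- list(
    x = st1$x[idx[1, ]],  # arm composition fixed under stratification
    mbar = t(take(st1$mbar)),
    ybar = t(take(st1$ybar)),
    swm = t(take(st1$swm)),
    swy = t(take(st1$swy)),
    swmy = t(take(st1$swmy)),
    ss1 = t(take(st1$ss1))
  )
  pt <- msem_point(bst, n3, n2, n1)
  ok <- pt$converged & is.finite(pt$b3_hat)
  n_ok <- sum(ok)
  se <- function(v) if (n_ok >= 2) sd(v[ok]) else NA_real_
  list(se_a = se(pt$a_hat), se_b3 = se(pt$b3_hat),
       se_b2 = se(pt$b2_hat), se_c = se(pt$c_hat), n_ok = n_ok)
}

#' Fit the latent-decomposition (MSEM-style) mediation model
#'
#' Estimates the level-3 paths on latent, measurement-error-free cluster
#' components via the method-of-moments decomposition of
#' [latent_between_cov()]: `a` is the regression of the latent M component
#' on X, `b3` and `c_prime` are partial regression coefficients of latent
#' Y_B on (latent M_B, X), and `b2` comes from the level-2 covariances.
#' Unlike the manifest cluster-mean regression, `b3` is not attenuated by
#' within-cluster sampling error. Standard errors are obtained by a
#' nonparametric cluster bootstrap (clusters resampled with replacement,
#' stratified by treatment arm), which is why MSEM-style inference pays for
#' its unbiasedness with larger standard errors and lower power.
#'
#' The moment estimator of the latent M variance can go negative in small
#' samples; such fits are flagged `converged = FALSE` (and excluded by the
#' power engine), mirroring the convergence failures of likelihood-based
#' multilevel SEM.
#'
#' @inheritParams fit_mvm
#' @param bootstrap_reps Number of bootstrap resamples (at least 50;
#'   default 200).
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `mediation_fit` (see [fit_mvm()]); the
#'   variance components are the latent level variances (not residuals) and
#'   the log-likelihood is `NA` (moment estimator).
#' @examples
#' d <- design_grid(a3 = 0.59, b3 = 0.59, c3p = 0.39, icc_m3 = 0.2,
#'                  icc_y2 = 0.1, icc_y3 = 0.2, n3 = 20, n2 = 5, n1 = 3)
#' fit <- fit_msem(simulate_mediation(d, seed = 1), bootstrap_reps = 100, seed = 2)
#' tidy(fit)
#' @export
fit_msem <- function(data, bootstrap_reps = 200, seed = 1) {
  if (bootstrap_reps < 50) abort("bootstrap_reps must be >= 50")
  us <- unit_summary(data)
  if (us$n2 < 2) abort("fit_msem() needs n2 >= 2")
  arms <- table(us$x)
  if (length(arms) != 2 || any(arms < 2)) {
    abort("fit_msem() needs two treatment arms with at least 2 clusters each")
  }
  st <- cluster_stats(us$x, matrix(us$units$m, ncol = 1),
                      matrix(us$units$ybar, ncol = 1),
                      matrix(us$units$ss1, ncol = 1), us$n3, us$n2)
  pt <- msem_point(st, us$n3, us$n2, us$n1)
  st1 <- lapply(st, function(v) if (is.matrix(v)) v[, 1] else v)
  set.seed(seed)
  bse <- msem_boot(st1, us$n3, us$n2, us$n1, bootstrap_reps)
  converged <- isTRUE(pt$converged[1]) && bse$n_ok >= bootstrap_reps / 2
  core <- list(
    a_hat = pt$a_hat, se_a = bse$se_a,
    b3_hat = pt$b3_hat, se_b3 = bse$se_b3,
    b2_hat = pt$b2_hat, se_b2 = bse$se_b2,
    c_hat = pt$c_hat, se_c = bse$se_c,
    icpt_m = mean(st1$mbar) - pt$a_hat * mean(us$x),
    icpt_y = NA_real_,
    tau_m3 = pt$v_mb, sig_m2 = pt$var_mw,
    tau_y3 = pt$v_yb, tau_y2 = pt$var_y2, sig_y1 = pt$sig1,
    loglik_m = NA_real_, loglik_y = NA_real_,
    converged = converged, truncated = !pt$converged[1]
  )
  new_mediation_fit(core, 1L, "MSEM", us$n3, us$n2, us$n1,
                    extra = list(bootstrap_reps = bootstrap_reps,
                                 bootstrap_ok = bse$n_ok))
}
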