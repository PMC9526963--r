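test_that("centering within context reproduces hand arithmetic and sums to zero", {
  dat <- tibble::tibble(
    cluster_id = rep(1:2, each = 3), unit_id = rep(1:3, 2),
    obs_id = 1L, x = rep(c(-1, 1), each = 3),
    m = c(1, 2, 3, 5, 5, 5), y = rnorm(6)
  )
  cwc <- decompose_cwc(dat)
  expect_equal(cwc$m_mean3, rep(c(2, 5), each = 3))
  expect_equal(cwc$m_dev, c(-1, 0, 1, 0, 0, 0))
  # identity on simulated data
  sim <- decompose_cwc(simulate_mediation(large_effect_design(), seed = 3))
  sums <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(sim, cluster_id, unit_id, m_dev), cluster_id),
    s = sum(m_dev))$s
  expect_true(all(abs(sums) < 1e-10))
})

test_that("closed-form ML matches lme4 on estimates, SEs, and log-likelihood", {
  skip_if_not_installed("lme4")
  for (seed in c(42, 7)) {
    d <- large_effect_design(n3 = 20, n2 = 5, n1 = 3)
    dat <- simulate_mediation(d, seed = seed)
    fit <- fit_mvm(dat)
    td <- tidy(fit)

    cwc <- decompose_cwc(dat)
    units <- dplyr::distinct(cwc, cluster_id, unit_id, x, m)
    mm <- lme4::lmer(m ~ x + (1 | cluster_id), data = units, REML = FALSE)
    ym <- lme4::lmer(
      y ~ m_mean3 + m_dev + x + (1 | cluster_id) + (1 | cluster_id:unit_id),
      data = cwc, REML = FALSE)

    expect_equal(td$estimate[td$term == "a"], unname(lme4::fixef(mm)["x"]),
                 tolerance = 1e-6)
    expect_equal(td$std.error[td$term == "a"],
                 unname(sqrt(diag(as.matrix(vcov(mm)))["x"])), tolerance = 1e-4)
    fe <- lme4::fixef(ym)
    se <- sqrt(diag(as.matrix(vcov(ym))))
    expect_equal(td$estimate[td$term == "b3"], unname(fe["m_mean3"]), tolerance = 1e-6)
    expect_equal(td$estimate[td$term == "b2"], unname(fe["m_dev"]), tolerance = 1e-6)
    expect_equal(td$estimate[td$term == "c_prime"], unname(fe["x"]), tolerance = 1e-6)
    expect_equal(td$std.error[td$term == "b3"], unname(se["m_mean3"]), tolerance = 1e-4)
    expect_equal(td$std.error[td$term == "b2"], unname(se["m_dev"]), tolerance = 1e-4)
    expect_equal(td$std.error[td$term == "c_prime"], unname(se["x"]), tolerance = 1e-4)
    expect_equal(fit$loglik_m, as.numeric(stats::logLik(mm)), tolerance = 1e-6)
    expect_equal(fit$loglik_y, as.numeric(stats::logLik(ym)), tolerance = 1e-6)
  }
})

test_that("M-model fixed effects equal OLS on cluster means (balanced shortcut)", {
  dat <- simulate_mediation(large_effect_design(n3 = 16, n2 = 10, n1 = 3), seed = 9)
  fit <- fit_mvm(dat)
  cm <- dat |>
    dplyr::distinct(cluster_id, unit_id, x, m) |>
    dplyr::group_by(cluster_id, x) |>
    dplyr::summarise(mbar = mean(m), .groups = "drop")
  ols <- stats::lm(mbar ~ x, data = cm)
  expect_equal(tidy(fit)$estimate[1], unname(coef(ols)["x"]), tolerance = 1e-8)
})

test_that("large-sample estimates approach the raw paths and the attenuation limit", {
  d <- large_effect_design(n3 = 2000, n2 = 20, n1 = 12)
  p <- derive_components(d)
  fit <- fit_mvm(simulate_mediation(d, seed = 21))
  td <- tidy(fit)
  expect_lt(abs(td$estimate[td$term == "a"] - p$a_raw), 0.01)
  expect_lt(abs(td$estimate[td$term == "b2"] - p$b2_raw), 0.01)
  lim <- attenuated_b3(p$b3_raw, p$b2_raw, p$var_mB_resid, p$var_mW, 20)
  expect_lt(abs(td$estimate[td$term == "b3"] - lim), 0.02)
})

test_that("noise-free systems are recovered exactly where identified", {
  # fully deterministic data: M is a_raw * X exactly, so a is recovered
  # exactly, but the cluster mean of M is collinear with X and the level-3
  # outcome regression drops rank
  p0 <- raw_params(a_raw = 0.3, b3_raw = 0.6, b2_raw = 0, c_raw = 0.2,
                   n3 = 10, n2 = 5, n1 = 3)
  f0 <- fit_mvm(simulate_mediation(p0, seed = 4))
  t0 <- tidy(f0)
  expect_equal(t0$estimate[t0$term == "a"], 0.3, tolerance = 1e-10)
  expect_false(f0$converged)
  expect_true(is.na(t0$estimate[t0$term == "b3"]))

  # level-3 variation in M beyond X identifies b3 and c'; with every noise
  # term in Y switched off they are recovered to machine precision
  p1 <- raw_params(a_raw = 0.3, b3_raw = 0.6, b2_raw = 0, c_raw = 0.2,
                   var_mB_resid = 0.2, n3 = 10, n2 = 5, n1 = 3)
  f1 <- fit_mvm(simulate_mediation(p1, seed = 4))
  t1 <- tidy(f1)
  expect_true(f1$converged)
  expect_equal(t1$estimate[t1$term == "b3"], 0.6, tolerance = 1e-8)
  expect_equal(t1$estimate[t1$term == "c_prime"], 0.2, tolerance = 1e-8)
  expect_true(is.na(t1$estimate[t1$term == "b2"]))  # no within-cluster M variance
})

test_that("zero between-cluster variance of the mediator mean is flagged, not fatal", {
  dat <- simulate_mediation(large_effect_design(n3 = 4, n2 = 3, n1 = 2), seed = 2)
  units <- dplyr::distinct(dat, cluster_id, unit_id)
  # force every cluster mean of M to zero while keeping within variation
  dat <- dat |>
    dplyr::group_by(cluster_id) |>
    dplyr::mutate(m = m - mean(m[!duplicated(unit_id)])) |>
    dplyr::ungroup()
  fit <- fit_mvm(dat)
  expect_false(fit$converged)
  expect_true(is.na(tidy(fit)$estimate[2]))
})

test_that("rescaling Y rescales its paths and SEs while the Sobel z is invariant", {
  dat <- simulate_mediation(large_effect_design(), seed = 31)
  f1 <- fit_mvm(dat)
  f2 <- fit_mvm(dplyr::mutate(dat, y = 3.7 * y))
  t1 <- tidy(f1); t2 <- tidy(f2)
  for (term in c("b3", "b2", "c_prime")) {
    expect_equal(t2$estimate[t2$term == term], 3.7 * t1$estimate[t1$term == term],
                 tolerance = 1e-8)
    expect_equal(t2$std.error[t2$term == term], 3.7 * t1$std.error[t1$term == term],
                 tolerance = 1e-8)
  }
  expect_equal(sobel_test(f2)$z, sobel_test(f1)$z, tolerance = 1e-10)
})

test_that("standard errors shrink at the root-n3 rate", {
  rate <- vapply(c(20, 80, 320), function(n3) {
    d <- large_effect_design(n3 = n3, n2 = 5, n1 = 3)
    mean(vapply(1:40, function(i) {
      tidy(fit_mvm(simulate_mediation(d, seed = 7000 + 13 * n3 + i)))$std.error[1]
    }, numeric(1)))
  }, numeric(1))
  slope <- coef(stats::lm(log(rate) ~ log(c(20, 80, 320))))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.05)
})
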