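test_that("without lower-level noise the latent covariances equal manifest ones", {
  p <- raw_params(a_raw = 0.3, b3_raw = 0.6, b2_raw = 0, c_raw = 0.2,
                  var_mB_resid = 0.2, n3 = 10, n2 = 5, n1 = 3)
  dat <- simulate_mediation(p, seed = 4)
  lb <- latent_between_cov(dat)
  cm <- dat |>
    dplyr::distinct(cluster_id, unit_id, x, m) |>
    dplyr::group_by(cluster_id, x) |>
    dplyr::summarise(mbar = mean(m), .groups = "drop")
  expect_equal(lb$between["m_b", "m_b"], var(cm$mbar), tolerance = 1e-10)
  expect_equal(lb$between["x", "m_b"], cov(cm$x, cm$mbar), tolerance = 1e-10)
  expect_equal(lb$within["m_w", "m_w"], 0)
})

test_that("the latent level-3 variance strips the cluster-mean sampling error", {
  d <- large_effect_design(n3 = 2000, n2 = 5, n1 = 3)
  stats <- vapply(1:20, function(i) {
    dat <- simulate_mediation(d, seed = 500 + i)
    lb <- latent_between_cov(dat)
    cm <- dat |>
      dplyr::distinct(cluster_id, unit_id, m) |>
      dplyr::group_by(cluster_id) |>
      dplyr::summarise(mbar = mean(m), .groups = "drop")
    c(var(cm$mbar), lb$between["m_b", "m_b"])
  }, numeric(2))
  # manifest cluster-mean variance is inflated to ~ icc + (1-icc)/n2 = 0.36
  expect_lt(abs(mean(stats[1, ]) - 0.36), 0.01)
  expect_lt(abs(mean(stats[2, ]) - 0.2), 0.01)
})

test_that("latent covariances with X vanish under a null design", {
  d <- null_design(n3 = 400, n2 = 5, n1 = 3)
  lb <- latent_between_cov(simulate_mediation(d, seed = 8))
  expect_lt(abs(lb$between["x", "m_b"]), 3 * sqrt(0.36 / 400))
  expect_lt(abs(lb$between["x", "y_b"]), 3 * sqrt(0.4 / 400))
})

test_that("the latent estimator is unattenuated where the manifest one is biased", {
  # the latent slope is noisy even at n3 = 2000 (the moment correction is
  # large at n2 = 5), so the consistency claim is tested on an average of
  # independent large datasets
  d <- large_effect_design(n3 = 2000, n2 = 5, n1 = 3)
  p <- derive_components(d)
  ests <- vapply(1:25, function(i) {
    dat <- simulate_mediation(d, seed = 1300 + i)
    c(tidy(fit_msem(dat, bootstrap_reps = 50, seed = i))$estimate[2],
      tidy(fit_mvm(dat))$estimate[2])
  }, numeric(2))
  b3_msem <- mean(ests[1, ]); b3_mvm <- mean(ests[2, ])
  lim <- attenuated_b3(p$b3_raw, p$b2_raw, p$var_mB_resid, p$var_mW, 5)
  expect_lt(abs(b3_msem - p$b3_raw), 0.02)
  expect_lt(abs(b3_mvm - lim), 0.02)
  expect_lt(b3_mvm, b3_msem - 0.1)  # the attenuation gap is material at n2 = 5
})

test_that("the attenuation gap shrinks as clusters grow internally", {
  gaps <- vapply(c(5, 20), function(n2) {
    d <- large_effect_design(n3 = 1000, n2 = n2, n1 = 3)
    p <- derive_components(d)
    p$b3_raw - attenuated_b3(p$b3_raw, p$b2_raw, p$var_mB_resid, p$var_mW, n2)
  }, numeric(1))
  expect_lt(gaps[2], gaps[1] / 2)
  # and empirically the MVM fit tracks the limit at both widths
  for (n2 in c(5, 20)) {
    d <- large_effect_design(n3 = 1000, n2 = n2, n1 = 3)
    p <- derive_components(d)
    b3 <- tidy(fit_mvm(simulate_mediation(d, seed = 1700 + n2)))$estimate[2]
    expect_lt(abs(b3 - attenuated_b3(p$b3_raw, p$b2_raw, p$var_mB_resid,
                                     p$var_mW, n2)), 0.03)
  }
})

test_that("noise-free data recover the raw paths exactly", {
  # fully deterministic: M proportional to X leaves b3/c unidentified (the
  # latent predictor matrix is singular) but a is still exact
  p0 <- raw_params(a_raw = 0.3, b3_raw = 0.6, b2_raw = 0, c_raw = 0.2,
                   n3 = 10, n2 = 5, n1 = 3)
  f0 <- fit_msem(simulate_mediation(p0, seed = 4), bootstrap_reps = 50, seed = 2)
  expect_equal(tidy(f0)$estimate[1], 0.3, tolerance = 1e-10)
  expect_false(f0$converged)

  # latent level-3 variation in M with all Y noise off: exact b3 and c'
  p1 <- raw_params(a_raw = 0.3, b3_raw = 0.6, b2_raw = 0, c_raw = 0.2,
                   var_mB_resid = 0.2, n3 = 10, n2 = 5, n1 = 3)
  fit <- fit_msem(simulate_mediation(p1, seed = 4), bootstrap_reps = 50, seed = 2)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "b3"], 0.6, tolerance = 1e-8)
  expect_equal(td$estimate[td$term == "c_prime"], 0.2, tolerance = 1e-8)
})

test_that("latent path estimates are unbiased under the null", {
  d <- null_design(n3 = 40, n2 = 5, n1 = 3)
  b3 <- vapply(1:200, function(i) {
    dat <- simulate_mediation(d, seed = 3000 + i)
    lb <- latent_between_cov(dat)
    s <- lb$between[c("m_b", "x"), c("m_b", "x")]
    if (s["m_b", "m_b"] <= 0) return(NA_real_)
    drop(solve(s, lb$between[c("m_b", "x"), "y_b"]))[1]
  }, numeric(1))
  b3 <- b3[is.finite(b3)]
  expect_lt(abs(mean(b3)), 3 * sd(b3) / sqrt(length(b3)))
})

test_that("MSEM bootstrap SEs exceed the MVM model SEs on the same data", {
  d <- large_effect_design(n3 = 40, n2 = 10, n1 = 3)
  ratio <- vapply(1:20, function(i) {
    dat <- simulate_mediation(d, seed = 4200 + i)
    se_msem <- tidy(fit_msem(dat, bootstrap_reps = 100, seed = i))$std.error[2]
    se_mvm <- tidy(fit_mvm(dat))$std.error[2]
    se_msem / se_mvm
  }, numeric(1))
  expect_gt(mean(ratio, na.rm = TRUE), 1)
})

test_that("the bootstrap SE stabilizes as resamples double", {
  dat <- simulate_mediation(large_effect_design(n3 = 200, n2 = 10, n1 = 3),
                            seed = 77)
  se1 <- tidy(fit_msem(dat, bootstrap_reps = 400, seed = 1))$std.error[2]
  se2 <- tidy(fit_msem(dat, bootstrap_reps = 800, seed = 2))$std.error[2]
  expect_lt(abs(se2 - se1) / se1, 0.10)
})

test_that("a negative latent mediator variance marks the fit non-converged", {
  # small icc_m3 with many units per cluster: the moment correction can
  # exceed the manifest between variance
  d <- design_grid(a3 = 0.14, b3 = 0.14, c3p = 0.14, icc_m3 = 0.05,
                   icc_y2 = 0.1, icc_y3 = 0.1, n3 = 10, n2 = 20, n1 = 3)
  conv <- vapply(1:40, function(i) {
    fit_msem(simulate_mediation(d, seed = 5200 + i),
             bootstrap_reps = 50, seed = i)$converged
  }, logical(1))
  expect_true(any(!conv))
  expect_true(any(conv))
})

test_that("too few clusters per arm is an error", {
  dat <- simulate_mediation(large_effect_design(n3 = 2, n2 = 5, n1 = 3), seed = 1)
  expect_error(fit_msem(dat, bootstrap_reps = 50, seed = 1), "arm")
  expect_error(fit_msem(simulate_mediation(large_effect_design(), seed = 1),
                        bootstrap_reps = 10, seed = 1), "bootstrap_reps")
})
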