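# Generate all replications of one design as unit-level sufficient
# statistics: unit M, unit-mean Y, and level-1 residual SS (exact Gaussian
# sampling at the statistic level; level-1 rows never materialize). Columns
# are replications. `per_unit_ss1` switches the level-1 residual SS between
# one pooled chi-square per replication (enough for the MVM fitter) and
# per-unit draws (needed by the MSEM cluster bootstrap).
simulate_reps <- function(p, reps, per_unit_ss1 = FALSE) {
  n3 <- p$n3; n2 <- p$n2; n1 <- p$n1
  x <- x_codes_for(n3)
  cl <- rep(seq_len(n3), each = n2)
  nu <- n3 * n2
  u <- matrix(rnorm(n3 * reps, 0, sqrt(p$var_mB_resid)), n3, reps)
  w <- matrix(rnorm(nu * reps, 0, sqrt(p$var_mW)), nu, reps)
  e_b <- matrix(rnorm(n3 * reps, 0, sqrt(p$var_yB_resid)), n3, reps)
  e_2 <- matrix(rnorm(nu * reps, 0, sqrt(p$var_y2_resid)), nu, reps)
  ebar1 <- matrix(rnorm(nu * reps, 0, sqrt(p$var_y1 / n1)), nu, reps)
  m_b <- p$a_raw * x + u
  m <- m_b[cl, , drop = FALSE] + w
  v <- p$b3_raw * m_b + p$c_raw * x + e_b
  ybar <- v[cl, , drop = FALSE] + p$b2_raw * w + e_2 + ebar1
  ss1 <- if (n1 > 1 && p$var_y1 > 0) {
    if (per_unit_ss1) {
      matrix(p$var_y1 * rchisq(nu * reps, df = n1 - 1), nu, reps)
    } else {
      p$var_y1 * rchisq(reps, df = nu * (n1 - 1))
    }
  } else {
    if (per_unit_ss1) matrix(0, nu, reps) else rep(0, reps)
  }
  list(x = x, m = m, ybar = ybar, ss1 = ss1)
}

design_substream <- function(seed, d) {
  substream_seed(seed,
                 round(100 * d$a3), round(100 * d$b3), round(100 * d$c3p),
                 round(100 * d$b2), round(100 * d$icc_m3),
                 round(100 * d$icc_y2), round(100 * d$icc_y3),
                 d$n3, d$n2, d$n1)
}

power_one_design <- function(d, estimator, reps, seed, alpha, direction,
                             bootstrap_reps) {
  p <- as.list(d)
  dseed <- design_substream(seed, d)
  set.seed(dseed)
  zcrit2 <- qnorm(1 - alpha / 2)
  zcrit1 <- qnorm(1 - alpha)

  if (estimator == "mvm") {
    sim <- simulate_reps(p, reps, per_unit_ss1 = FALSE)
    core <- mvm_core(sim$x, sim$m, sim$ybar, sim$ss1, p$n3, p$n2, p$n1)
    ok <- core$converged & is.finite(core$se_a) & is.finite(core$se_b3) &
      core$se_a > 0 & core$se_b3 > 0
    a <- core$a_hat[ok]; b <- core$b3_hat[ok]
    se_ab <- sqrt(a^2 * core$se_b3[ok]^2 + b^2 * core$se_a[ok]^2)
    z <- (a * b) / se_ab
  } else {
    sim <- simulate_reps(p, reps, per_unit_ss1 = TRUE)
    st <- cluster_stats(sim$x, sim$m, sim$ybar, sim$ss1, p$n3, p$n2)
    pt <- msem_point(st, p$n3, p$n2, p$n1)
    z <- rep(NA_real_, reps)
    for (r in which(pt$converged)) {
      st1 <- list(x = st$x, mbar = st$mbar[, r], ybar = st$ybar[, r],
                  swm = st$swm[, r], swy = st$swy[, r],
                  swmy = st$swmy[, r], ss1 = st$ss1[, r])
      bse <- msem_boot(st1, p$n3, p$n2, p$n1, bootstrap_reps)
      if (bse$n_ok >= bootstrap_reps / 2 &&
          is.finite(bse$se_a) && is.finite(bse$se_b3) &&
          bse$se_a > 0 && bse$se_b3 > 0) {
        ab <- pt$a_hat[r] * pt$b3_hat[r]
        z[r] <- ab / sqrt(pt$a_hat[r]^2 * bse$se_b3^2 +
                            pt$b3_hat[r]^2 * bse$se_a^2)
      }
    }
    z <- z[is.finite(z)]
  }

  completed <- length(z)
  if (completed == 0) {
    abort("degenerate design: no replication produced a usable fit")
  }
  rej2 <- sum(abs(z) >= zcrit2)
  rej1 <- sum(direction * z >= zcrit1)
  p2 <- rej2 / completed
  p1 <- rej1 / completed
  tibble::tibble(
    estimator = toupper(estimator),
    reps_requested = reps,
    reps_completed = completed,
    rejections_two = rej2,
    rejections_one = rej1,
    power_two = p2,
    power_one = p1,
    mc_se_two = sqrt(p2 * (1 - p2) / completed),
    mc_se_one = sqrt(p1 * (1 - p1) / completed),
    seed = seed,
    design_seed = dseed
  )
}

#' Monte Carlo power of the Sobel test for each design
#'
#' For every design (row), repeatedly simulates data from the implied
#' population, fits the chosen estimator, applies the Sobel test to the
#' indirect effect, and reports rejection proportions for the 2-sided and
#' 1-sided tests in one pass (the 1-sided decision is recovered from the
#' stored z statistic). Replications whose fit does not converge are
#' excluded from the power denominator; `reps_completed` exposes the
#' completion count so an "out of requested replications" power can also be
#' formed. Monte Carlo standard errors `sqrt(p(1-p)/reps_completed)`
#' accompany every estimate.
#'
#' Each design draws from its own random substream derived from `seed` and
#' the design's field values, so results are identical whatever the order
#' or parallelization of the sweep, and any single design can be recomputed
#' in isolation.
#'
#' @inheritParams validate_designs
#' @param estimator `"mvm"` (manifest multilevel regression, the default)
#'   or `"msem"` (latent decomposition with cluster bootstrap).
#' @param reps Replications per design (default 500).
#' @param seed Run-level integer seed.
#' @param alpha Test level (default 0.05).
#' @param direction Hypothesized sign of the indirect effect for the
#'   1-sided test (default +1, the sign of every design in the reference
#'   grid).
#' @param bootstrap_reps Bootstrap resamples per replication (MSEM only).
#' @return A tibble with one row per design: the design columns, `n_total`,
#'   and the power accounting described above. Class `medpower_result`,
#'   which has an [autoplot()] method.
#' @examples
#' d <- design_grid(a3 = 0.59, b3 = 0.59, c3p = 0.39, icc_m3 = 0.2,
#'                  icc_y2 = 0.2, icc_y3 = 0.2, n3 = 40, n2 = 5, n1 = 6)
#' estimate_power(d, reps = 100, seed = 1)
#' @export
estimate_power <- function(designs, estimator = c("mvm", "msem"), reps = 500,
                           seed = 1, alpha = 0.05, direction = 1,
                           bootstrap_reps = 200) {
  estimator <- match.arg(estimator)
  if (reps < 1) abort("reps must be >= 1")
  comp <- derive_components(designs)
  comp <- total_sample(comp)
  rows <- purrr::map(seq_len(nrow(comp)), function(i) {
    power_one_design(comp[i, ], estimator, reps, seed, alpha, direction,
                     bootstrap_reps)
  })
  out <- dplyr::bind_cols(
    comp[, c(design_fields, "n_total")],
    dplyr::bind_rows(rows)
  )
  class(out) <- c("medpower_result", class(out))
  out
}

#' Sweep a design grid with checkpointing
#'
#' [estimate_power()] over a (possibly large) grid, writing completed rows
#' to a checkpoint CSV in chunks so an interrupted sweep resumes where it
#' stopped with identical results. The checkpoint records the run settings;
#' resuming with different settings or a grid that does not contain the
#' checkpointed designs is an error. Because every design has its own seed
#' substream, results do not depend on chunking, resumption, or the number
#' of workers.
#'
#' @inheritParams estimate_power
#' @param checkpoint Path to a checkpoint CSV, or `NULL` for no
#'   checkpointing.
#' @param workers Number of forked worker processes (via
#'   [parallel::mclapply()]; 1 = sequential).
#' @param chunk_size Designs per checkpoint flush.
#' @return As [estimate_power()], rows in the order of `designs`.
#' @export
sweep_power <- function(designs, estimator = c("mvm", "msem"), reps = 500,
                        seed = 1, alpha = 0.05, direction = 1,
                        bootstrap_reps = 200, checkpoint = NULL,
                        workers = 1, chunk_size = 500) {
  estimator <- match.arg(estimator)
  comp <- total_sample(derive_components(designs))
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- readr::read_csv(checkpoint, col_types = readr::cols(),
                            progress = FALSE)
  }
  key <- function(df) do.call(paste, c(df[design_fields], sep = "|"))
  if (!is.null(done) && nrow(done) > 0) {
    if (!all(done$estimator == toupper(estimator)) ||
        !all(done$reps_requested == reps) || !all(done$seed == seed)) {
      abort("checkpoint settings (estimator/reps/seed) do not match this call")
    }
    if (!all(key(done) %in% key(comp))) {
      abort("checkpoint contains designs that are not in this grid")
    }
  }
  todo <- if (is.null(done)) seq_len(nrow(comp)) else which(!key(comp) %in% key(done))
  run_one <- function(i) {
    power_one_design(comp[i, ], estimator, reps, seed, alpha, direction,
                     bootstrap_reps)
  }
  chunks <- split(todo, ceiling(seq_along(todo) / chunk_size))
  new_rows <- list()
  for (ch in chunks) {
    res <- if (workers > 1) {
      parallel::mclapply(ch, run_one, mc.cores = workers)
    } else {
      lapply(ch, run_one)
    }
    block <- dplyr::bind_cols(comp[ch, c(design_fields, "n_total")],
                              dplyr::bind_rows(res))
    if (!is.null(checkpoint)) {
      readr::write_csv(block, checkpoint, append = file.exists(checkpoint))
    }
    new_rows[[length(new_rows) + 1]] <- block
  }
  out <- dplyr::bind_rows(done, dplyr::bind_rows(new_rows))
  out <- out[match(key(comp), key(out)), ]
  class(out) <- c("medpower_result", class(out))
  out
}
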