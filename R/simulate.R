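#' @noRd
#' Deterministic substream seed from a run seed and integer keys.
#' Multiplicative-xor mixing in exact double arithmetic, reduced modulo
#' 2^31 - 2 so the result is always a valid positive 32-bit seed. Different
#' key tuples give (for practical purposes) unrelated Mersenne-Twister
#' initializations.
substream_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(seed) %% m) + 1
  for (k in c(...)) {
    h <- (h * 48271) %% m
    h <- (h + (as.numeric(k) %% m) * 16807) %% m
    h <- bitwXor(as.integer(h), as.integer((h * 69069) %% 2^31))
    h <- (abs(as.numeric(h)) %% m)
  }
  as.integer(h %% (m - 1) + 1)
}

x_codes_for <- function(n3) {
  rep(c(-1, 1), each = n3 / 2)
}

#' Simulate one balanced 3-2-1 mediation dataset
#'
#' Generates long-format data from the three-level Gaussian random-intercept
#' model implied by a design: the cluster-level treatment X (coded -1/+1,
#' first half of clusters control), a level-2 mediator M with variance split
#' across levels 3 and 2, and a level-1 outcome Y with variance at levels 3,
#' 2, and 1. For cluster k, level-2 unit j, observation i:
#' \deqn{M_{jk} = a\,X_k + u_k + w_{jk}}
#' \deqn{Y_{ijk} = b_3^{raw}(a X_k + u_k) + c^{raw} X_k + e_{Bk}
#'                + b_2^{raw} w_{jk} + e_{2jk} + e_{1ijk}}
#' with independent Gaussian terms whose variances come from
#' [derive_components()]. The same `(design, seed)` always reproduces the
#' same dataset.
#'
#' @param design A one-row design tibble (see [design_grid()]); raw
#'   components are derived automatically if absent.
#' @param seed Integer seed for this dataset.
#' @return A tibble with `n3 * n2 * n1` rows and columns `cluster_id`,
#'   `unit_id`, `obs_id`, `x`, `m`, `y`. `m` is constant within a level-2
#'   unit and `x` within a cluster.
#' @examples
#' d <- design_grid(a3 = 0.59, b3 = 0.59, c3p = 0.39, icc_m3 = 0.2,
#'                  icc_y2 = 0.1, icc_y3 = 0.2, n3 = 10, n2 = 5, n1 = 3)
#' sim <- simulate_mediation(d, seed = 7)
#' nrow(sim)  # 150
#' @export
simulate_mediation <- function(design, seed) {
  if (nrow(design) != 1) abort("simulate_mediation() expects a single design (one row)")
  p <- as.list(if ("a_raw" %in% names(design)) design else derive_components(design))
  n3 <- p$n3; n2 <- p$n2; n1 <- p$n1
  x <- x_codes_for(n3)

  set.seed(seed)
  u <- rnorm(n3, 0, sqrt(p$var_mB_resid))
  w <- rnorm(n3 * n2, 0, sqrt(p$var_mW))
  e_b <- rnorm(n3, 0, sqrt(p$var_yB_resid))
  e_2 <- rnorm(n3 * n2, 0, sqrt(p$var_y2_resid))
  e_1 <- rnorm(n3 * n2 * n1, 0, sqrt(p$var_y1))

  m_b <- p$a_raw * x + u                      # latent level-3 component of M
  cl <- rep(seq_len(n3), each = n2)
  m <- m_b[cl] + w
  v <- p$b3_raw * m_b + p$c_raw * x + e_b     # level-3 component of Y
  s <- p$b2_raw * w + e_2                     # level-2 component of Y
  unit_row <- rep(seq_len(n3 * n2), each = n1)
  y <- v[cl][unit_row] + s[unit_row] + e_1

  tibble::tibble(
    cluster_id = cl[unit_row],
    unit_id = rep(rep(seq_len(n2), each = n1), times = n3),
    obs_id = rep(seq_len(n1), times = n3 * n2),
    x = x[cl][unit_row],
    m = m[unit_row],
    y = y
  )
}

#' Read/write long-format mediation datasets
#'
#' CSV with header `cluster_id,unit_id,obs_id,x,m,y`; numeric columns are
#' written at full double precision so a round trip is lossless.
#'
#' @param data A dataset as returned by [simulate_mediation()].
#' @param path File path.
#' @return `write_mediation_csv()` returns `path` invisibly;
#'   `read_mediation_csv()` returns the dataset tibble.
#' @export
write_mediation_csv <- function(data, path) {
  cols <- c("cluster_id", "unit_id", "obs_id", "x", "m", "y")
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0("dataset is missing column(s): ", paste(missing, collapse = ", ")))
  }
  out <- data[cols]
  # 17 significant digits guarantee exact double round trips
  for (v in c("x", "m", "y")) out[[v]] <- sprintf("%.17g", out[[v]])
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_mediation_csv
#' @export
read_mediation_csv <- function(path) {
  # parse floats via as.numeric(): readr's fast parser can be off by an ulp
  out <- readr::read_csv(path,
    col_types = readr::cols(
      cluster_id = readr::col_integer(),
      unit_id = readr::col_integer(),
      obs_id = readr::col_integer(),
      x = readr::col_character(),
      m = readr::col_character(),
      y = readr::col_character()
    )
  )
  for (v in c("x", "m", "y")) out[[v]] <- as.numeric(out[[v]])
  out
}
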