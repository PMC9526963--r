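#' Build a grid of 3-2-1 mediation design specifications
#'
#' A design is one cell of a power-analysis grid: the standardized paths of
#' the mediation model, the intraclass correlations (ICCs) of mediator and
#' outcome, and the per-level sample sizes. `design_grid()` fully crosses the
#' supplied value lists and returns one row per design, ordered
#' lexicographically over the arguments in the order they are declared (last
#' argument varying fastest), so enumeration is stable across runs.
#'
#' The defaults are the reference grid for implementation-trial planning:
#' small/medium/large standardized indirect-effect paths (0.14, 0.39, 0.59),
#' small/medium direct effects, a medium level-2 slope, ICCs of 0.05, 0.10,
#' 0.20 at each relevant level, and realistic sample sizes per level. Fully
#' crossed these give 17,496 designs.
#'
#' @param a3 Standardized level-3 path X to M (dimensionless).
#' @param b3 Standardized level-3 path M to Y.
#' @param c3p Standardized level-3 direct effect X to Y.
#' @param b2 Standardized level-2 (within-cluster) path M to Y.
#' @param icc_m3 Proportion of mediator variance at level 3, in (0, 1).
#' @param icc_y2,icc_y3 Proportions of outcome variance at levels 2 and 3;
#'   their sum must stay below 1.
#' @param n3 Number of level-3 clusters (must be even: the two arms are
#'   assigned exactly 50/50).
#' @param n2 Number of level-2 units per cluster (at least 2).
#' @param n1 Number of level-1 observations per level-2 unit (at least 1).
#'
#' @return A tibble with one row per design and the ten columns above, plus
#'   class `"design_grid"`.
#' @examples
#' nrow(design_grid())            # 17496
#' design_grid(n3 = 40, n2 = 10)  # restrict two axes
#' @export
design_grid <- function(a3 = c(0.14, 0.39, 0.59),
                        b3 = c(0.14, 0.39, 0.59),
                        c3p = c(0.14, 0.39),
                        b2 = 0.39,
                        icc_m3 = c(0.05, 0.10, 0.20),
                        icc_y2 = c(0.05, 0.10, 0.20),
                        icc_y3 = c(0.05, 0.10, 0.20),
                        n3 = c(10, 20, 40, 60),
                        n2 = c(5, 10, 20),
                        n1 = c(3, 6, 12)) {
  values <- list(a3 = a3, b3 = b3, c3p = c3p, b2 = b2,
                 icc_m3 = icc_m3, icc_y2 = icc_y2, icc_y3 = icc_y3,
                 n3 = n3, n2 = n2, n1 = n1)
  for (nm in names(values)) {
    if (length(values[[nm]]) == 0 || anyNA(values[[nm]])) {
      abort(paste0("design_grid(): `", nm, "` must be a non-empty numeric vector"))
    }
  }
  grid <- do.call(tidyr::expand_grid, values)
  validate_designs(grid)
  class(grid) <- c("design_grid", class(grid))
  grid
}

design_fields <- c("a3", "b3", "c3p", "b2",
                   "icc_m3", "icc_y2", "icc_y3", "n3", "n2", "n1")

#' Validate design specifications
#'
#' Checks every row of a design tibble against the constraints of the
#' standardized 3-2-1 parameterization: ICCs in (0, 1) with
#' `icc_y2 + icc_y3 < 1`; `|a3| < 1` and `|b2| < 1`; the level-3 explained
#' fraction `b3^2 + c3p^2 + 2*a3*b3*c3p < 1`; `n3` even and at least 2
#' (exact two-arm balance); `n2 >= 2`; `n1 >= 1`. The first violated
#' constraint raises an error naming the offending field.
#'
#' @param designs A data frame with the columns produced by [design_grid()].
#' @return `designs`, invisibly, if all rows are valid.
#' @export
validate_designs <- function(designs) {
  missing <- setdiff(design_fields, names(designs))
  if (length(missing) > 0) {
    abort(paste0("missing design column(s): ", paste(missing, collapse = ", ")))
  }
  d <- designs
  fail <- function(field, why) {
    abort(paste0("invalid design specification: field `", field, "` ", why))
  }
  if (any(d$icc_m3 <= 0 | d$icc_m3 >= 1)) fail("icc_m3", "must lie in (0, 1)")
  if (any(d$icc_y2 <= 0 | d$icc_y3 <= 0)) fail("icc_y2/icc_y3", "must be positive")
  if (any(d$icc_y2 + d$icc_y3 >= 1)) fail("icc_y2", "+ icc_y3 must be < 1")
  if (any(abs(d$a3) >= 1)) fail("a3", "must satisfy |a3| < 1")
  if (any(abs(d$b2) >= 1)) fail("b2", "must satisfy |b2| < 1")
  r2b <- d$b3^2 + d$c3p^2 + 2 * d$a3 * d$b3 * d$c3p
  if (any(r2b >= 1)) fail("b3", "with c3p implies level-3 explained variance >= 1")
  if (any(d$n3 < 2 | d$n3 %% 2 != 0)) fail("n3", "must be even and >= 2 for exact two-arm balance")
  if (any(d$n2 < 2)) fail("n2", "must be >= 2")
  if (any(d$n1 < 1)) fail("n1", "must be >= 1")
  if (any(c(d$n1, d$n2, d$n3) %% 1 != 0)) fail("n3/n2/n1", "must be whole numbers")
  invisible(designs)
}

#' Total sample size of each design
#'
#' Appends `n_total = n3 * n2 * n1`, the number of level-1 observations.
#'
#' @inheritParams validate_designs
#' @return The input with an `n_total` column.
#' @examples
#' total_sample(design_grid(n3 = 10, n2 = 5, n1 = 3))$n_total  # 150
#' @export
total_sample <- function(designs) {
  dplyr::mutate(designs, n_total = .data$n3 * .data$n2 * .data$n1)
}

#' Count designs by total sample size
#'
#' Tabulates how many designs in a grid share each total sample size
#' (the "total sample size" block of a design-frequency table).
#'
#' @inheritParams validate_designs
#' @return A tibble with columns `n_total` and `n_designs`, ascending in
#'   `n_total`; the counts sum to `nrow(designs)`.
#' @export
count_designs_by_total <- function(designs) {
  total_sample(designs) |>
    dplyr::count(.data$n_total, name = "n_designs") |>
    dplyr::arrange(.data$n_total)
}

#' Write a design grid to CSV
#'
#' One row per design, columns in canonical declaration order, full float
#' precision. The file round-trips through [readr::read_csv()].
#'
#' @inheritParams validate_designs
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_designs_csv <- function(designs, path) {
  validate_designs(designs)
  readr::write_csv(designs[, union(design_fields, names(designs))], path)
  invisible(path)
}

#' Read a grid definition from a JSON or YAML config file
#'
#' The config holds one entry per design field (scalar or list of values);
#' missing fields fall back to the defaults of [design_grid()]. The format is
#' chosen by file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Path to the config file.
#' @return A fully crossed design grid (see [design_grid()]).
#' @export
read_grid_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    abort(paste0("unsupported config extension: `.", ext, "` (use .json or .yaml)"))
  )
  unknown <- setdiff(names(cfg), design_fields)
  if (length(unknown) > 0) {
    abort(paste0("unknown grid field(s) in config: ", paste(unknown, collapse = ", ")))
  }
  do.call(design_grid, lapply(cfg, unlist))
}
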