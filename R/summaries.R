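#' Adequacy of power by design characteristic
#'
#' Tabulates, for every value of every design parameter (and for total
#' sample size, and overall), how many designs were evaluated and how many
#' reached the adequacy threshold — the classic design-frequency table of a
#' power-analysis sweep.
#'
#' @param results A power result tibble from [estimate_power()] /
#'   [sweep_power()].
#' @param threshold Adequate-power threshold (default 0.8).
#' @param sided `"two"` (default) or `"one"`: which rejection proportion to
#'   threshold.
#' @return A tibble with columns `characteristic`, `value`, `n_designs`,
#'   `n_adequate`, `prop_adequate`; the first row is the overall total.
#' @export
summarize_power_marginals <- function(results, threshold = 0.8,
                                      sided = c("two", "one")) {
  sided <- match.arg(sided)
  pw <- results[[paste0("power_", sided)]]
  res <- total_sample(results)
  res$.adequate <- pw >= threshold
  chars <- c(design_fields, "n_total")
  one <- function(ch) {
    res |>
      dplyr::group_by(value = .data[[ch]]) |>
      dplyr::summarise(n_designs = dplyr::n(),
                       n_adequate = sum(.data$.adequate, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(characteristic = ch, .before = 1) |>
      dplyr::arrange(.data$value)
  }
  total <- tibble::tibble(characteristic = "total", value = NA_real_,
                          n_designs = nrow(res),
                          n_adequate = sum(res$.adequate, na.rm = TRUE))
  dplyr::bind_rows(total, purrr::map_dfr(chars, one)) |>
    dplyr::mutate(prop_adequate = .data$n_adequate / .data$n_designs)
}

#' Minimum sample sizes for adequate power
#'
#' For each effect-size/ICC cell — a combination of `a3`, `b3`, `c3p`,
#' `icc_m3`, `icc_y3` (collapsing over any remaining axes such as
#' `icc_y2`) — finds the smallest sample-size combination with power at or
#' above the threshold. "Smallest" is lexicographic: smallest `n3` first
#' (highest-level units are the costliest to recruit), then smallest `n2`,
#' then smallest `n1`. Cells where no combination qualifies are returned
#' with `NA` sample sizes.
#'
#' @inheritParams summarize_power_marginals
#' @return A tibble with one row per cell: `icc_m3`, `icc_y3`, `a3`, `b3`,
#'   `c3p`, the winning `n3`, `n2`, `n1`, `n_total`, and its `power`
#'   (`NA` when no design in the cell qualifies).
#' @export
minimum_sample_sizes <- function(results, threshold = 0.8,
                                 sided = c("two", "one")) {
  sided <- match.arg(sided)
  pcol <- paste0("power_", sided)
  res <- total_sample(results)
  cells <- dplyr::distinct(res, .data$icc_m3, .data$icc_y3,
                           .data$a3, .data$b3, .data$c3p)
  best <- res |>
    dplyr::filter(.data[[pcol]] >= threshold) |>
    dplyr::arrange(.data$n3, .data$n2, .data$n1) |>
    dplyr::group_by(.data$icc_m3, .data$icc_y3, .data$a3, .data$b3, .data$c3p) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::mutate(power = .data[[pcol]]) |>
    dplyr::select("icc_m3", "icc_y3", "a3", "b3", "c3p",
                  "n3", "n2", "n1", "n_total", "power")
  cells |>
    dplyr::left_join(best, by = c("icc_m3", "icc_y3", "a3", "b3", "c3p")) |>
    dplyr::arrange(.data$icc_m3, .data$icc_y3, .data$a3, .data$b3, .data$c3p)
}
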