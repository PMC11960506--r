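#' Plot measured dose-response points with fitted Hill overlays
#'
#' @param data Long tibble with columns `re_id`, `dosage`, `value` (e.g.
#'   from [as_tibble.dosage_matrix()]).
#' @param fits Fit table from [fit_dose_response()] for the same REs.
#'
#' @return A ggplot, faceted by RE, dosage as percent on the x axis.
#' @export
plot_dose_response <- function(data, fits) {
  fits <- filter(fits, .data$converged)
  grid <- tidyr::expand_grid(re_id = fits$re_id, d = seq(0, 1, length.out = 101)) |>
    dplyr::left_join(fits, by = "re_id") |>
    mutate(y = hill_mean(.data$d, .data$K, .data$h, .data$y_min, .data$y_max))
  # measured values on the scaled axis used for fitting
  scaled <- data |>
    group_by(.data$re_id) |>
    mutate(value = .data$value / max(abs(.data$value))) |>
    ungroup()
  ggplot2::ggplot(scaled, ggplot2::aes(x = 100 * .data$dosage, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = 100 * .data$d, y = .data$y),
                       color = "#d95f02") +
    ggplot2::facet_wrap(~re_id, scales = "free_y") +
    ggplot2::labs(x = "TF dosage (%)", y = "scaled accessibility") +
    ggplot2::theme_minimal()
}

#' Theoretical ED50 versus second-site affinity ratio
#'
#' The competition-model panel: for each competition strength `c`, the
#' two-site theoretical ED50 (relative to the single-site value) as a
#' function of the second site's K_D ratio. Ratios above the horizontal
#' reference line sensitize; at `c = 0` no ratio does.
#'
#' @param c_values Competition strengths to draw.
#' @param L Nucleosome/open equilibrium constant.
#' @param ratios K_D ratio grid.
#'
#' @return A ggplot on log10 x scale.
#' @export
plot_theory_ed50 <- function(c_values = c(0, 0.001, 0.01), L = 1000,
                             ratios = 10^seq(0, 5, by = 0.25)) {
  dat <- bind_rows(purrr::map(c_values, function(cc) {
    scan <- sensitizing_threshold(L = L, c = cc, ratios = ratios)
    mutate(scan$scan, c = cc, rel_ed50 = .data$ed50 / scan$single_ed50)
  }))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ratio, y = .data$rel_ed50,
                                    color = factor(.data$c))) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, color = "grey50") +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "second-site K_D ratio (low/high affinity)",
                  y = "two-site ED50 / single-site ED50",
                  color = "competition c") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_hill Plot a single fitted Hill curve.
#' @param object A `hill_fit`.
#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, ...) {
  d <- seq(0, 1, length.out = 101)
  dat <- tibble(dosage = 100 * d, y = predict(object, data.frame(d = d)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$dosage, y = .data$y)) +
    ggplot2::geom_line(color = "#d95f02") +
    ggplot2::labs(x = "TF dosage (%)", y = "fitted response") +
    ggplot2::theme_minimal()
}

#' @describeIn sensitizing_threshold Plot the scanned ED50s against the
#'   ratio grid.
#' @param object A `sensitizing_scan`.
#' @param ... Unused.
#' @method autoplot sensitizing_scan
#' @export
autoplot.sensitizing_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$ratio, y = .data$ed50)) +
    ggplot2::geom_hline(yintercept = object$single_ed50, linetype = 2,
                        color = "grey50") +
    ggplot2::geom_point(ggplot2::aes(color = .data$sensitizing)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "second-site K_D ratio", y = "theoretical ED50") +
    ggplot2::theme_minimal()
}
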