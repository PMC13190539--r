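#' Plot the mixture fit over the methylation distribution
#'
#' Histogram of log methylation with the weighted component densities and,
#' when supplied, the intersection cut-off.
#'
#' @param object A [fit_bnmm()] object.
#' @param values Methylation percentages to draw the histogram from
#'   (optional; components alone are drawn otherwise).
#' @param cutoff Optional `meth_cutoff` to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bnmm_fit <- function(object, values = NULL, cutoff = NULL, ...) {
  grid <- seq(object$means[1] - 4 * object$sds[1],
              object$means[2] + 4 * object$sds[2], length.out = 400)
  dens <- tibble::tibble(
    x = rep(grid, 2),
    density = c(object$weights[1] * dnorm(grid, object$means[1], object$sds[1]),
                object$weights[2] * dnorm(grid, object$means[2], object$sds[2])),
    component = rep(c("unmethylated", "methylated"), each = length(grid))
  )
  p <- ggplot2::ggplot(dens, ggplot2::aes(x = .data$x, y = .data$density,
                                          colour = .data$component))
  if (!is.null(values)) {
    hist_df <- tibble::tibble(x = log(pmax(values, object$floor_pct)))
    p <- p + ggplot2::geom_histogram(
      data = hist_df,
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      inherit.aes = FALSE, bins = 40, fill = "grey85", colour = "grey70"
    )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.8)
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff$log_value,
                                 linetype = "dashed")
  }
  p + ggplot2::labs(x = "log(mean methylation %)", y = "density",
                    colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the threshold-scan concordance curve
#'
#' Mean out-of-fold concordance index against the candidate cut-off, with
#' the selected threshold marked.
#'
#' @param object A [scan_thresholds()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.threshold_scan <- function(object, ...) {
  df <- dplyr::filter(object$scan, .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$candidate, y = .data$c_mean)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_cutoff,
                        colour = "forestgreen") +
    ggplot2::labs(x = "candidate cut-off (% methylation)",
                  y = "mean out-of-fold concordance index") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step plot
#'
#' @param object A [km_estimate()] curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    dplyr::select(object$steps, "time", "survival")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months", y = "overall survival",
                  title = object$group %||% NULL) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves of the three methylation tiers
#'
#' @param object A [three_tier_survival_report()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tier_survival_report <- function(object, ...) {
  df <- purrr::map_dfr(object$curves, function(cv) {
    dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                     dplyr::select(cv$steps, "time", "survival")) |>
      dplyr::mutate(tier = cv$group)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$tier)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "months from primary surgery", y = "overall survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
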