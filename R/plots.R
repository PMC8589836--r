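# Quick-look plotting helpers.

#' Plot a fluorescence or extension trace
#'
#' @param trace Tibble with `time_s` and either `intensity_au` or
#'   `extension_nm`.
#' @param events Optional event/pause tibble with `start_s`/`end_s` to shade.
#' @return A ggplot.
#' @export
plot_trace <- function(trace, events = NULL) {
  ycol <- if (!is.null(trace$intensity_au)) "intensity_au" else "extension_nm"
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time_s, .data[[ycol]])) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (ycol == "intensity_au") "intensity (a.u.)" else "extension (nm)")
  if (!is.null(events) && nrow(events) > 0) {
    p <- p + ggplot2::geom_rect(
      data = events,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.2, fill = "steelblue"
    )
  }
  p
}

#' Plot simulated packaging trajectories
#'
#' @param results Output of [simulate_packaging()] run with
#'   `keep_trajectory = TRUE`.
#' @return A ggplot of unpackaged DNA length vs. time.
#' @export
plot_kmc_trajectories <- function(results) {
  if (is.null(results$trajectory)) {
    abort("Run `simulate_packaging(..., keep_trajectory = TRUE)` to plot trajectories.")
  }
  df <- results |>
    dplyr::select("traj_id", "outcome", "trajectory") |>
    tidyr::unnest("trajectory")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$unpackaged_bp,
                                   group = .data$traj_id,
                                   colour = .data$outcome)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (arb. units)", y = "unpackaged DNA (bp)")
}
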