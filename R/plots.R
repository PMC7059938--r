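#' Plot normalized gap-junction conductance curves
#'
#' @param channel channel name or [channel_spec()].
#' @param vj voltage grid, mV.
#' @return a ggplot object.
#' @export
plot_gj_curve <- function(channel, vj = seq(-120, 120, by = 1)) {
  tab <- gj_curve(channel, vj)
  long <- rbind(
    data.frame(vj_mV = tab$vj_mV, g = tab$g_inst, regime = "instantaneous"),
    data.frame(vj_mV = tab$vj_mV, g = tab$g_ss, regime = "steady-state"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$vj_mV, y = .data$g,
                                     colour = .data$regime)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "transjunctional voltage (mV)",
                  y = "normalized conductance",
                  title = channel_spec(channel)$name) +
    ggplot2::theme_minimal()
}

#' Wavefront snapshots of a strand simulation
#'
#' @param object a `strand_sim`.
#' @param times snapshot times, ms (nearest recorded frames are used).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.strand_sim <- function(object, times = NULL, ...) {
  if (is.null(times))
    times <- stats::quantile(object$time, c(0.1, 0.3, 0.5, 0.7, 0.9))
  idx <- unique(vapply(times, function(t) which.min(abs(object$time - t)),
                       integer(1)))
  df <- do.call(rbind, lapply(idx, function(i) {
    data.frame(x = object$x, v = object$v[i, ],
               t = sprintf("%.1f ms", object$time[i]))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$v,
                                   colour = .data$t)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position (mm)", y = "v (mV)", colour = "time") +
    ggplot2::theme_minimal()
}

#' Plot a conduction-velocity vs coupling sweep
#'
#' @param tab output of [cv_beta_sweep()] (possibly several row-bound
#'   sweeps with distinct `model`/`direction`).
#' @return a ggplot object (log-x, CV in cm/s; blocked rows are dropped).
#' @export
plot_cv_beta <- function(tab) {
  df <- tab[!tab$blocked & !is.na(tab$cv), , drop = FALSE]
  df$series <- paste(df$model, df$direction)
  ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$beta, y = .data$cv,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "gap-junctional coupling (%)", y = "CV (cm/s)") +
    ggplot2::theme_minimal()
}

#' Plot an effective-conductivity map
#'
#' @param object a `sigma_map` from [sigma_table()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sigma_map <- function(object, ...) {
  df <- sigma_map_tbl(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y_mV_per_mm,
                                   y = .data$sigma_mS_per_mm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "potential gradient (mV/mm)",
                  y = "effective conductivity (mS/mm)") +
    ggplot2::theme_minimal()
}

#' Write an effective-conductivity table as CSV
#'
#' @param map a `sigma_map`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sigma_csv <- function(map, path) {
  utils::write.csv(sigma_map_tbl(map), path, row.names = FALSE)
  invisible(path)
}
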