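utils::globalVariables(c("time_s", "count", "kind", "ili_s", "size",
                         "bin_start_s", "time", "value", "variable"))

#' Plot the cumulative record of a session
#'
#' @param record A [session_record()].
#' @return A ggplot object.
#' @export
plot_cumulative_record <- function(record) {
  cr <- cumulative_record(record)
  ggplot2::ggplot(cr, ggplot2::aes(x = time_s / 60, y = count, colour = kind)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Time (min)", y = "Cumulative count", colour = NULL,
                  title = sprintf("Subject %s, %s", record$subject_tag,
                                  format(record$schedule, compact = TRUE))) +
    ggplot2::theme_classic()
}

#' Histogram of within-cluster inter-lick intervals
#'
#' @param clusters Clusters from [segment_clusters()].
#' @param binwidth Histogram bin width, seconds.
#' @return A ggplot object.
#' @export
plot_ili_histogram <- function(clusters, binwidth = 0.01) {
  ilis <- unlist(lapply(clusters, function(cl) cl$ilis), use.names = FALSE)
  df <- tibble::tibble(ili_s = ilis)
  ggplot2::ggplot(df, ggplot2::aes(x = ili_s)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "Inter-lick interval (s)", y = "Count") +
    ggplot2::theme_classic()
}

#' Histogram of lick-cluster sizes
#'
#' @inheritParams plot_ili_histogram
#' @param binwidth Bin width in licks.
#' @return A ggplot object.
#' @export
plot_cluster_size_histogram <- function(clusters, binwidth = 5) {
  df <- tibble::tibble(size = vapply(clusters, function(cl) cl$size, 0L))
  ggplot2::ggplot(df, ggplot2::aes(x = size)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0) +
    ggplot2::labs(x = "Cluster size (licks)", y = "Count") +
    ggplot2::theme_classic()
}

#' Plot binned motion activity
#'
#' @param bins Output of [bin_activity()].
#' @return A ggplot object.
#' @export
plot_activity_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = bin_start_s / 60, y = count)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::labs(x = "Time (min)", y = "Motion events / bin") +
    ggplot2::theme_classic()
}

#' Plot an environmental sensor series
#'
#' Four stacked panels: temperature, humidity, pressure, lux.
#'
#' @param series Env tibble from [simulate_env()] or [read_env_log()].
#' @return A ggplot object.
#' @export
plot_env_series <- function(series) {
  long <- do.call(rbind, lapply(ENV_VARS, function(v) {
    tibble::tibble(time = series$time, variable = v, value = series[[v]])
  }))
  long$variable <- factor(long$variable, levels = ENV_VARS)
  ggplot2::ggplot(long, ggplot2::aes(x = time, y = value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(variable), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_classic()
}
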