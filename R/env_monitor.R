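#' Environmental simulation parameters
#'
#' Baselines, noise and events for the simulated animal-room sensor trace:
#' temperature (deg C), relative humidity (%), barometric pressure (kPa)
#' and illuminance (lux) sampled every 10 minutes. Lighting follows a
#' reverse light cycle by default (lights off at 09:00, on at 21:00).
#' Optional features emulate what real housing-room traces show: brief
#' lux spikes when technicians enter during the dark phase, and a step
#' change in temperature/humidity at a configurable changepoint (such as
#' an airflow adjustment).
#'
#' @param temperature_c,humidity_pct,pressure_kpa Baseline levels.
#' @param lux_on,lux_off Illuminance when lights are on / off.
#' @param lights_off_hour,lights_on_hour Clock hours (0-24) at which the
#'   room lights switch off and on. Defaults 9 and 21 (reverse cycle).
#' @param temperature_sd,humidity_sd,pressure_sd,lux_sd Gaussian sensor
#'   noise SDs.
#' @param spike_rate_per_day Mean number of technician-entry lux spikes
#'   per day (single-sample spikes during the dark phase).
#' @param spike_lux Illuminance during a spike.
#' @param changepoint_s Optional time offset (seconds from series start)
#'   at which the step change occurs; `NULL` for none.
#' @param temperature_step,humidity_step Step sizes applied from
#'   `changepoint_s` onward.
#' @return An object of class `env_params`.
#' @export
env_params <- function(temperature_c = 22, humidity_pct = 45,
                       pressure_kpa = 101.3, lux_on = 200, lux_off = 0,
                       lights_off_hour = 9, lights_on_hour = 21,
                       temperature_sd = 0.1, humidity_sd = 0.5,
                       pressure_sd = 0.05, lux_sd = 2,
                       spike_rate_per_day = 0, spike_lux = 150,
                       changepoint_s = NULL, temperature_step = 0,
                       humidity_step = 0) {
  stopifnot(
    humidity_pct >= 0, humidity_pct <= 100, pressure_kpa > 0,
    lux_on >= 0, lux_off >= 0,
    lights_off_hour >= 0, lights_off_hour < 24,
    lights_on_hour >= 0, lights_on_hour < 24,
    temperature_sd >= 0, humidity_sd >= 0, pressure_sd >= 0, lux_sd >= 0,
    spike_rate_per_day >= 0
  )
  structure(
    list(temperature_c = temperature_c, humidity_pct = humidity_pct,
         pressure_kpa = pressure_kpa, lux_on = lux_on, lux_off = lux_off,
         lights_off_hour = lights_off_hour, lights_on_hour = lights_on_hour,
         temperature_sd = temperature_sd, humidity_sd = humidity_sd,
         pressure_sd = pressure_sd, lux_sd = lux_sd,
         spike_rate_per_day = spike_rate_per_day, spike_lux = spike_lux,
         changepoint_s = changepoint_s,
         temperature_step = temperature_step, humidity_step = humidity_step),
    class = "env_params"
  )
}

#' Simulate an environmental sensor series
#'
#' Produces 144 samples per day (10-min cadence): square-wave illuminance
#' on the configured light cycle, flat climate baselines with Gaussian
#' sensor noise, optional technician-entry lux spikes and an optional step
#' change in temperature/humidity.
#'
#' @param days Number of days, `>= 1`.
#' @param params An [env_params()].
#' @param seed Integer seed.
#' @param start Absolute time of the first sample (`POSIXct`, midnight by
#'   default).
#' @return Tibble with columns `time`, `temperature_c`, `humidity_pct`,
#'   `pressure_kpa`, `lux`.
#' @examples
#' env <- simulate_env(1, env_params(temperature_sd = 0, lux_sd = 0), seed = 1)
#' nrow(env)          # 144
#' unique(env$lux)    # two-valued square wave
#' @export
simulate_env <- function(days, params = env_params(), seed = 1,
                         start = as.POSIXct("2016-07-01 00:00:00", tz = "UTC")) {
  stopifnot(inherits(params, "env_params"), days >= 1)
  old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_rng)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_rng, envir = globalenv())
  })
  set.seed(as.integer(seed))

  n <- as.integer(round(days * 144))
  offset_s <- (seq_len(n) - 1L) * 600
  time <- start + offset_s
  hour <- (as.numeric(start) %% 86400 + offset_s) %% 86400 / 3600

  off_h <- params$lights_off_hour
  on_h <- params$lights_on_hour
  # dark phase spans [off_h, on_h) on the clock, wrapping midnight if needed
  dark <- if (off_h <= on_h) hour >= off_h & hour < on_h
          else hour >= off_h | hour < on_h
  lux <- ifelse(dark, params$lux_off, params$lux_on)

  if (params$spike_rate_per_day > 0) {
    n_spikes <- stats::rpois(1, params$spike_rate_per_day * days)
    dark_idx <- which(dark)
    if (n_spikes > 0 && length(dark_idx)) {
      at <- sample(dark_idx, min(n_spikes, length(dark_idx)))
      lux[at] <- params$spike_lux
    }
  }

  temp <- rep(params$temperature_c, n)
  hum <- rep(params$humidity_pct, n)
  if (!is.null(params$changepoint_s)) {
    after <- offset_s >= params$changepoint_s
    temp[after] <- temp[after] + params$temperature_step
    hum[after] <- hum[after] + params$humidity_step
  }
  tibble::tibble(
    time = time,
    temperature_c = temp + stats::rnorm(n, 0, params$temperature_sd),
    humidity_pct = pmin(100, pmax(0, hum + stats::rnorm(n, 0, params$humidity_sd))),
    pressure_kpa = params$pressure_kpa + stats::rnorm(n, 0, params$pressure_sd),
    lux = pmax(0, lux + stats::rnorm(n, 0, params$lux_sd))
  )
}

#' Write / read an environmental log CSV
#'
#' Plain CSV with header `time_iso,temperature_c,humidity_pct,pressure_kpa,lux`,
#' one row per 10-min sample, times in ISO-8601 UTC.
#'
#' @param series Env tibble as produced by [simulate_env()].
#' @param path File path.
#' @return `path` (write) or the parsed tibble (read).
#' @export
write_env_log <- function(series, path) {
  lines <- c(
    "time_iso,temperature_c,humidity_pct,pressure_kpa,lux",
    sprintf("%s,%.4f,%.4f,%.4f,%.4f",
            format(series$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
            series$temperature_c, series$humidity_pct,
            series$pressure_kpa, series$lux)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' @rdname write_env_log
#' @export
read_env_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_iso", "temperature_c", "humidity_pct", "pressure_kpa", "lux")
  if (!all(need %in% names(df))) {
    stop("environmental log must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  tibble::tibble(
    time = as.POSIXct(df$time_iso, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    temperature_c = df$temperature_c, humidity_pct = df$humidity_pct,
    pressure_kpa = df$pressure_kpa, lux = df$lux
  )
}

ENV_VARS <- c("temperature_c", "humidity_pct", "pressure_kpa", "lux")

#' Compare two co-located environmental devices
#'
#' Pairs samples from two series by nearest timestamp (within `max_gap_s`)
#' and reports the mean and SD of the paired differences `a - b` for each
#' variable, the standard check that two sensor sets placed side by side
#' agree.
#'
#' @param series_a,series_b Env tibbles sharing (approximately) the same
#'   sampling times.
#' @param max_gap_s Maximum timestamp mismatch for a pair, seconds
#'   (default 300, half the nominal cadence).
#' @return Tibble with `variable`, `mean_diff`, `sd_diff`, `n`.
#' @export
compare_devices <- function(series_a, series_b, max_gap_s = 300) {
  ta <- as.numeric(series_a$time); tb <- as.numeric(series_b$time)
  idx <- findInterval(ta, tb)
  cand_lo <- pmax(idx, 1L)
  cand_hi <- pmin(idx + 1L, length(tb))
  d_lo <- abs(ta - tb[cand_lo]); d_hi <- abs(ta - tb[cand_hi])
  nearest <- ifelse(d_lo <= d_hi, cand_lo, cand_hi)
  gap <- pmin(d_lo, d_hi)
  ok <- gap <= max_gap_s
  if (sum(ok) < 2L) {
    stop("series share fewer than 2 alignable timestamps", call. = FALSE)
  }
  rows <- lapply(ENV_VARS, function(v) {
    d <- series_a[[v]][ok] - series_b[[v]][nearest[ok]]
    tibble::tibble(variable = v, mean_diff = mean(d),
                   sd_diff = stats::sd(d), n = length(d))
  })
  do.call(rbind, rows)
}

#' Detect light-cycle transitions from the lux trace
#'
#' Classifies each sample as light or dark against a threshold and reports
#' the state changes. A change of state only registers once it persists
#' for `debounce` consecutive samples, so single-sample technician-entry
#' spikes are ignored; the transition is timed at the first sample of the
#' new state.
#'
#' @param series Env tibble, time-sorted.
#' @param lux_threshold Absolute threshold; by default the midpoint of the
#'   5th and 95th percentiles of the lux trace (the sensor is uncalibrated,
#'   so only relative level matters).
#' @param debounce Consecutive samples required to accept a state change.
#' @return Tibble with `time` and `direction` (`"on"`/`"off"`),
#'   alternating; empty for a constant series.
#' @export
detect_light_transitions <- function(series, lux_threshold = NULL, debounce = 2L) {
  lux <- series$lux
  if (length(lux) == 0L) {
    return(tibble::tibble(time = series$time[0], direction = character(0)))
  }
  if (is.null(lux_threshold)) {
    q <- stats::quantile(lux, c(0.05, 0.95), names = FALSE, type = 7)
    lux_threshold <- mean(q)
  }
  above <- lux >= lux_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  state <- r$values[1]
  t_out <- numeric(0); d_out <- character(0)
  for (j in seq_along(r$values)) {
    if (r$values[j] != state && r$lengths[j] >= debounce) {
      state <- r$values[j]
      t_out <- c(t_out, as.numeric(series$time[starts[j]]))
      d_out <- c(d_out, if (state) "on" else "off")
    }
  }
  tibble::tibble(
    time = as.POSIXct(t_out, origin = "1970-01-01", tz = "UTC"),
    direction = d_out
  )
}

#' Estimate a single step change in an environmental variable
#'
#' Least-squares single-changepoint fit: the split minimizing the total
#' within-segment sum of squares. Returns the changepoint time (first
#' sample of the post-change segment) and the step size (mean after minus
#' mean before).
#'
#' @param series Env tibble.
#' @param variable One of `"temperature_c"`, `"humidity_pct"`,
#'   `"pressure_kpa"`, `"lux"`.
#' @param min_segment Minimum samples on each side of the split.
#' @return List with `time`, `step`, `index`, `mean_before`, `mean_after`.
#' @export
estimate_changepoint <- function(series, variable = "temperature_c",
                                 min_segment = 6L) {
  stopifnot(variable %in% ENV_VARS)
  x <- series[[variable]]
  n <- length(x)
  if (n < 2L * min_segment) {
    stop("series too short for changepoint estimation", call. = FALSE)
  }
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ks <- seq(min_segment, n - min_segment)  # last index of the 'before' segment
  s1 <- cs[ks]; n1 <- ks
  s2 <- cs[n] - s1; n2 <- n - n1
  rss <- (cs2[n]) - s1^2 / n1 - s2^2 / n2
  k <- ks[which.min(rss)]
  list(
    time = series$time[k + 1L],
    step = mean(x[(k + 1L):n]) - mean(x[1:k]),
    index = k + 1L,
    mean_before = mean(x[1:k]),
    mean_after = mean(x[(k + 1L):n])
  )
}
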