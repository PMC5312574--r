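#' Segment lick times into clusters
#'
#' A lick cluster (burst) is a maximal run of licks in which every
#' consecutive inter-lick interval is strictly below the threshold
#' (default 0.5 s); runs of fewer than two licks are excluded. A gap of
#' exactly the threshold splits (the strict-`<` convention).
#'
#' @param lick_times Non-decreasing numeric vector of lick times, seconds.
#' @param threshold_s Positive segmentation threshold, seconds. Default 0.5.
#' @param spout Optional label (`"active"`/`"inactive"`) stamped on each
#'   cluster. Spouts are segmented independently: segment each spout's
#'   licks separately rather than the merged stream.
#' @return List of `lick_cluster` objects, each with fields `spout`,
#'   `lick_times`, `size` and `ilis` (the `size - 1` within-cluster gaps).
#' @examples
#' segment_clusters(c(0, 0.1, 0.2, 1.0, 1.4, 5.0))
#' # two clusters (sizes 3 and 2); the isolated lick at 5.0 is excluded
#' @export
segment_clusters <- function(lick_times, threshold_s = 0.5, spout = NA_character_) {
  stopifnot(is.numeric(lick_times), length(threshold_s) == 1L, threshold_s > 0)
  if (is.unsorted(lick_times)) {
    stop("lick times must be non-decreasing", call. = FALSE)
  }
  n <- length(lick_times)
  if (n < 2L) return(list())
  new_run <- c(TRUE, diff(lick_times) >= threshold_s)
  run_id <- cumsum(new_run)
  runs <- split(lick_times, run_id)
  runs <- runs[lengths(runs) >= 2L]
  lapply(unname(runs), function(v) {
    structure(list(spout = spout, lick_times = v, size = length(v),
                   ilis = diff(v)),
              class = "lick_cluster")
  })
}

#' @export
print.lick_cluster <- function(x, ...) {
  cat(sprintf("<lick_cluster> %d licks over %.3f s (spout %s)\n",
              x$size, diff(range(x$lick_times)), x$spout))
  invisible(x)
}

#' Summarize lick microstructure
#'
#' Mean and SEM of cluster sizes and of within-cluster inter-lick
#' intervals over a set of clusters from one spout. ILIs are pooled across
#' clusters by default (a single grand mean over all within-cluster gaps);
#' `ili_mode = "per_cluster"` instead averages per-cluster ILI means.
#'
#' @param clusters List of clusters from [segment_clusters()].
#' @param total_licks Optional total lick count on the spout (counting
#'   licks excluded from clusters); recorded in the summary.
#' @param ili_mode `"pooled"` (default) or `"per_cluster"`.
#' @return One-row tibble: `n_clusters`, `mean_cluster_size`,
#'   `sem_cluster_size`, `mean_ili_s`, `sem_ili_s`, `total_licks`,
#'   `empty` (TRUE when there are no clusters so the means are undefined).
#' @export
summarize_microstructure <- function(clusters, total_licks = NA_integer_,
                                     ili_mode = c("pooled", "per_cluster")) {
  ili_mode <- match.arg(ili_mode)
  sizes <- vapply(clusters, function(cl) cl$size, 0L)
  n <- length(sizes)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  if (n == 0L) {
    return(tibble::tibble(
      n_clusters = 0L, mean_cluster_size = NA_real_, sem_cluster_size = NA_real_,
      mean_ili_s = NA_real_, sem_ili_s = NA_real_,
      total_licks = as.integer(total_licks), empty = TRUE
    ))
  }
  ilis <- if (ili_mode == "pooled") {
    unlist(lapply(clusters, function(cl) cl$ilis), use.names = FALSE)
  } else {
    vapply(clusters, function(cl) mean(cl$ilis), 0)
  }
  tibble::tibble(
    n_clusters = n,
    mean_cluster_size = mean(sizes),
    sem_cluster_size = sem(sizes),
    mean_ili_s = mean(ilis),
    sem_ili_s = sem(ilis),
    total_licks = as.integer(total_licks),
    empty = FALSE
  )
}

#' Per-spout microstructure analysis of a session
#'
#' Segments each spout's licks independently and summarizes both.
#'
#' @param record A [session_record()] (or event tibble).
#' @param threshold_s Segmentation threshold, seconds.
#' @param ili_mode Passed to [summarize_microstructure()].
#' @return Two-row tibble (active, inactive) with a `spout` column ahead
#'   of the [summarize_microstructure()] columns.
#' @export
analyze_licks <- function(record, threshold_s = 0.5,
                          ili_mode = c("pooled", "per_cluster")) {
  ili_mode <- match.arg(ili_mode)
  events <- if (inherits(record, "session_record")) record$events else record
  out <- lapply(c(active = "lick_active", inactive = "lick_inactive"), function(k) {
    times <- events$time_s[events$kind == k]
    cl <- segment_clusters(times, threshold_s,
                           spout = if (k == "lick_active") "active" else "inactive")
    summarize_microstructure(cl, total_licks = length(times), ili_mode = ili_mode)
  })
  res <- do.call(rbind, out)
  tibble::add_column(res, spout = c("active", "inactive"), .before = 1L)
}

#' One-row session summary
#'
#' Lick and reward counts for a session, the per-animal row behind
#' group-level summaries of responding.
#'
#' @param record A [session_record()].
#' @return One-row tibble: `subject_tag`, `schedule`, `licks_active`,
#'   `licks_inactive`, `rewards`.
#' @export
session_summary <- function(record) {
  stopifnot(inherits(record, "session_record"))
  k <- record$events$kind
  tibble::tibble(
    subject_tag = record$subject_tag,
    schedule = format(record$schedule, compact = TRUE),
    licks_active = sum(k == "lick_active"),
    licks_inactive = sum(k == "lick_inactive"),
    rewards = record$rewards
  )
}

#' Cumulative record of a session
#'
#' The classic operant visualization: running counts of active licks,
#' inactive licks and rewards against session time. Each series starts at
#' (0, 0) and ends at (session end, total), so its endpoint equals the
#' [session_summary()] count.
#'
#' @param record A [session_record()].
#' @param kinds Event kinds to accumulate.
#' @return Tibble with columns `kind`, `time_s`, `count` (step function,
#'   monotone non-decreasing within each kind).
#' @export
cumulative_record <- function(record,
                              kinds = c("lick_active", "lick_inactive", "reward")) {
  stopifnot(inherits(record, "session_record"))
  ev <- record$events
  end_t <- ev$time_s[nrow(ev)]
  out <- lapply(kinds, function(k) {
    t <- ev$time_s[ev$kind == k]
    tibble::tibble(
      kind = k,
      time_s = c(0, t, end_t),
      count = c(0L, seq_along(t), length(t))
    )
  })
  do.call(rbind, out)
}

#' Bin motion activity into fixed windows
#'
#' Counts motion events in half-open bins `[k*bin_s, (k+1)*bin_s)` across
#' the session (an event exactly at the session end falls in the last
#' bin). The default 60 s bin matches the conventional 1-min activity
#' trace.
#'
#' @param motion_times Numeric event times within `[0, session_s]`.
#' @param bin_s Bin width, seconds. Default 60.
#' @param session_s Session length, seconds.
#' @return Tibble with `bin_start_s` and `count`; `sum(count)` equals
#'   `length(motion_times)`.
#' @export
bin_activity <- function(motion_times, bin_s = 60, session_s) {
  stopifnot(bin_s > 0, session_s > 0)
  if (length(motion_times) && (min(motion_times) < 0 || max(motion_times) > session_s)) {
    stop("motion times must lie within [0, session_s]", call. = FALSE)
  }
  n_bins <- ceiling(session_s / bin_s)
  idx <- pmin(floor(motion_times / bin_s) + 1L, n_bins)
  tibble::tibble(
    bin_start_s = (seq_len(n_bins) - 1L) * bin_s,
    count = tabulate(idx, nbins = n_bins)
  )
}

#' Compare active vs inactive responding across subjects
#'
#' Two-sample Student's t-test (pooled variance, two-sided) on per-subject
#' values, with the conventional significance stars: `*` for p < 0.05,
#' `**` for p < 0.01, `***` for p < 0.001.
#'
#' @param group_active Numeric vector, one value per subject.
#' @param group_inactive Numeric vector, one value per subject.
#' @return List with `t`, `df`, `p`, `stars`, `mean_active`,
#'   `mean_inactive`.
#' @examples
#' compare_spouts(c(101, 98, 112), c(3, 7, 2))
#' @export
compare_spouts <- function(group_active, group_inactive) {
  n1 <- length(group_active); n2 <- length(group_inactive)
  if (n1 < 2L || n2 < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  m1 <- mean(group_active); m2 <- mean(group_inactive)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1L) * stats::var(group_active) +
          (n2 - 1L) * stats::var(group_inactive)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  if (se == 0) {
    tval <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
  } else {
    tval <- (m1 - m2) / se
  }
  p <- 2 * stats::pt(-abs(tval), df)
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
  list(t = tval, df = df, p = p, stars = stars,
       mean_active = m1, mean_inactive = m2)
}
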