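# Independent reference implementations used to cross-check the package.
# These are deliberately written in a different style from the package
# code (plain accumulating loops, no shared helpers) so agreement between
# the two routes is informative.

# Single-pass replay of a reinforcement schedule over a raw input stream.
# Returns the reward times (relative to the leading scan) and the session
# end time. For VR the requirement sequence must be supplied explicitly
# via spec$vr_draws so that both routes see the same draws.
replay_oracle <- function(stream, spec) {
  rel <- stream$time_s - stream$time_s[1]
  active <- rel[stream$kind == "lick_active"]
  if (spec$family != "PR") active <- active[active < spec$session_s]

  draws_used <- 0
  requirement_now <- function(n_rewards) {
    if (spec$family == "FR") return(spec$ratio)
    if (spec$family == "PR") return(spec$ratio + n_rewards * spec$pr_step)
    draws_used <<- draws_used + 1
    spec$vr_draws[((draws_used - 1) %% length(spec$vr_draws)) + 1]
  }

  rewards <- c()
  need <- requirement_now(0)
  counted <- 0
  blocked_before <- -Inf
  for (tt in active) {
    if (tt < blocked_before) next
    counted <- counted + 1
    if (counted >= need) {
      rewards <- c(rewards, tt)
      blocked_before <- tt + spec$timeout_s
      counted <- 0
      need <- requirement_now(length(rewards))
    }
  }
  end_t <- if (spec$family == "PR") {
    la <- active[length(active)]
    (if (length(active)) la else 0) + spec$pr_idle_stop_s
  } else {
    spec$session_s
  }
  list(reward_times = as.numeric(rewards), end_time = end_t)
}

# Naive lick-cluster segmentation: grows clusters one lick at a time.
naive_segment <- function(times, threshold = 0.5) {
  clusters <- list()
  current <- c()
  for (tt in times) {
    if (length(current) == 0) {
      current <- tt
    } else if (tt - current[length(current)] < threshold) {
      current <- c(current, tt)
    } else {
      if (length(current) >= 2) clusters[[length(clusters) + 1]] <- current
      current <- tt
    }
  }
  if (length(current) >= 2) clusters[[length(clusters) + 1]] <- current
  clusters
}

# Random raw input stream: leading scan plus mixed licks and motion.
random_stream <- function(n_licks, mean_gap = 0.3, tag = "0A1B2C3D4E5F") {
  gaps <- stats::rexp(n_licks, 1 / mean_gap)
  times <- cumsum(gaps)
  kind <- sample(c("lick_active", "lick_inactive", "motion"), n_licks,
                 replace = TRUE, prob = c(0.7, 0.2, 0.1))
  events_frame(
    time_s = c(0, times),
    kind = c("rfid_scan", kind),
    tag = c(tag, rep(NA_character_, n_licks))
  )
}

# Random schedule spec covering all three families.
random_spec <- function() {
  fam <- sample(c("FR", "VR", "PR"), 1)
  schedule_spec(
    family = fam,
    ratio = sample(1:20, 1),
    pr_step = sample(1:10, 1),
    timeout_s = stats::runif(1, 0, 30),
    cue_s = stats::runif(1, 0, 10),
    session_s = stats::runif(1, 30, 600),
    pr_idle_stop_s = stats::runif(1, 60, 600),
    vr_draws = if (fam == "VR") sample(1:19, sample(3:12, 1), replace = TRUE)
  )
}

reward_times_of <- function(record) {
  record$events$time_s[record$events$kind == "reward"]
}
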