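#' Draw a variable-ratio requirement
#'
#' VR schedules reward after a randomly chosen number of counted licks with
#' a predetermined average. The draw is uniform on the integers
#' `{1, ..., 2*mean - 1}`, which has expectation exactly `mean`, bounded
#' support and minimum 1. Draws come from R's current RNG stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param mean Positive integer mean requirement.
#' @param n Number of draws.
#' @return Integer vector of length `n`.
#' @examples
#' set.seed(1)
#' vr_draw_requirement(10, n = 5)
#' vr_draw_requirement(1)  # degenerate: always 1
#' @export
vr_draw_requirement <- function(mean, n = 1L) {
  mean <- as.integer(mean)
  if (length(mean) != 1L || is.na(mean) || mean < 1L) {
    stop("VR mean must be a positive integer", call. = FALSE)
  }
  sample.int(2L * mean - 1L, n, replace = TRUE)
}

#' Progressive-ratio requirement for the k-th reward
#'
#' The PR requirement grows arithmetically: the k-th reward requires
#' `ratio + (k - 1) * pr_step` counted licks, so with the defaults (base 10,
#' step 5) the sequence is 10, 15, 20, ... The final requirement an animal
#' completes before the session times out is its break point.
#'
#' @param k Reward index, an integer (vector) `>= 1`.
#' @param spec A [schedule_spec()] (its `ratio` and `pr_step` are used).
#' @return Integer vector of requirements.
#' @examples
#' pr_requirement(1:4, schedule_spec("PR", ratio = 10, pr_step = 5))
#' @export
pr_requirement <- function(k, spec) {
  stopifnot(inherits(spec, "schedule_spec"))
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L)) {
    stop("reward index k must be >= 1", call. = FALSE)
  }
  spec$ratio + (k - 1L) * spec$pr_step
}

# Requirement in force after `rewards` rewards have been delivered.
next_requirement <- function(spec, rewards, draw_fun) {
  switch(spec$family,
    FR = spec$ratio,
    VR = draw_fun(),
    PR = pr_requirement(rewards + 1L, spec)
  )
}

#' Create a fresh schedule state
#'
#' The mutable state threaded through [schedule_on_lick()]: the lick
#' counter, the requirement currently in force, the number of rewards
#' delivered, the end of any running timeout, and (for VR) a private RNG
#' state so that requirement draws are reproducible and isolated from the
#' global RNG.
#'
#' @param spec A [schedule_spec()].
#' @param seed Integer seed for VR requirement draws. Required for VR
#'   unless `spec$vr_draws` supplies an explicit sequence; ignored
#'   otherwise.
#' @return An object of class `schedule_state`.
#' @export
new_schedule_state <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "schedule_spec"))
  st <- list(
    licks_toward_requirement = 0L,
    current_requirement = NA_integer_,
    rewards_delivered = 0L,
    timeout_until = NA_real_,
    last_active_lick_at = NA_real_,
    last_time = -Inf,
    draw_index = 0L,
    rng_state = NULL
  )
  class(st) <- "schedule_state"
  if (spec$family == "VR" && is.null(spec$vr_draws)) {
    if (is.null(seed)) {
      stop("VR schedules need a seed (or an explicit vr_draws sequence)",
           call. = FALSE)
    }
    st$rng_state <- local_rng_state(as.integer(seed))
  }
  draw <- make_draw_fun(st, spec)
  st <- draw$state
  st$current_requirement <- next_requirement(spec, 0L, draw$fn)
  st <- draw$collect(st)
  st
}

# Captures a .Random.seed vector for an isolated stream seeded with `seed`.
local_rng_state <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  get(".Random.seed", globalenv())
}

# Builds a draw function bound to a schedule state's private RNG stream or
# explicit vr_draws list. Returns the (possibly updated) state, the draw
# closure, and a collector that writes the advanced RNG state back.
make_draw_fun <- function(st, spec) {
  if (spec$family != "VR") {
    return(list(state = st, fn = function() NA_integer_,
                collect = function(s) s))
  }
  if (!is.null(spec$vr_draws)) {
    env <- new.env(parent = emptyenv())
    env$i <- st$draw_index
    fn <- function() {
      env$i <- env$i + 1L
      spec$vr_draws[[((env$i - 1L) %% length(spec$vr_draws)) + 1L]]
    }
    collect <- function(s) { s$draw_index <- env$i; s }
    return(list(state = st, fn = fn, collect = collect))
  }
  env <- new.env(parent = emptyenv())
  env$rng <- st$rng_state
  fn <- function() {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$rng, envir = globalenv())
    val <- vr_draw_requirement(spec$ratio, 1L)
    env$rng <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    val
  }
  collect <- function(s) { s$rng_state <- env$rng; s }
  list(state = st, fn = fn, collect = collect)
}

#' Advance a schedule state by one active-spout lick
#'
#' Applies one lick at time `t` to the schedule: licks inside the
#' post-reward timeout window `[reward_t, reward_t + timeout_s)` are logged
#' but not counted; a lick landing exactly at the end of the window counts.
#' Counted licks increment the counter; when it reaches the requirement a
#' reward is issued, the counter resets, the timeout starts, and (VR/PR)
#' the next requirement is drawn or incremented. The reward-triggering
#' lick itself is included in the requirement count.
#'
#' @param state A [new_schedule_state()].
#' @param t Lick time in seconds; must be `>=` the previous event time.
#' @param spec The [schedule_spec()] the state was created for.
#' @return A list with elements `state` (updated) and `reward` (logical).
#' @seealso [fr_on_lick()], [vr_on_lick()] for family-checked wrappers.
#' @export
schedule_on_lick <- function(state, t, spec) {
  stopifnot(inherits(state, "schedule_state"), inherits(spec, "schedule_spec"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t)) {
    stop("lick time must be a single number", call. = FALSE)
  }
  if (t < state$last_time) {
    stop(sprintf("non-monotone lick time: %g after %g", t, state$last_time),
         call. = FALSE)
  }
  state$last_time <- t
  state$last_active_lick_at <- t
  in_timeout <- !is.na(state$timeout_until) && t < state$timeout_until
  reward <- FALSE
  if (!in_timeout) {
    state$licks_toward_requirement <- state$licks_toward_requirement + 1L
    if (state$licks_toward_requirement >= state$current_requirement) {
      reward <- TRUE
      state$rewards_delivered <- state$rewards_delivered + 1L
      state$licks_toward_requirement <- 0L
      state$timeout_until <- t + spec$timeout_s
      draw <- make_draw_fun(state, spec)
      state <- draw$state
      state$current_requirement <-
        next_requirement(spec, state$rewards_delivered, draw$fn)
      state <- draw$collect(state)
    }
  }
  list(state = state, reward = reward)
}

#' @rdname schedule_on_lick
#' @export
fr_on_lick <- function(state, t, spec) {
  if (spec$family != "FR") stop("spec is not a fixed-ratio schedule", call. = FALSE)
  schedule_on_lick(state, t, spec)
}

#' @rdname schedule_on_lick
#' @export
vr_on_lick <- function(state, t, spec) {
  if (spec$family != "VR") stop("spec is not a variable-ratio schedule", call. = FALSE)
  schedule_on_lick(state, t, spec)
}

#' Run a full operant session over an input event stream
#'
#' The session controller consumes a time-ordered stream of raw input
#' events (licks on either spout, motion, RFID scans) and produces the
#' complete session log the acquisition system would have written. The
#' session timer starts at the leading RFID scan: a `session_start` event
#' is emitted at the scan time and all logged times are relative to it.
#' Active-spout licks drive the reinforcement schedule; inactive-spout
#' licks and motion are logged with no programmed consequence. Each reward
#' appends `reward` and `cue_on` events at the reward time and a `cue_off`
#' event `cue_s` later (truncated at session end). FR/VR sessions end at
#' `session_s`, with later input discarded; PR sessions end
#' `pr_idle_stop_s` after the last active-spout lick.
#'
#' @param input_events Event tibble (see [events_frame()]) whose first row
#'   is an `rfid_scan`; only `lick_active`, `lick_inactive`, `motion` and
#'   `rfid_scan` kinds are accepted as input.
#' @param spec A [schedule_spec()]; if `NULL` it is resolved from the
#'   leading scan's tag via `map`.
#' @param map Optional [rfid_schedule_map()] used when `spec` is `NULL`.
#' @param seed Integer seed for VR requirement draws (required for VR
#'   without `vr_draws`); recorded in the returned record.
#' @param start_time Absolute session start time (`POSIXct`).
#' @return A [session_record()].
#' @examples
#' stream <- events_frame(
#'   time_s = c(0, 1:12 * 0.2),
#'   kind = c("rfid_scan", rep("lick_active", 12)),
#'   tag = c("0A1B2C3D4E5F", rep(NA, 12))
#' )
#' rec <- run_session(stream, schedule_spec("FR", 10, timeout_s = 20))
#' rec$rewards  # 1: the 10th counted lick triggered the pump
#' @export
run_session <- function(input_events, spec = NULL, map = NULL, seed = NULL,
                        start_time = as.POSIXct("2016-07-01 09:00:00", tz = "UTC")) {
  stopifnot(is.data.frame(input_events))
  ev <- input_events
  if (nrow(ev) == 0L || ev$kind[1] != "rfid_scan") {
    stop("input stream must begin with an rfid_scan (session start trigger)",
         call. = FALSE)
  }
  allowed <- c("lick_active", "lick_inactive", "motion", "rfid_scan")
  bad <- which(!(ev$kind %in% allowed))
  if (length(bad)) {
    stop(sprintf("input event %d has kind '%s'; only raw input kinds %s are accepted",
                 bad[1], ev$kind[bad[1]], paste(allowed, collapse = "/")),
         call. = FALSE)
  }
  if (is.unsorted(ev$time_s)) {
    bad <- which(diff(ev$time_s) < 0)[1] + 1L
    stop(sprintf("input events out of order at event %d", bad), call. = FALSE)
  }
  subject_tag <- toupper(ev$tag[1])
  if (!isTRUE(validate_tag(subject_tag))) {
    stop("leading rfid_scan must carry a valid 12-hex tag", call. = FALSE)
  }
  if (is.null(spec)) {
    spec <- resolve_schedule(subject_tag, map %||% rfid_schedule_map())
  }

  n <- nrow(ev)
  t0 <- ev$time_s[1]
  times <- ev$time_s - t0
  kinds <- ev$kind
  tags <- ev$tag

  # VR draws use an isolated RNG stream restored on exit
  use_rng <- spec$family == "VR" && is.null(spec$vr_draws)
  if (use_rng && is.null(seed)) {
    stop("VR sessions need a seed (or an explicit vr_draws sequence)",
         call. = FALSE)
  }
  old_rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  if (use_rng) {
    on.exit({
      if (is.null(old_rng)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old_rng, envir = globalenv())
    })
    set.seed(seed)
  }
  vr_i <- 0L
  draw_req <- function() {
    if (spec$family == "FR") return(spec$ratio)
    if (spec$family == "PR") return(pr_requirement(n_rewards + 1L, spec))
    if (!is.null(spec$vr_draws)) {
      vr_i <<- vr_i + 1L
      return(spec$vr_draws[[((vr_i - 1L) %% length(spec$vr_draws)) + 1L]])
    }
    vr_draw_requirement(spec$ratio, 1L)
  }

  fixed_len <- spec$family != "PR"
  cap <- 4L * n + 8L
  out_t <- numeric(cap); out_k <- character(cap); out_g <- rep(NA_character_, cap)
  m <- 0L
  emit <- function(t, k, g = NA_character_) {
    m <<- m + 1L
    out_t[m] <<- t; out_k[m] <<- k; out_g[m] <<- g
  }

  pend_cue <- numeric(0)  # pending cue_off times, ascending
  count <- 0L
  n_rewards <- 0L
  timeout_until <- -Inf
  last_active <- NA_real_
  requirement <- draw_req()

  emit(0, "session_start")
  for (i in seq_len(n)) {
    t <- times[i]
    if (fixed_len && t >= spec$session_s) break
    while (length(pend_cue) && pend_cue[1] <= t) {
      emit(pend_cue[1], "cue_off")
      pend_cue <- pend_cue[-1]
    }
    if (i == 1L) next  # the triggering scan is represented by session_start
    emit(t, kinds[i], if (kinds[i] == "rfid_scan") toupper(tags[i]) else NA_character_)
    if (kinds[i] == "lick_active") {
      last_active <- t
      if (t >= timeout_until) {
        count <- count + 1L
        if (count >= requirement) {
          n_rewards <- n_rewards + 1L
          emit(t, "reward")
          emit(t, "cue_on")
          pend_cue <- c(pend_cue, t + spec$cue_s)
          timeout_until <- t + spec$timeout_s
          count <- 0L
          requirement <- draw_req()
        }
      }
    }
  }

  end_t <- if (fixed_len) spec$session_s
           else (if (is.na(last_active)) 0 else last_active) + spec$pr_idle_stop_s
  if (!fixed_len && m > 0L) {
    keep <- out_t[seq_len(m)] <= end_t
    keep_idx <- which(keep)
    m <- length(keep_idx)
    out_t[seq_len(m)] <- out_t[keep_idx]
    out_k[seq_len(m)] <- out_k[keep_idx]
    out_g[seq_len(m)] <- out_g[keep_idx]
  }
  for (off in pend_cue) emit(min(off, end_t), "cue_off")
  emit(end_t, "session_end")

  events <- events_frame(out_t[seq_len(m)], out_k[seq_len(m)], out_g[seq_len(m)])
  session_record(subject_tag, spec, events, start_time = start_time, seed = seed)
}
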