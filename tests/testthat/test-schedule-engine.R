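test_that("a fresh FR1 schedule rewards the very first lick", {
  spec <- schedule_spec("FR", 1)
  st <- new_schedule_state(spec)
  res <- fr_on_lick(st, 0, spec)
  expect_true(res$reward)
  expect_equal(res$state$rewards_delivered, 1L)
})

test_that("FR10 rewards only on the 10th counted lick", {
  spec <- schedule_spec("FR", 10, timeout_s = 0)
  st <- new_schedule_state(spec)
  got <- logical(10)
  for (i in 1:10) {
    res <- fr_on_lick(st, i * 0.15, spec)
    st <- res$state
    got[i] <- res$reward
  }
  expect_equal(got, c(rep(FALSE, 9), TRUE))
  expect_equal(st$licks_toward_requirement, 0L)
})

test_that("licks inside the timeout are logged but never counted", {
  spec <- schedule_spec("FR", 2, timeout_s = 10)
  st <- new_schedule_state(spec)
  for (t in c(0, 1)) st <- schedule_on_lick(st, t, spec)$state  # reward at t=1
  r <- schedule_on_lick(st, 5, spec)   # inside [1, 11)
  expect_equal(r$state$licks_toward_requirement, 0L)
  r <- schedule_on_lick(r$state, 11, spec)  # exactly at the boundary: counts
  expect_equal(r$state$licks_toward_requirement, 1L)
  r <- schedule_on_lick(r$state, 11.2, spec)
  expect_true(r$reward)
})

test_that("stepwise lick processing rejects non-monotone times", {
  spec <- schedule_spec("FR", 5)
  st <- schedule_on_lick(new_schedule_state(spec), 3, spec)$state
  expect_error(schedule_on_lick(st, 2, spec), "non-monotone")
})

test_that("VR draws are uniform on 1..2m-1 with the right mean", {
  set.seed(11)
  draws <- vr_draw_requirement(10, n = 1e5)
  expect_true(all(draws >= 1 & draws <= 19))
  se <- stats::sd(1:19) / sqrt(1e5)
  expect_lt(abs(mean(draws) - 10), 3 * se)
  expect_equal(vr_draw_requirement(1, n = 50), rep(1L, 50))  # degenerate
  expect_error(vr_draw_requirement(0), "positive")
})

test_that("PR requirements follow the arithmetic progression", {
  spec <- schedule_spec("PR", 10, pr_step = 5)
  expect_equal(pr_requirement(1, spec), 10L)
  expect_equal(pr_requirement(3, spec), 20L)
  expect_true(all(diff(pr_requirement(1:100, spec)) > 0))
  expect_error(pr_requirement(0, spec), ">= 1")
})

test_that("RFID map resolves mapped tags and defaults to VR10", {
  pr <- schedule_spec("PR", 10)
  fr <- schedule_spec("FR", 10)
  map <- rfid_schedule_map(list(
    "AAAAAAAAAAAA" = pr, "BBBBBBBBBBBB" = fr, "CCCCCCCCCCCC" = fr
  ))
  expect_equal(resolve_schedule("AAAAAAAAAAAA", map)$family, "PR")
  # two alternative tags resolve to the same schedule
  expect_equal(resolve_schedule("BBBBBBBBBBBB", map),
               resolve_schedule("CCCCCCCCCCCC", map))
  deflt <- resolve_schedule("0123456789AB", map)
  expect_equal(deflt$family, "VR")
  expect_equal(deflt$ratio, 10L)
  expect_error(resolve_schedule("xyz", map), "hexadecimal")
})

test_that("schedule configs load from YAML with defaults filled in", {
  cfg <- read_schedule_config(system.file("extdata", "fr10.yaml",
                                          package = "lickometry"))
  expect_equal(cfg, schedule_spec("FR", 10))
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("family: FR", "ratio: 10", "pump_steps: 4"), bad)
  expect_error(read_schedule_config(bad), "unknown")
})

scan_stream <- function(times, kinds) {
  events_frame(c(0, times), c("rfid_scan", kinds),
               c("0A1B2C3D4E5F", rep(NA_character_, length(times))))
}

test_that("a scan with no licks yields an empty fixed-length session", {
  rec <- run_session(scan_stream(numeric(0), character(0)),
                     schedule_spec("FR", 10))
  expect_equal(rec$rewards, 0L)
  expect_equal(rec$events$kind, c("session_start", "session_end"))
  expect_equal(rec$events$time_s, c(0, 3600))
})

test_that("a PR session ends the stop window after the last active lick", {
  spec <- schedule_spec("PR", 10)
  rec <- run_session(scan_stream(c(10, 50, 80, 100), rep("lick_active", 4)), spec)
  expect_equal(rec$events$time_s[nrow(rec$events)], 700)
  # trailing inactive licks and motion beyond the stop window are dropped
  rec2 <- run_session(
    scan_stream(c(100, 800, 5000), c("lick_active", "motion", "lick_inactive")),
    spec
  )
  expect_equal(rec2$events$time_s[nrow(rec2$events)], 700)
  expect_false("lick_inactive" %in% rec2$events$kind)
  expect_equal(sum(rec2$events$kind == "motion"), 0L)
})

test_that("the controller enforces its input contract", {
  expect_error(run_session(events_frame(0, "lick_active"), schedule_spec("FR")),
               "rfid_scan")
  bad <- scan_stream(c(5, 3), c("lick_active", "lick_active"))
  expect_error(run_session(bad, schedule_spec("FR")), "out of order")
  withreward <- scan_stream(1, "reward")
  expect_error(run_session(withreward, schedule_spec("FR")), "raw input")
  expect_error(run_session(scan_stream(numeric(0), character(0)),
                           schedule_spec("VR", 10)), "seed")
})

test_that("rewards trigger paired cue events spanning the cue duration", {
  spec <- schedule_spec("FR", 2, timeout_s = 0, cue_s = 5, session_s = 100)
  rec <- run_session(scan_stream(c(1, 2, 30, 31, 98, 99),
                                 rep("lick_active", 6)), spec)
  ons <- rec$events$time_s[rec$events$kind == "cue_on"]
  offs <- rec$events$time_s[rec$events$kind == "cue_off"]
  expect_equal(ons, c(2, 31, 99))
  expect_equal(offs, c(7, 36, 100))  # last pair truncated at session end
  expect_true(all(diff(rec$events$time_s) >= 0))
})

test_that("input beyond the fixed session length is discarded", {
  spec <- schedule_spec("FR", 1, timeout_s = 0, session_s = 60)
  rec <- run_session(scan_stream(c(10, 59.9, 60, 61),
                                 rep("lick_active", 4)), spec)
  expect_equal(sum(rec$events$kind == "lick_active"), 2L)
  expect_equal(rec$rewards, 2L)
  expect_equal(rec$events$time_s[nrow(rec$events)], 60)
})

test_that("VR sessions are reproducible under a seed and match stepwise replay", {
  spec <- schedule_spec("VR", 10, timeout_s = 2)
  set.seed(33)
  stream <- random_stream(3000)
  a <- run_session(stream, spec, seed = 7)
  b <- run_session(stream, spec, seed = 7)
  expect_identical(a$events, b$events)
  c_ <- run_session(stream, spec, seed = 8)
  expect_false(identical(reward_times_of(a), reward_times_of(c_)))

  # the stepwise API with the same seed reproduces the reward times
  st <- new_schedule_state(spec, seed = 7)
  rel <- stream$time_s - stream$time_s[1]
  active <- rel[stream$kind == "lick_active" & rel < spec$session_s]
  rt <- c()
  for (tt in active) {
    res <- vr_on_lick(st, tt, spec)
    st <- res$state
    if (res$reward) rt <- c(rt, tt)
  }
  expect_equal(reward_times_of(a), rt)
})

test_that("FR is the degenerate case of VR", {
  set.seed(5)
  stream <- random_stream(2000)
  for (m in c(1L, 7L)) {
    fr <- run_session(stream, schedule_spec("FR", m, timeout_s = 3))
    vr <- run_session(stream, schedule_spec("VR", m, timeout_s = 3,
                                            vr_draws = m))
    expect_identical(reward_times_of(fr), reward_times_of(vr))
  }
})

test_that("the session seed and config are recorded in the written log", {
  set.seed(2)
  stream <- random_stream(500)
  rec <- run_session(stream, schedule_spec("VR", 10), seed = 123)
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(rec, path)
  back <- read_event_log(path)
  expect_equal(back$seed, 123L)
  expect_equal(back$schedule$family, "VR")
})
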