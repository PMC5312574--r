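test_that("cluster segmentation follows the 0.5 s / two-lick rules", {
  expect_equal(segment_clusters(numeric(0)), list())
  expect_equal(segment_clusters(0.0), list())  # singleton excluded
  cl <- segment_clusters(c(0.0, 0.1, 0.2, 1.0, 1.4, 5.0))
  expect_length(cl, 2)
  expect_equal(vapply(cl, function(x) x$size, 0L), c(3L, 2L))
  expect_equal(cl[[1]]$lick_times, c(0.0, 0.1, 0.2))
  expect_equal(cl[[2]]$ilis, 0.4)
  # a gap of exactly the threshold splits (strict-inequality convention)
  expect_length(segment_clusters(c(0, 0.5)), 0)
  expect_length(segment_clusters(c(0, 0.49999)), 1)
  expect_error(segment_clusters(c(1, 0.5)), "non-decreasing")
})

test_that("segmentation is idempotent and monotone in the threshold", {
  set.seed(42)
  for (i in 1:20) {
    times <- cumsum(ifelse(stats::runif(300) < 0.7,
                           stats::runif(300, 0.05, 0.4),
                           stats::runif(300, 0.5, 3)))
    cl <- segment_clusters(times)
    resegmented <- segment_clusters(unlist(lapply(cl, function(x) x$lick_times)))
    expect_equal(lapply(resegmented, function(x) x$lick_times),
                 lapply(cl, function(x) x$lick_times))
    for (thr in c(0.3, 0.15)) {
      smaller <- segment_clusters(times, threshold_s = thr)
      expect_lte(sum(vapply(smaller, function(x) x$size, 0L)),
                 sum(vapply(cl, function(x) x$size, 0L)))
    }
  }
})

test_that("microstructure summaries are hand-checkable", {
  cl <- segment_clusters(c(0, 0.1, 0.2, 1.0, 1.1))
  s <- summarize_microstructure(cl, total_licks = 5)
  expect_equal(s$n_clusters, 2L)
  expect_equal(s$mean_cluster_size, 2.5)
  expect_equal(s$mean_ili_s, 0.1)
  expect_false(s$empty)
  expect_gte(s$total_licks, sum(vapply(cl, function(x) x$size, 0L)))

  single <- summarize_microstructure(segment_clusters(c(0, 0.1)))
  expect_true(is.na(single$sem_cluster_size))  # SEM undefined at n = 1

  empty <- summarize_microstructure(list())
  expect_true(empty$empty)
  expect_true(is.na(empty$mean_cluster_size))
})

test_that("pooled and per-cluster ILI aggregation differ as documented", {
  cl <- segment_clusters(c(0, 0.1, 0.2, 0.3, 2.0, 2.4))
  pooled <- summarize_microstructure(cl, ili_mode = "pooled")
  per <- summarize_microstructure(cl, ili_mode = "per_cluster")
  expect_equal(pooled$mean_ili_s, mean(c(0.1, 0.1, 0.1, 0.4)))
  expect_equal(per$mean_ili_s, mean(c(0.1, 0.4)))
})

test_that("session summaries count events by kind", {
  rec <- run_session(events_frame(0, "rfid_scan", "0A1B2C3D4E5F"),
                     schedule_spec("FR", 10))
  expect_equal(unlist(session_summary(rec)[, c("licks_active", "licks_inactive",
                                               "rewards")]),
               c(licks_active = 0L, licks_inactive = 0L, rewards = 0L))

  stream <- events_frame(c(0, 1, 2, 3), c("rfid_scan", rep("lick_active", 3)),
                         c("0A1B2C3D4E5F", rep(NA, 3)))
  rec <- run_session(stream, schedule_spec("FR", 1, timeout_s = 0))
  expect_equal(session_summary(rec)$rewards, 3L)
})

test_that("cumulative records conserve totals and never decrease", {
  set.seed(9)
  stream <- random_stream(2000)
  rec <- run_session(stream, schedule_spec("FR", 10, session_s = 400))
  cr <- cumulative_record(rec)
  sm <- session_summary(rec)
  for (k in unique(cr$kind)) {
    series <- cr[cr$kind == k, ]
    expect_true(all(diff(series$count) >= 0))
    expected <- switch(k, lick_active = sm$licks_active,
                       lick_inactive = sm$licks_inactive,
                       reward = sm$rewards)
    expect_equal(series$count[nrow(series)], expected)
    # independent running-count check
    t_k <- rec$events$time_s[rec$events$kind == k]
    expect_equal(series$count[-c(1, nrow(series))], seq_along(t_k))
  }
  empty <- run_session(events_frame(0, "rfid_scan", "0A1B2C3D4E5F"),
                       schedule_spec("FR", 10))
  cr0 <- cumulative_record(empty)
  expect_true(all(cr0$count == 0))
})

test_that("activity binning uses half-open 1-min bins and conserves counts", {
  b <- bin_activity(numeric(0), bin_s = 60, session_s = 300)
  expect_equal(nrow(b), 5)
  expect_true(all(b$count == 0))

  b <- bin_activity(c(0, 59.9, 60.0), bin_s = 60, session_s = 300)
  expect_equal(b$count, c(2L, 1L, 0L, 0L, 0L))

  set.seed(4)
  times <- stats::runif(500, 0, 3600)
  b <- bin_activity(times, session_s = 3600)
  expect_equal(sum(b$count), 500L)
  expect_equal(nrow(b), 60)
  expect_error(bin_activity(c(-1), session_s = 10), "within")
})

test_that("the pooled t-test matches the reference implementation", {
  expect_error(compare_spouts(1, c(1, 2)), "at least 2")

  same <- compare_spouts(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "")

  far <- compare_spouts(c(101, 102, 103), c(1, 2, 3))
  expect_lt(far$p, 0.001)
  expect_equal(far$stars, "***")

  set.seed(12)
  for (i in 1:25) {
    a <- stats::rnorm(sample(3:12, 1), mean = stats::runif(1, 0, 5))
    b <- stats::rnorm(sample(3:12, 1))
    mine <- compare_spouts(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("per-spout analysis segments the spouts independently", {
  # interleaved spouts: licks on the other spout must not break a cluster
  ev <- rbind(
    events_frame(0, "session_start"),
    events_frame(c(1.0, 1.1, 1.2, 1.3), c("lick_active", "lick_inactive",
                                          "lick_active", "lick_inactive")),
    events_frame(10, "session_end")
  )
  rec <- session_record("0A1B2C3D4E5F", schedule_spec("FR"), ev)
  m <- analyze_licks(rec)
  expect_equal(m$n_clusters[m$spout == "active"], 1L)
  expect_equal(m$mean_ili_s[m$spout == "active"], 0.2)
  expect_equal(m$n_clusters[m$spout == "inactive"], 1L)
})
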