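test_that("protocol timing arithmetic reproduces the printed values", {
  expect_equal(run_duration_s(96, 140, 5), 67.2)
  expect_equal(run_duration_s(1, 1, 5), 0.005)
  expect_equal(run_duration_s(96, 120, 5), 57.6)
  expect_equal(scan_duration_s(11, 2000, 96, 140, 5), 749.2)
  expect_equal(scan_duration_s(0, 2000, 96, 140, 5), 10)
  expect_equal(scan_duration_s(1, 0, 96, 140, 5), run_duration_s(96, 140, 5))
  expect_identical(spgre_discard_count(2000, 96), 21L)
  expect_identical(spgre_discard_count(96, 96), 1L)
  expect_identical(spgre_discard_count(97, 96), 2L)
  expect_identical(trial_timepoints(100, 600, 5), 140L)
  expect_identical(trial_timepoints(50, 550, 5), 120L)
  expect_identical(trial_timepoints(5, 0, 5), 1L)
  expect_error(trial_timepoints(101, 600, 5), "divisible")
})

test_that("paradigm presets reproduce the protocol table", {
  p1 <- paradigm_preset("paradigm_I")
  expect_equal(c(p1$stim_ms, p1$isi_ms, p1$n_runs_per_scan, p1$n_scans),
               c(50, 550, 11, 3))
  expect_identical(p1$trial_timepoints_m, 120L)
  p2 <- paradigm_preset("paradigm_II")
  expect_equal(c(p2$stim_ms, p2$isi_ms, p2$n_runs_per_scan), c(200, 500, 10))
  p3 <- paradigm_preset("paradigm_III")
  expect_equal(c(p3$stim_ms, p3$isi_ms, p3$matrix_n, p3$n_subjects),
               c(100, 600, 96, 3))
  expect_identical(p3$trial_timepoints_m, 140L)
  p5 <- paradigm_preset("paradigm_V")
  expect_identical(p5$matrix_n, 192L)
  expect_identical(p5$resolution, "1x1x5mm")
  expect_error(paradigm_preset("paradigm_X"), "unknown")
})

test_that("loop-swapped schedule structure: counts, uniqueness, timing", {
  s <- diana_schedule(96, 140, n_dummy = 2000, tr_ms = 5)
  expect_identical(nrow(s$events), 96L * 140L)
  expect_false(anyDuplicated(s$events[c("phase_line", "time_point")]) > 0)
  expect_lt(max(abs(diff(s$events$absolute_time_s) - 0.005)), 1e-12)
  expect_equal(s$events$absolute_time_s[1], 2000 * 0.005)
  # within each trial all M time points of one line are consecutive
  first_trial <- s$events[s$events$trial_index == 1, ]
  expect_identical(unique(first_trial$phase_line), 1L)
  expect_identical(first_trial$time_point, 1:140)
  expect_identical(nrow(diana_schedule(1, 1)$events), 1L)

  # center line revisit interval across sequential runs is N*M*TR
  N <- 16; M <- 10
  r1 <- diana_schedule(N, M, tr_ms = 5)
  r2 <- diana_schedule(N, M, tr_ms = 5, start_time_s = N * M * 0.005)
  ctr <- floor(N / 2) + 1
  t1 <- r1$events$absolute_time_s[r1$events$phase_line == ctr]
  t2 <- r2$events$absolute_time_s[r2$events$phase_line == ctr]
  expect_equal(t2 - t1, rep(N * M * 0.005, M))

  # centric ordering touches the center line in the first trial
  sc <- diana_schedule(N, M, line_order = "centric")
  expect_identical(sc$events$phase_line[1], as.integer(ctr))
  expect_identical(sort(unique(sc$events$phase_line)), 1:N)
})

test_that("conventional SPGRE schedule crosses k-space center every N*TR", {
  s <- spgre_schedule(96, 512, tr_ms = 5)
  expect_identical(nrow(s$events), 96L * 512L)
  ctr_times <- s$events$absolute_time_s[s$events$phase_line == 49L]
  expect_equal(unique(round(diff(ctr_times), 10)), 96 * 0.005)
  # N = 1: every event is a center-line pass
  s1 <- spgre_schedule(1, 5, tr_ms = 5)
  expect_true(all(s1$events$phase_line == 1L))
  expect_equal(diff(s1$events$absolute_time_s), rep(0.005, 4))
})

test_that("acquisition of a static phantom is reconstruction-exact and time-invariant", {
  ph <- tiny_phantom(32)
  sq <- seq_params(5, 2.4, 4)
  kd <- simulate_acquisition(ph, sq, diana_schedule(32, 8, tr_ms = 5))
  ks <- simulate_acquisition(ph, sq, spgre_schedule(32, 8, tr_ms = 5))
  # every time point's k-space identical for a static, noise-free object
  for (t in 2:8) expect_equal(kd$k[, , t], kd$k[, , 1])
  # loop order does not matter for a static object
  expect_equal(kd$k, ks$k)
  # and reconstruction matches the directly rasterized image
  im <- reconstruct(kd)
  base <- baseline_image(ph, sq)
  expect_lt(max(abs(im$data[, , 1] - base)) / max(base), 1e-6)
  expect_error(simulate_acquisition(tiny_phantom(16), sq,
                                    diana_schedule(32, 4)), "matrix size")
})

test_that("drift scales loop-swapped lines per trial; a boxcar response is local in time", {
  ph <- tiny_phantom(32)
  sq <- seq_params(5, 2.4, 4)
  sched <- diana_schedule(32, 10, tr_ms = 5)
  kd <- simulate_acquisition(ph, sq, sched, drift = drift_model(60))  # 1%/s
  # within one trial (line) magnitudes follow the within-trial drift;
  # across trials lines scale by the drift factor at their acquisition times
  line_mean <- function(k, n) mean(Mod(k[n, , ]))
  base <- simulate_acquisition(ph, sq, sched)
  f1 <- line_mean(kd$k, 1) / line_mean(base$k, 1)
  f20 <- line_mean(kd$k, 20) / line_mean(base$k, 20)
  t1 <- mean(sched$events$absolute_time_s[sched$events$phase_line == 1])
  t20 <- mean(sched$events$absolute_time_s[sched$events$phase_line == 20])
  expect_equal(f20 / f1, (1 + t20 / 100) / (1 + t1 / 100), tolerance = 1e-9)

  # injected response, no noise: only time points inside the boxcar differ
  resp <- response_model(0.5, onset_ms = 10, duration_ms = 15,
                         active_roi = "target")
  kr <- simulate_acquisition(ph, sq, sched, response = resp)
  affected <- vapply(1:10, function(t) max(abs(kr$k[, , t] - base$k[, , t])) > 0,
                     logical(1))
  expect_identical(affected, ((0:9) * 5) >= 10 & ((0:9) * 5) < 25)
})

test_that("event-count conservation and schedule validation", {
  expect_error(diana_schedule(0, 5), ">= 1")
  s <- diana_schedule(12, 7)
  expect_identical(nrow(s$events), 84L)
  tab <- table(s$events$phase_line)
  expect_true(all(tab == 7))
})
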