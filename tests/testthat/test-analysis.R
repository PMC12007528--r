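test_that("percent change has the closed form implied by a mean baseline", {
  expect_equal(percent_change(rep(7, 50)), rep(0, 50))

  # boxcar on 30 of 140 points: elevated points read amplitude minus the
  # baseline offset induced by including them in the temporal mean
  a <- 5e-4; k <- 30; m <- 140
  x <- rep(1000, m); x[11:(10 + k)] <- 1000 * (1 + a)
  pc <- percent_change(x)
  expected_hi <- 100 * a * (1 - k / m) / (1 + a * k / m)
  expect_equal(unique(round(pc[11:(10 + k)], 12)),
               round(expected_hi, 12))
  expect_equal(expected_hi, 0.0393, tolerance = 1e-3)

  # scale invariance
  expect_equal(percent_change(2 * x), pc)
  # zero-baseline voxels are returned as zeros, not NaN
  expect_identical(percent_change(rep(0, 10)), rep(0, 10))
})

test_that("linear detrending removes ramps, keeps means, and is idempotent", {
  t <- 1:100
  ramp <- 3 + 0.02 * t
  d <- detrend_linear(ramp)
  expect_equal(d, rep(mean(ramp), 100))

  # line + boxcar: boxcar preserved up to the projection bias of the fit
  box <- as.numeric(t >= 20 & t < 40)
  y <- 5 + 0.05 * t + box
  fit <- lm(box ~ t)                    # oracle: what the fit steals
  expect_equal(detrend_linear(y) - mean(y),
               as.numeric(box - fitted(fit)), tolerance = 1e-10)

  expect_equal(detrend_linear(detrend_linear(y)), detrend_linear(y))
  expect_equal(mean(detrend_linear(y)), mean(y))
})

test_that("Gaussian smoothing kernel behaves as a 3-tap normalized filter", {
  expect_equal(smooth_gaussian(rep(4.2, 30)), rep(4.2, 30))

  imp <- rep(0, 21); imp[11] <- 1
  sm <- smooth_gaussian(imp)
  w <- dnorm(-1:1, sd = 0.6); w <- w / sum(w)
  expect_equal(sm[10:12], w)
  expect_equal(sum(sm), 1)

  # white-noise variance is reduced by the sum of squared taps
  set.seed(5)
  x <- matrix(rnorm(200 * 500), 200, 500)
  ratio <- mean(apply(smooth_gaussian(x), 1, var)) / mean(apply(x, 1, var))
  expect_equal(ratio, sum(w^2), tolerance = 0.02)
  expect_error(smooth_gaussian(1:10, window_points = 4), "odd")
})

test_that("across-run confidence intervals are calibrated and pool as 1/sqrt(k)", {
  runs <- matrix(rep(sin(1:50), 4), 4, 50, byrow = TRUE)
  rr <- ci_across_runs(runs)
  expect_equal(max(rr$ci_halfwidth), 0)   # identical runs: zero-width CI
  expect_equal(rr$mean, sin(1:50))

  # null calibration: ~5% of time points exclude zero over many replicates
  set.seed(9)
  excl <- replicate(60, {
    r <- ci_across_runs(matrix(rnorm(30 * 140), 30, 140))
    mean(abs(r$mean) > r$ci_halfwidth)
  })
  expect_gt(mean(excl), 0.03)
  expect_lt(mean(excl), 0.075)

  # pooling k copies of a run set shrinks the CI half-width by ~sqrt(k)
  set.seed(10)
  base_runs <- matrix(rnorm(30 * 40), 30, 40)
  one <- ci_across_runs(base_runs)
  four <- group_average(list(base_runs, base_runs, base_runs, base_runs))
  expect_equal(mean(four$ci_halfwidth / one$ci_halfwidth), 0.5,
               tolerance = 0.05)
  expect_identical(four$n_runs, 120L)
  expect_error(ci_across_runs(matrix(1, 1, 10)), "at least 2")
})

test_that("temporal SNR definition, guards, and sqrt(V) ROI scaling", {
  set.seed(3)
  v <- 25; m <- 1000
  x <- array(1000 + rnorm(v * m), dim = c(5, 5, m))
  ts <- tsnr(x)
  expect_equal(mean(ts$map), 1000, tolerance = 0.1)
  mask <- matrix(TRUE, 5, 5)
  rt <- roi_tsnr(ts, mask)
  expect_equal(rt$expected_roi_tsnr, rt$voxel_tsnr * 5)
  # measured tSNR of the ROI-mean time course scales by sqrt(V) under
  # i.i.d. voxel noise
  meas <- roi_timecourse_tsnr(x, mask)
  expect_lt(abs(meas / (rt$voxel_tsnr * sqrt(v)) - 1), 0.1)

  # constant voxels are flagged, never infinite
  xc <- array(5, dim = c(2, 2, 10))
  tc <- tsnr(xc)
  expect_true(all(is.na(tc$map)))
  expect_false(any(tc$valid))
  expect_error(roi_tsnr(tc, matrix(TRUE, 2, 2)), "no valid voxels")
})

test_that("minimum detectable amplitude matches a Monte-Carlo power simulation", {
  expect_lt(min_detectable_pct(1e9, 25, 30), 1e-6)          # tsnr -> infinity
  expect_equal(min_detectable_pct(1000, 25, 120) * 2,
               min_detectable_pct(1000, 25, 30))            # 4x runs halves it

  # Monte-Carlo oracle: inject delta_min into V-voxel ROI means across runs,
  # test per replicate with a two-sided z-test at alpha = 0.05
  tsnr_v <- 1000; v <- 25; n_runs <- 30
  dmin <- min_detectable_pct(tsnr_v, v, n_runs)
  set.seed(17)
  nsim <- 4000
  se_pct <- 100 / (tsnr_v * sqrt(v * n_runs))
  zstat <- (dmin + rnorm(nsim, 0, se_pct)) / se_pct
  power <- mean(abs(zstat) > qnorm(0.975))
  expect_equal(power, 0.8, tolerance = 0.15)
})

test_that("response characterization recovers noise-free injections exactly", {
  # zero-noise boxcar: onset and duration exact, amplitude equal to the
  # chain's deterministic output (oracle built from lm() + stats::filter())
  m <- 140; tr <- 5; a <- 0.05; k <- 30
  phase <- (seq_len(m) - 1) * tr
  gain <- 1 + a / 100 * (phase >= 75 & phase < 225)
  run <- smooth_gaussian(detrend_linear(percent_change(1000 * gain)))
  rr <- ci_across_runs(rbind(run, run, run), tr_ms = tr)
  est <- estimate_response(rr, stim_onset_index = 1)
  expect_true(est$significant)
  expect_equal(est$onset_ms, 75)
  expect_lte(abs(est$duration_ms - 150), 10)

  # independent oracle for the chain's noise-free amplitude
  s <- 1000 * gain
  pc <- 100 * (s - mean(s)) / mean(s)
  dt <- as.numeric(residuals(lm(pc ~ phase))) + mean(pc)
  w <- dnorm(-1:1, sd = 0.6); w <- w / sum(w)
  padded <- c(dt[2], dt, dt[m - 1])
  sm <- as.numeric(stats::filter(padded, w, sides = 2))[2:(m + 1)]
  expect_equal(est$amplitude_pct, max(sm), tolerance = 1e-10)
  # the chain attenuates the boxcar: baseline inclusion (1 - k/m) and the
  # detrending tilt shave the plateau; the peak lands near 0.65 * a
  expect_lt(est$amplitude_pct, a * (1 - k / m))
  expect_gt(est$amplitude_pct, 0.5 * a)
})

test_that("stochastic recovery at paradigm-like noise levels and null specificity", {
  set.seed(31)
  # 33 runs, voxel tSNR 1000, V = 25: injected 0.05% boxcar at 75-225 ms
  runs <- sim_runs_roi(33, m_tp = 140, v = 25, amp_pct = 0.05,
                       onset_ms = 75, dur_ms = 150)
  est <- estimate_response(ci_across_runs(runs, tr_ms = 5))
  expect_true(est$significant)
  expect_gt(est$amplitude_pct, 0.03)
  expect_lt(est$amplitude_pct, 0.07)
  expect_lte(abs(est$onset_ms - 75), 25)

  # null data: no significant response in >= 90% of seeds
  set.seed(32)
  hits <- replicate(20, {
    r <- ci_across_runs(sim_runs_roi(33, m_tp = 140, v = 25, amp_pct = 0))
    estimate_response(r)$significant
  })
  expect_gte(mean(!hits), 0.9)
})

test_that("the analysis chain applies its stages in the stated order", {
  ph <- tiny_phantom(32)
  sq <- seq_params(5, 2.4, 4, n_dummy = 0)
  nz <- noise_model(0.4, seed = 8L)
  ks <- simulate_acquisition(ph, sq, diana_schedule(32, 20, tr_ms = 5),
                             noise = nz, drift = drift_model(2))
  series <- reconstruct(ks)
  mask <- ph$rois$target

  got <- run_roi_timecourse(series, mask)
  manual <- roi_aggregate(
    smooth_gaussian(detrend_linear(percent_change(series$data))), mask)
  expect_equal(got, manual)

  # permuting the stages changes the output (guards silent reordering)
  swapped <- roi_aggregate(
    detrend_linear(smooth_gaussian(percent_change(series$data))), mask)
  expect_false(isTRUE(all.equal(got, swapped)))
  pre_agg <- smooth_gaussian(detrend_linear(percent_change(
    roi_aggregate(series$data, mask))))
  expect_false(isTRUE(all.equal(got, pre_agg)))
})

test_that("per-trial k-space normalization removes global drift, not signal", {
  ph <- tiny_phantom(32)
  sq <- seq_params(5, 2.4, 4, n_dummy = 0)
  par <- paradigm("scaled", 50, 150, 5, 32)   # M = 40
  drift <- drift_model(rate_pct_per_min = 1)

  # two sequential runs under drift: un-normalized run means step by
  # rate * N*M*TR; normalized, the step is gone
  ks <- simulate_scan(ph, sq, par, n_runs = 2, drift = drift)
  rm_un <- vapply(ks, function(k) mean(reconstruct(k)$data), numeric(1))
  step <- 1 * 32 * 40 * 0.005 / 60 / 100
  expect_lt(abs((rm_un[2] / rm_un[1] - 1) / step - 1), 0.01)
  kn <- lapply(ks, normalize_trials)
  rm_no <- vapply(kn, function(k) mean(reconstruct(k)$data), numeric(1))
  expect_lt(abs(rm_no[2] / rm_no[1] - 1), 1e-5)
  # the structure-preserving scan normalization also removes the step
  rm_sc <- vapply(normalize_scan(ks),
                  function(k) mean(reconstruct(k)$data), numeric(1))
  expect_lt(abs(rm_sc[2] / rm_sc[1] - 1), 1e-5)

  # trial-averaged ROI time course is flat after normalization + chain
  rr <- analyze_runs(lapply(normalize_scan(ks), reconstruct),
                     ph$rois$object)
  expect_lt(max(abs(rr$mean)), 1e-3)

  # drift-free null data: per-trial normalization leaves percent-change
  # time courses unchanged (factors are exactly constant)
  k0 <- simulate_acquisition(ph, sq, diana_schedule(32, 40, tr_ms = 5))
  tc_raw <- run_roi_timecourse(reconstruct(k0), ph$rois$target)
  tc_nrm <- run_roi_timecourse(reconstruct(normalize_trials(k0)),
                               ph$rois$target)
  expect_lt(max(abs(tc_raw - tc_nrm)), 1e-6)

  # scan normalization preserves a response's percent-change time course
  resp <- response_model(0.05, 20, 60, active_roi = "target")
  kr <- simulate_scan(ph, sq, par, n_runs = 2, response = resp)
  tcs <- lapply(lapply(normalize_scan(kr), reconstruct),
                run_roi_timecourse, mask = ph$rois$target)
  tc0 <- run_roi_timecourse(reconstruct(kr[[1]]), ph$rois$target)
  expect_lt(max(abs(tcs[[1]] - tc0)), 1e-6)

  # zero-energy line and wrong mode are explicit errors
  kz <- kr[[1]]; kz$k[3, , ] <- 0
  expect_error(normalize_trials(kz), "zero energy")
  ksp <- simulate_acquisition(ph, sq, spgre_schedule(32, 4, tr_ms = 5))
  expect_error(normalize_trials(ksp), "loop-swapped")
})

test_that("responses injected in the target ROI do not leak into control ROIs", {
  ph <- tiny_phantom(32)
  sq <- seq_params(5, 2.4, 4, n_dummy = 0)
  par <- paradigm("scaled", 50, 150, 5, 32)
  resp <- response_model(0.5, onset_ms = 20, duration_ms = 60,
                         active_roi = "target")
  ks <- simulate_scan(ph, sq, par, n_runs = 3, response = resp,
                      noise = noise_model(0.05, seed = 12L))
  runs <- lapply(normalize_scan(ks), reconstruct)
  rr_t <- analyze_runs(runs, ph$rois$target)
  rr_c <- analyze_runs(runs, ph$rois$control)
  expect_gt(max(rr_t$mean), 0.2)
  expect_lt(max(abs(rr_c$mean)), 0.05)
})
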