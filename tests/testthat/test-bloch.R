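test_that("steady state matches the recursion fixed point and its limits", {
  sq <- seq_params(tr_ms = 5, te_ms = 2.4, fa_deg = 4)

  # saturation limit: very long T1 drives Mss to 0
  expect_lt(steady_state_mz(sq, tissue_params(t1_ms = 1e12)), 1e-6)
  # vanishing flip angle: no saturation, Mss -> 1
  expect_equal(steady_state_mz(seq_params(fa_deg = 1e-6),
                               tissue_params(2000)), 1, tolerance = 1e-8)

  # brute-force iteration of the per-TR recurrence as oracle
  iterate_to_fp <- function(tr, t1, fa_deg, n = 2e5) {
    e1 <- exp(-tr / t1); ca <- cos(fa_deg * pi / 180); mz <- 1
    for (i in seq_len(n)) mz <- 1 + (mz * ca - 1) * e1
    mz
  }
  for (t1 in c(800, 2000, 4500)) {
    expect_equal(steady_state_mz(sq, tissue_params(t1)),
                 iterate_to_fp(5, t1, 4), tolerance = 1e-10)
  }
  expect_error(tissue_params(t1_ms = -1), "positive")
  expect_error(seq_params(tr_ms = 0), "positive")
})

test_that("transient approach reports pre-pulse Mz and is monotone", {
  sq <- seq_params(5, 2.4, 4)
  tc <- simulate_approach(sq, tissue_params(2000), n_pulses = 1, m0 = 1)
  expect_equal(tc$mz[1], 1)  # curve starts at the fully relaxed state

  # very short T1: recovery per TR is nearly complete, convergence immediate
  tc_fast <- simulate_approach(sq, tissue_params(t1_ms = 1), n_pulses = 50,
                               rel_tol = 1e-4)
  expect_lt(tc_fast$n_to_tolerance, 10)

  tc_slow <- simulate_approach(sq, tissue_params(2000), n_pulses = 3000)
  expect_true(all(diff(tc_slow$mz) <= 0))          # non-increasing from m0 = 1
  expect_true(all(tc_slow$mz > 0 & tc_slow$mz <= 1))
  expect_equal(tail(tc_slow$mz, 1), tc_slow$mss, tolerance = 1e-3)

  # from m0 below the steady state the approach is non-decreasing
  tc_up <- simulate_approach(sq, tissue_params(2000), 2000, m0 = 0.01)
  expect_true(all(diff(tc_up$mz) >= 0))
})

test_that("fixed-point property holds over a TR/T1/FA grid", {
  for (tr in c(3, 5, 10)) for (t1 in c(500, 2000, 4000)) for (fa in c(2, 4, 15)) {
    sq <- seq_params(tr_ms = tr, te_ms = tr / 2, fa_deg = fa)
    for (m0 in c(0.05, 1)) {
      tc <- simulate_approach(sq, tissue_params(t1), n_pulses = 2e4, m0 = m0)
      expect_equal(tail(tc$mz, 1) / tc$mss, 1, tolerance = 1e-8)
    }
  }
})

test_that("dummy-pulse counts match the exponential-approach closed form", {
  sq <- seq_params(5, 2.4, 4)
  # analytic estimate: 1/T1* = 1/T1 - ln(cos a)/TR, n = ceil(-T1*/TR * log(...))
  analytic <- function(t1, rel_tol) {
    e1 <- exp(-5 / t1); ca <- cos(4 * pi / 180)
    mss <- (1 - e1) / (1 - e1 * ca)
    t1_star <- 1 / (1 / t1 - log(ca) / 5)
    ceiling(-t1_star * log(rel_tol * mss / (1 - mss)) / 5)
  }
  for (t1 in c(1000, 2500, 4500)) for (tol in c(0.01, 0.05)) {
    got <- dummy_pulses_to_steady_state(sq, t1_grid = t1, rel_tol = tol)
    expect_lte(abs(got$table$n_dummy - analytic(t1, tol)), 2)
  }
})

test_that("dummy count is monotone in tolerance and in T1", {
  sq <- seq_params(5, 2.4, 4)
  loose <- dummy_pulses_to_steady_state(sq, t1_grid = 1000, rel_tol = 0.1)
  tight <- dummy_pulses_to_steady_state(sq, t1_grid = 1000, rel_tol = 0.01)
  expect_lt(loose$table$n_dummy, tight$table$n_dummy)

  grid <- dummy_pulses_to_steady_state(sq)$table
  expect_true(all(diff(grid$n_dummy) > 0))   # non-decreasing in T1
  expect_error(dummy_pulses_to_steady_state(sq, t1_grid = numeric(0)),
               "non-empty")
  expect_error(dummy_pulses_to_steady_state(sq, rel_tol = 0.5), "rel_tol")
})

test_that("RF-spoiled ensemble converges to the ideal-spoiling signal", {
  sq <- seq_params(5, 2.4, 4, rf_phase_increment_deg = 50)
  ts <- tissue_params(2000, 33)
  ens <- simulate_rf_spoiled_ensemble(sq, ts, n_isochromats = 500,
                                      n_pulses = 3000)
  ideal <- spgre_signal(sq, ts)
  expect_equal(tail(ens$signal, 1), ideal, tolerance = 0.05)

  # near-zero flip angle: no transverse signal at any excitation
  sq0 <- seq_params(5, 2.4, 1e-6)
  ens0 <- simulate_rf_spoiled_ensemble(sq0, ts, 100, 100)
  expect_lt(max(ens0$signal), 1e-7)

  # ensemble-size self-consistency
  s1 <- simulate_rf_spoiled_ensemble(sq, ts, 500, 2000)
  s2 <- simulate_rf_spoiled_ensemble(sq, ts, 1000, 2000)
  expect_equal(tail(s1$signal, 1), tail(s2$signal, 1), tolerance = 0.01)
  expect_error(simulate_rf_spoiled_ensemble(sq, ts, 10, 100), "100")
})

test_that("ensemble with spoiling off and crushed T2 reduces to the longitudinal recursion", {
  sq <- seq_params(5, 2.4, 4)
  ts <- tissue_params(2000, 1e-6)   # transverse magnetization dies within a TR
  ens <- simulate_rf_spoiled_ensemble(sq, ts, n_isochromats = 100,
                                      n_pulses = 300, spoiling = FALSE)
  tc <- simulate_approach(sq, ts, n_pulses = 300)
  expect_equal(ens$mz, tc$mz, tolerance = 1e-6)
})
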