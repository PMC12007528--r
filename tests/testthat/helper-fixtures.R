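# Shared fixtures, all built in code.

# Small asymmetric two-compartment phantom for fast acquisition tests.
# The target ROI is a v x v block of gray matter; a control block sits in
# white matter.
tiny_phantom <- function(n = 32, target_side = 5) {
  grid <- matrix(0L, n, n)
  xx <- matrix(seq_len(n), n, n)
  yy <- matrix(seq_len(n), n, n, byrow = TRUE)
  cx <- n / 2 + 0.7
  cy <- n / 2 - 1.3
  body <- (xx - cx)^2 + (yy - cy)^2 <= (0.42 * n)^2
  core <- (xx - cx - 1)^2 + (yy - cy)^2 <= (0.24 * n)^2
  grid[body] <- 2L   # GM
  grid[core] <- 3L   # WM
  tx <- round(cx) + 2; ty <- round(cy + 0.3 * n)
  target <- matrix(FALSE, n, n)
  target[tx:(tx + target_side - 1), ty:(ty + target_side - 1)] <- TRUE
  target <- target & grid == 2L
  ctrl <- matrix(FALSE, n, n)
  ctrl[(round(cx) - 2):(round(cx) + 2), (round(cy) - 2):(round(cy) + 2)] <- TRUE
  ctrl <- ctrl & grid == 3L
  digital_phantom(grid,
                  list("2" = tissue_params(2000, 33, 0.8),
                       "3" = tissue_params(1200, 26, 0.7)),
                  rois = list(target = target, control = ctrl,
                              object = grid > 0L))
}

# Smooth asymmetric test image for registration (two Gaussian blobs on a
# dark background, zero near the edges).
smooth_test_image <- function(n = 48) {
  xx <- matrix(seq_len(n), n, n)
  yy <- matrix(seq_len(n), n, n, byrow = TRUE)
  exp(-((xx - 0.42 * n)^2 + (yy - 0.58 * n)^2) / (0.02 * n^2)) +
    0.6 * exp(-((xx - 0.66 * n)^2 + (yy - 0.33 * n)^2) / (0.03 * n^2))
}

# Run-level ROI simulation at the image level: V i.i.d. voxels with baseline
# `base`, thermal SD `sigma` (voxel tSNR = base/sigma), and a multiplicative
# boxcar of `amp_pct` percent on [onset_ms, onset_ms + dur_ms). Returns the
# ROI percent-change time course of one run after the standard chain
# (percent change -> detrend -> smooth -> ROI mean).
sim_run_roi_tc <- function(m_tp = 140, v = 25, tr_ms = 5, amp_pct = 0,
                           onset_ms = 75, dur_ms = 150, base = 1000,
                           sigma = 1) {
  phase <- (seq_len(m_tp) - 1) * tr_ms
  gain <- 1 + (amp_pct / 100) * (phase >= onset_ms & phase < onset_ms + dur_ms)
  x <- matrix(base, v, m_tp) * rep(gain, each = v) +
    matrix(rnorm(v * m_tp, 0, sigma), v, m_tp)
  x <- smooth_gaussian(detrend_linear(percent_change(x)))
  colMeans(x)
}

# Matrix of run-level ROI time courses.
sim_runs_roi <- function(n_runs, ...) {
  t(vapply(seq_len(n_runs), function(i) sim_run_roi_tc(...),
           numeric(list(...)$m_tp %||% 140)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
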