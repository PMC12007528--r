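#' Canonical double-gamma hemodynamic response function
#'
#' The standard double-gamma HRF: a gamma density peaking at `peak_s` minus a
#' scaled gamma undershoot peaking near `undershoot_s`, normalized to unit
#' maximum.
#'
#' @param t_s Time in seconds (>= 0).
#' @param peak_s Peak delay (default 6 s; shape of the positive gamma).
#' @param undershoot_s Undershoot delay (default 16 s).
#' @param ratio Undershoot amplitude ratio (default 1/6).
#' @return HRF values at `t_s`.
#' @export
canonical_hrf <- function(t_s, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  h <- stats::dgamma(t_s, shape = peak_s, rate = 1) -
    ratio * stats::dgamma(t_s, shape = undershoot_s, rate = 1)
  h / max(h)
}

#' Fourier-domain localizer for block-design BOLD data
#'
#' Detects voxels whose amplitude spectrum matches the expected spectrum of a
#' periodic block paradigm convolved with the canonical HRF, the quick
#' frequency-domain analysis used to place the imaging slice. The detection
#' statistic is the projection of the voxel's amplitude spectrum at the
#' paradigm fundamental and its harmonics (up to Nyquist) onto the expected
#' harmonic amplitudes, normalized by the voxel's root-mean-square
#' off-harmonic amplitude. Constant series score 0. The default threshold is
#' calibrated by white-noise simulation to a 5% voxelwise false-positive
#' rate.
#'
#' @param x Voxels-by-time matrix, 3D array or [image_series()] of an
#'   EPI-like acquisition.
#' @param period_s Paradigm period in seconds (default 12: 5 s on, 7 s off).
#' @param sampling_s Volume TR in seconds (default 1).
#' @param stim_on_s On-block duration in seconds (default 5).
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio Passed to [canonical_hrf()].
#' @param threshold Detection threshold; `NULL` (default) calibrates it by
#'   simulating `nsim` white-noise voxels and taking the `1 - alpha` quantile.
#' @param alpha Voxelwise false-positive rate for the calibrated threshold.
#' @param nsim Number of null voxels for calibration.
#' @param seed Seed for the calibration simulation.
#' @return A list of class `localizer_result`: `stat` (per voxel), `mask`
#'   (`stat > threshold`), `threshold`, `harmonic_bins`,
#'   `expected_amplitudes`.
#' @export
fourier_localizer <- function(x, period_s = 12, sampling_s = 1, stim_on_s = 5,
                              hrf_peak_s = 6, hrf_undershoot_s = 16,
                              hrf_ratio = 1 / 6, threshold = NULL,
                              alpha = 0.05, nsim = 500, seed = 1L) {
  v <- .as_vox_t(x)
  T_ <- ncol(v$m)
  if (T_ * sampling_s < 2 * period_s)
    stop("series must span at least two paradigm cycles", call. = FALSE)
  cycles <- T_ * sampling_s / period_s
  if (abs(cycles - round(cycles)) > 1e-6)
    stop("series length must hold an integer number of paradigm cycles",
         call. = FALSE)
  cycles <- round(cycles)
  # expected response: boxcar convolved with the canonical HRF
  t_grid <- (seq_len(T_) - 1) * sampling_s
  box <- as.numeric((t_grid %% period_s) < stim_on_s)
  hrf <- canonical_hrf(seq(0, 32, by = sampling_s), hrf_peak_s,
                       hrf_undershoot_s, hrf_ratio)
  expc <- stats::convolve(box, rev(hrf), type = "open")[seq_len(T_)]
  nyq <- floor(T_ / 2)
  harm <- seq(cycles, nyq, by = cycles)           # spectral bins (cycles/series)
  amp_expected <- Mod(stats::fft(expc - mean(expc)))[harm + 1L]
  e <- amp_expected / sqrt(sum(amp_expected^2))

  stat_of <- function(m) {
    a <- Mod(stats::mvfft(t(m - rowMeans(m))))[2:(nyq + 1L), , drop = FALSE]
    on <- a[harm, , drop = FALSE]
    off <- a[-harm, , drop = FALSE]
    num <- as.numeric(crossprod(on, e))
    den <- sqrt(colMeans(off^2))
    ifelse(den == 0, 0, num / den)
  }
  stat <- stat_of(v$m)
  if (is.null(threshold)) {
    null_stat <- with_seed(seed, {
      stat_of(matrix(stats::rnorm(nsim * T_), nsim, T_))
    })
    threshold <- as.numeric(stats::quantile(null_stat, 1 - alpha))
  }
  res <- list(stat = if (!is.null(v$dim)) matrix(stat, v$dim[1], v$dim[2]) else stat,
              mask = if (!is.null(v$dim)) matrix(stat > threshold, v$dim[1], v$dim[2])
                     else stat > threshold,
              threshold = threshold, harmonic_bins = harm,
              expected_amplitudes = amp_expected)
  class(res) <- "localizer_result"
  res
}

#' @export
print.localizer_result <- function(x, ...) {
  cat(sprintf("Fourier localizer: %d voxels, threshold %.3f, %d above threshold\n",
              length(x$stat), x$threshold, sum(x$mask)))
  invisible(x)
}
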