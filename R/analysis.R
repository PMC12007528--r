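#' Per-trial normalization of loop-swapped k-space
#'
#' In a loop-swapped run each trial contributes exactly one phase-encode line
#' at all M time points, so "normalizing each trial by its mean signal"
#' operates per line: every complex sample of line `n` is divided by that
#' line's normalization factor, the mean over the M time points of the line's
#' root-sum-square magnitude. A slow global drift, which scales whole trials,
#' is thereby removed exactly for a static object (up to the small within-trial
#' drift, which the later linear detrending absorbs).
#'
#' Dividing a line by its own magnitude whitens the k-space profile, so when a
#' per-line `reference` magnitude is supplied (normally the across-run mean of
#' that line's factor, see [normalize_scan()]) each line is re-scaled to it,
#' which removes the trial-wise drift scale while preserving the image
#' structure.
#'
#' @param kspace A `kspace_series` acquired in loop-swapped (`diana`) mode.
#' @param reference Optional numeric vector of per-line reference magnitudes
#'   by which lines are re-scaled after unit normalization.
#' @return A normalized `kspace_series`; the per-line factors are attached as
#'   attribute `"factors"`.
#' @export
normalize_trials <- function(kspace, reference = NULL) {
  stopifnot(inherits(kspace, "kspace_series"))
  if (kspace$mode != "diana")
    stop("per-trial normalization is defined for loop-swapped (diana) runs",
         call. = FALSE)
  if (anyNA(kspace$k)) stop("k-space is undersampled", call. = FALSE)
  fac <- trial_factors(kspace)
  scale <- if (is.null(reference)) 1 / fac else reference / fac
  for (n in seq_len(dim(kspace$k)[1]))
    kspace$k[n, , ] <- kspace$k[n, , ] * scale[n]
  attr(kspace, "factors") <- fac
  kspace
}

#' Per-trial normalization factors of a loop-swapped run
#'
#' @param kspace A loop-swapped `kspace_series`.
#' @return Numeric vector: for each phase line, the mean over the M time
#'   points of the line's root-sum-square magnitude. Zero-energy lines are an
#'   error.
#' @export
trial_factors <- function(kspace) {
  d <- dim(kspace$k)
  fac <- numeric(d[1])
  for (n in seq_len(d[1])) {
    rss <- sqrt(colSums(Mod(array(kspace$k[n, , ], dim = d[2:3]))^2))
    fac[n] <- mean(rss)
    if (fac[n] == 0)
      stop(sprintf("phase line %d has zero energy; cannot normalize", n),
           call. = FALSE)
  }
  fac
}

#' Per-trial normalization of a scan of loop-swapped runs
#'
#' Normalizes every trial (line) of every run by its own mean-signal factor
#' and re-scales it to the across-run mean factor of that line. The trial-wise
#' drift scale — including the inter-run step — is removed while the k-space
#' magnitude profile, and hence the reconstructed image, is preserved.
#'
#' @param runs List of loop-swapped `kspace_series` (one scan).
#' @return List of normalized `kspace_series`.
#' @export
normalize_scan <- function(runs) {
  if (length(runs) == 0L) return(runs)
  fac <- vapply(runs, trial_factors, numeric(dim(runs[[1]]$k)[1]))
  ref <- rowMeans(fac)
  lapply(runs, normalize_trials, reference = ref)
}

# coerce image_series/array/matrix to voxels x T plus reshape info
.as_vox_t <- function(x) {
  if (inherits(x, "image_series")) x <- x$data
  if (is.array(x) && length(dim(x)) == 3L) {
    d <- dim(x)
    list(m = matrix(x, d[1] * d[2], d[3]), dim = d)
  } else if (is.matrix(x)) {
    list(m = x, dim = NULL)
  } else {
    list(m = matrix(x, 1L), dim = NULL)
  }
}

.restore <- function(m, info, x_in) {
  if (!is.null(info$dim)) {
    out <- array(m, dim = info$dim)
  } else if (is.matrix(x_in)) out <- m
  else out <- drop(m)
  out
}

#' Percent signal change
#'
#' Converts each voxel's time course to
#' `100 * (s(t) - baseline) / baseline`, with the baseline the temporal mean
#' of that voxel's series. Scale-invariant; constant series map to all zeros.
#' Voxels with zero baseline are returned as all zeros.
#'
#' @param x An [image_series()], a 3D array, a voxels-by-time matrix, or a
#'   vector.
#' @return Same shape as the input, in percent units.
#' @export
percent_change <- function(x) {
  v <- .as_vox_t(x)
  b <- rowMeans(v$m)
  out <- 100 * (v$m - b) / ifelse(b == 0, 1, b)
  out[b == 0, ] <- 0
  .restore(out, v, x)
}

#' Remove a least-squares linear trend per voxel
#'
#' The fitted line's slope component is removed and the original mean is kept,
#' so percent-change semantics persist. Idempotent; a pure ramp becomes
#' constant.
#'
#' @inheritParams percent_change
#' @return Same shape as the input.
#' @export
detrend_linear <- function(x) {
  v <- .as_vox_t(x)
  T_ <- ncol(v$m)
  tc <- seq_len(T_) - (T_ + 1) / 2
  denom <- sum(tc^2)
  slope <- (v$m %*% tc) / denom
  out <- v$m - slope %*% matrix(tc, nrow = 1)
  .restore(out, v, x)
}

#' Gaussian temporal smoothing
#'
#' Discrete Gaussian kernel of `window_points` taps (default 3, sigma = 0.6
#' time points, normalized to sum 1) applied along time with reflective
#' boundaries. A 3-tap kernel leaves constants unchanged and reproduces its
#' taps on a unit impulse.
#'
#' @inheritParams percent_change
#' @param window_points Odd kernel length.
#' @param sigma Kernel standard deviation in time points.
#' @return Same shape as the input.
#' @export
smooth_gaussian <- function(x, window_points = 3, sigma = 0.6) {
  if (window_points %% 2 != 1 || window_points < 1)
    stop("window_points must be a positive odd number", call. = FALSE)
  v <- .as_vox_t(x)
  T_ <- ncol(v$m)
  h <- (window_points - 1) / 2
  w <- stats::dnorm(seq(-h, h), sd = sigma)
  w <- w / sum(w)
  if (h == 0 || T_ == 1L) return(.restore(v$m, v, x))
  if (T_ <= h) stop("series shorter than the kernel half-width", call. = FALSE)
  # reflective (mirror) padding: ..., x[3], x[2] | x[1], ..., x[T] | x[T-1], ...
  padl <- v$m[, (h + 1):2, drop = FALSE]
  padr <- v$m[, (T_ - 1):(T_ - h), drop = FALSE]
  xp <- cbind(padl, v$m, padr)
  out <- matrix(0, nrow(v$m), T_)
  for (j in seq_along(w))
    out <- out + w[j] * xp[, j:(j + T_ - 1), drop = FALSE]
  .restore(out, v, x)
}

#' Average a voxelwise series over an ROI
#'
#' @param x An [image_series()] or 3D array (voxelwise percent change).
#' @param mask Logical matrix.
#' @return Numeric vector, one value per time point.
#' @export
roi_aggregate <- function(x, mask) {
  if (inherits(x, "image_series")) x <- x$data
  d <- dim(x)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("mask must be a logical matrix matching the image", call. = FALSE)
  if (!any(mask)) stop("empty ROI mask", call. = FALSE)
  m <- matrix(x, d[1] * d[2], d[3])
  colMeans(m[as.vector(mask), , drop = FALSE])
}

#' Mean and confidence interval of ROI time courses across runs
#'
#' Runs are the exchangeable unit: the per-time-point mean is the arithmetic
#' mean over runs and the confidence half-width is
#' `t(1 - (1-level)/2, n_runs - 1) * SE` across runs.
#'
#' @param run_tc Matrix of ROI percent-change time courses, runs x time
#'   points (or a list of equal-length vectors).
#' @param level Confidence level (default 0.95).
#' @param roi ROI name (metadata).
#' @param tr_ms Sampling interval of the time course in ms (metadata).
#' @return An object of class `roi_response` with fields `mean`,
#'   `ci_halfwidth`, `runs`, `n_runs`, `level`, `roi`, `tr_ms`.
#' @export
ci_across_runs <- function(run_tc, level = 0.95, roi = "roi", tr_ms = 5) {
  if (is.list(run_tc)) run_tc <- do.call(rbind, run_tc)
  if (!is.matrix(run_tc) || nrow(run_tc) < 2L)
    stop("run_tc must be a matrix with at least 2 runs", call. = FALSE)
  n <- nrow(run_tc)
  mu <- colMeans(run_tc)
  se <- apply(run_tc, 2, stats::sd) / sqrt(n)
  hw <- stats::qt(1 - (1 - level) / 2, df = n - 1) * se
  structure(list(mean = mu, ci_halfwidth = hw, runs = run_tc, n_runs = n,
                 level = level, roi = roi, tr_ms = tr_ms),
            class = "roi_response")
}

#' @export
print.roi_response <- function(x, ...) {
  cat(sprintf("ROI response '%s': %d time points, %d runs, %.0f%% CI; peak mean %.4f%%\n",
              x$roi, length(x$mean), x$n_runs, 100 * x$level, max(x$mean)))
  invisible(x)
}

#' Pool runs from several subjects into a group ROI response
#'
#' All runs from all subjects are treated as exchangeable units and pooled
#' before the across-run mean and confidence interval are computed.
#'
#' @param responses List of `roi_response` objects (or run matrices).
#' @param level Confidence level.
#' @return An `roi_response` over the pooled runs.
#' @export
group_average <- function(responses, level = 0.95) {
  mats <- lapply(responses, function(r)
    if (inherits(r, "roi_response")) r$runs else r)
  roi <- if (inherits(responses[[1]], "roi_response")) responses[[1]]$roi else "roi"
  tr <- if (inherits(responses[[1]], "roi_response")) responses[[1]]$tr_ms else 5
  ci_across_runs(do.call(rbind, mats), level = level, roi = roi, tr_ms = tr)
}

#' Temporal SNR map
#'
#' Per-voxel temporal mean divided by temporal standard deviation over the
#' run's time points. Voxels with zero variance are flagged invalid (`NA` in
#' the map) rather than reported as infinite.
#'
#' @param x An [image_series()] or 3D array.
#' @return An object of class `tsnr_map` with `map` (matrix, `NA` where
#'   undefined) and `valid` (logical matrix).
#' @export
tsnr <- function(x) {
  if (inherits(x, "image_series")) x <- x$data
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  val <- sdv > 0
  out <- rep(NA_real_, length(mu))
  out[val] <- mu[val] / sdv[val]
  structure(list(map = matrix(out, d[1], d[2]),
                 valid = matrix(val, d[1], d[2])),
            class = "tsnr_map")
}

#' ROI summary of a tSNR map
#'
#' Mean voxelwise tSNR over the (valid) ROI voxels, plus the expected tSNR of
#' the ROI-mean time course under i.i.d. voxel noise, `voxel tSNR * sqrt(V)`.
#'
#' @param map A `tsnr_map` from [tsnr()].
#' @param mask Logical ROI matrix.
#' @return List with `voxel_tsnr`, `n_voxels`, `expected_roi_tsnr`.
#' @export
roi_tsnr <- function(map, mask) {
  stopifnot(inherits(map, "tsnr_map"))
  sel <- mask & map$valid
  if (!any(sel)) stop("no valid voxels in ROI", call. = FALSE)
  v <- sum(mask)
  vt <- mean(map$map[sel])
  list(voxel_tsnr = vt, n_voxels = v, expected_roi_tsnr = vt * sqrt(v))
}

#' tSNR of the ROI-mean time course
#'
#' @param x An [image_series()] or 3D array.
#' @param mask Logical ROI matrix.
#' @return Scalar tSNR of the spatially averaged time course.
#' @export
roi_timecourse_tsnr <- function(x, mask) {
  tc <- roi_aggregate(if (inherits(x, "image_series")) x$data else x, mask)
  s <- stats::sd(tc)
  if (s == 0) stop("ROI-mean time course has zero variance", call. = FALSE)
  mean(tc) / s
}

#' Minimum detectable percent signal change
#'
#' Two-sided one-sample test on the per-time-point ROI mean across runs, under
#' i.i.d. voxel noise: the ROI-and-run averaged noise SD in percent units is
#' `100 / (tsnr * sqrt(V * n_runs))`, so
#' \deqn{\Delta_{min} = \frac{z_{1-\alpha/2} + z_{power}}{tsnr\sqrt{V\,n_{runs}}} \times 100.}
#'
#' @param voxel_tsnr Temporal SNR of a single voxel.
#' @param n_voxels Number of ROI voxels V.
#' @param n_runs Number of runs averaged.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power.
#' @return Minimum detectable amplitude in percent.
#' @examples
#' min_detectable_pct(1000, 25, 30)
#' @export
min_detectable_pct <- function(voxel_tsnr, n_voxels, n_runs, alpha = 0.05,
                               power = 0.8) {
  if (voxel_tsnr <= 0 || n_voxels < 1 || n_runs < 1)
    stop("invalid inputs", call. = FALSE)
  100 * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) /
    (voxel_tsnr * sqrt(n_voxels * n_runs))
}

#' Characterize a trial-averaged evoked response
#'
#' Works on a trial-averaged ROI response (pipeline-smoothed mean and
#' across-run CI). The onset is the first post-stimulus time point opening a
#' run of at least `min_consecutive` consecutive points whose lower CI bound
#' exceeds zero; the duration is the length of that contiguous supra-zero run;
#' the amplitude is the peak of the mean in the post-stimulus window. The
#' consecutivity requirement keeps the false-positive rate of the pointwise
#' (uncorrected) CIs low; the characterization is descriptive, not
#' inferential.
#'
#' @param roi_response An `roi_response` from [ci_across_runs()].
#' @param stim_onset_index 1-based index of the stimulus onset time point.
#' @param min_consecutive Minimum consecutive supra-zero points to declare a
#'   response (default 3).
#' @return An object of class `response_estimate` with `amplitude_pct`,
#'   `onset_ms`, `duration_ms`, `significant`.
#' @export
estimate_response <- function(roi_response, stim_onset_index = 1L,
                              min_consecutive = 3L) {
  stopifnot(inherits(roi_response, "roi_response"))
  mu <- roi_response$mean
  lo <- mu - roi_response$ci_halfwidth
  T_ <- length(mu)
  idx <- stim_onset_index:T_
  amp <- max(mu[idx])
  supra <- lo[idx] > 0
  r <- rle(supra)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= min_consecutive)
  if (length(hit)) {
    first <- hit[1L]
    onset_ms <- (idx[starts[first]] - stim_onset_index) * roi_response$tr_ms
    duration_ms <- r$lengths[first] * roi_response$tr_ms
    significant <- TRUE
  } else {
    onset_ms <- NA_real_
    duration_ms <- NA_real_
    significant <- FALSE
  }
  structure(list(amplitude_pct = amp, onset_ms = onset_ms,
                 duration_ms = duration_ms, significant = significant,
                 min_consecutive = as.integer(min_consecutive)),
            class = "response_estimate")
}

#' @export
print.response_estimate <- function(x, ...) {
  if (x$significant)
    cat(sprintf("response: amplitude %.4f%%, onset %g ms, duration %g ms\n",
                x$amplitude_pct, x$onset_ms, x$duration_ms))
  else
    cat(sprintf("no significant response (peak mean %.4f%%)\n", x$amplitude_pct))
  invisible(x)
}

#' Voxelwise trial-averaged analysis chain
#'
#' Applies, in order: percent signal change, linear detrending, Gaussian
#' temporal smoothing, then ROI averaging. This fixed order is the analysis
#' contract; [ci_across_runs()] is applied across the resulting run-level
#' time courses.
#'
#' @param series An [image_series()] (one reconstructed run) or 3D array.
#' @param mask Logical ROI matrix.
#' @param window_points,sigma Passed to [smooth_gaussian()].
#' @return Numeric ROI percent-change time course.
#' @export
run_roi_timecourse <- function(series, mask, window_points = 3, sigma = 0.6) {
  x <- percent_change(series)
  x <- detrend_linear(x)
  x <- smooth_gaussian(x, window_points = window_points, sigma = sigma)
  roi_aggregate(x, mask)
}

#' Trial-averaged ROI response over several runs
#'
#' @param runs List of [image_series()] (one per retained run).
#' @param mask Logical ROI matrix.
#' @param level Confidence level.
#' @param roi ROI name.
#' @param ... Passed to [run_roi_timecourse()].
#' @return An `roi_response`.
#' @export
analyze_runs <- function(runs, mask, level = 0.95, roi = "roi", ...) {
  tc <- lapply(runs, run_roi_timecourse, mask = mask, ...)
  tr <- if (inherits(runs[[1]], "image_series")) runs[[1]]$tr_ms else 5
  ci_across_runs(do.call(rbind, tc), level = level, roi = roi, tr_ms = tr)
}
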