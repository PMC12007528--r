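#' Construct a digital phantom
#'
#' A digital phantom is a 2D integer label map plus per-compartment tissue
#' parameters and named ROI masks. Voxels with label 0 are background (air)
#' and carry no signal.
#'
#' @param grid Integer matrix (label map), square.
#' @param compartments Named list mapping label (as character) to
#'   [tissue_params()].
#' @param rois Named list of logical matrices with the same dimensions as
#'   `grid`.
#' @return An object of class `digital_phantom`.
#' @export
digital_phantom <- function(grid, compartments, rois = list()) {
  grid <- as.matrix(grid)
  if (nrow(grid) != ncol(grid)) stop("label map must be square", call. = FALSE)
  labs <- sort(unique(as.integer(grid)))
  labs <- labs[labs != 0L]
  for (l in labs)
    if (is.null(compartments[[as.character(l)]]))
      stop(sprintf("label %d has no compartment parameters", l), call. = FALSE)
  for (nm in names(rois)) {
    r <- rois[[nm]]
    if (!is.logical(r) || !identical(dim(r), dim(grid)))
      stop(sprintf("ROI '%s' must be a logical mask matching the grid", nm),
           call. = FALSE)
  }
  structure(list(grid = grid, compartments = compartments, rois = rois),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat(sprintf("digital phantom: %d x %d, %d compartments, ROIs: %s\n",
              nrow(x$grid), ncol(x$grid), length(x$compartments),
              paste(names(x$rois), collapse = ", ")))
  invisible(x)
}

# deterministic disc mask
.disc <- function(n, cx, cy, r) {
  xx <- matrix(seq_len(n), n, n)
  yy <- matrix(seq_len(n), n, n, byrow = TRUE)
  (xx - cx)^2 + (yy - cy)^2 <= r^2
}

#' Build a default digital phantom
#'
#' Two presets are provided. `"brain_slice"` is an oblique-axial-like slice
#' with CSF rim, cortical gray-matter ribbon and white-matter core, a target
#' gray-matter ROI at the posterior midline (calcarine-like, `target_v1`), a
#' gray-matter control ROI with exactly the same number of voxels as the
#' target (matched for statistical power) and a white-matter control ROI.
#' `"tubes"` mimics a stability phantom of centrifuge tubes doped to distinct
#' T1 values; it carries one ROI per tube plus their union (`tubes`).
#' Construction is fully deterministic.
#'
#' Tissue parameters are 7 T-like defaults: WM T1 1200 ms / T2* 26 ms /
#' PD 0.70; GM 2000 / 33 / 0.80; CSF 4300 / 100 / 1.00.
#'
#' @param matrix_size Grid size, 96 or 192.
#' @param preset `"brain_slice"` or `"tubes"`.
#' @return A [digital_phantom()].
#' @examples
#' ph <- make_default_phantom(96, "brain_slice")
#' sum(ph$rois$target_v1) == sum(ph$rois$control_gm)
#' @export
make_default_phantom <- function(matrix_size = 96,
                                 preset = c("brain_slice", "tubes")) {
  preset <- match.arg(preset)
  if (!matrix_size %in% c(96L, 192L))
    stop("matrix_size must be 96 or 192", call. = FALSE)
  n <- as.integer(matrix_size)
  # slightly off-center, as an oblique slice would be; also avoids the exact
  # reflection symmetry that zeroes individual k-space rows
  cx <- (n + 1) / 2 + 0.021 * n
  cy <- (n + 1) / 2 - 0.034 * n
  if (preset == "brain_slice") {
    head_r <- 0.42 * n
    csf_r <- 0.40 * n
    wm_r <- 0.30 * n
    grid <- matrix(0L, n, n)
    grid[.disc(n, cx, cy, head_r)] <- 1L            # CSF rim
    grid[.disc(n, cx, cy, csf_r)]  <- 2L            # cortical GM ribbon
    grid[.disc(n, cx + 0.012 * n, cy, wm_r)] <- 3L  # WM core
    gm <- grid == 2L
    wm <- grid == 3L
    xx <- matrix(seq_len(n), n, n)
    yy <- matrix(seq_len(n), n, n, byrow = TRUE)
    # target: posterior (large y) midline wedge of the GM ribbon
    target <- gm & yy > cy + 0.31 * n & abs(xx - cx) < 0.12 * n
    v <- sum(target)
    # GM control: anterior GM voxels, count matched to the target
    cand <- which(gm & yy < cy - 0.28 * n)
    ord <- cand[order(yy[cand], xx[cand])]
    control_gm <- matrix(FALSE, n, n)
    if (length(ord) < v) stop("phantom geometry: not enough anterior GM voxels")
    control_gm[ord[seq_len(v)]] <- TRUE
    # WM control: disc in the anterior WM core
    control_wm <- wm & .disc(n, cx, cy - 0.18 * n, 0.07 * n)
    comps <- list(
      "1" = tissue_params(t1_ms = 4300, t2s_ms = 100, pd = 1.00),  # CSF
      "2" = tissue_params(t1_ms = 2000, t2s_ms = 33,  pd = 0.80),  # GM
      "3" = tissue_params(t1_ms = 1200, t2s_ms = 26,  pd = 0.70)   # WM
    )
    digital_phantom(grid, comps,
                    rois = list(target_v1 = target, control_gm = control_gm,
                                control_wm = control_wm,
                                brain = grid > 0L))
  } else {
    # four tubes with distinct T1 (manganese-chloride-like doping series);
    # distinct radii keep the layout free of exact symmetries
    grid <- matrix(0L, n, n)
    centers <- rbind(c(cx - 0.20 * n, cy - 0.19 * n),
                     c(cx + 0.21 * n, cy - 0.20 * n),
                     c(cx - 0.19 * n, cy + 0.21 * n),
                     c(cx + 0.20 * n, cy + 0.20 * n))
    radii <- c(0.12, 0.13, 0.14, 0.15) * n
    rois <- list()
    for (i in 1:4) {
      m <- .disc(n, centers[i, 1], centers[i, 2], radii[i])
      grid[m] <- i
      rois[[paste0("tube_", i)]] <- m
    }
    rois$tubes <- grid > 0L
    comps <- list(
      "1" = tissue_params(t1_ms = 300,  t2s_ms = 20, pd = 1),
      "2" = tissue_params(t1_ms = 800,  t2s_ms = 30, pd = 1),
      "3" = tissue_params(t1_ms = 1500, t2s_ms = 40, pd = 1),
      "4" = tissue_params(t1_ms = 3000, t2s_ms = 50, pd = 1)
    )
    digital_phantom(grid, comps, rois = rois)
  }
}

#' Functional response model
#'
#' A phenomenological percent-signal-change pulse applied multiplicatively to
#' the steady-state baseline inside a trial, in a subset of voxels. The shape
#' is a boxcar (default) or a half-sine over `[onset, onset + duration)` of
#' trial phase. Amplitude 0 gives null data. No biophysical mechanism is
#' implied; this is the injected ground truth for recovery tests.
#'
#' @param amplitude_pct Peak percent signal change (may be 0).
#' @param onset_ms Latency after stimulus onset (trial phase 0), >= 0.
#' @param duration_ms Response duration in ms, > 0.
#' @param shape `"boxcar"` or `"half_sine"`.
#' @param active_roi Name of the phantom ROI carrying the response, or
#'   `"all"` for every non-background voxel.
#' @return An object of class `response_model`.
#' @export
response_model <- function(amplitude_pct = 0.05, onset_ms = 75,
                           duration_ms = 150,
                           shape = c("boxcar", "half_sine"),
                           active_roi = "target_v1") {
  shape <- match.arg(shape)
  if (onset_ms < 0) stop("onset_ms must be >= 0", call. = FALSE)
  if (duration_ms <= 0) stop("duration_ms must be > 0", call. = FALSE)
  structure(list(amplitude_pct = amplitude_pct, onset_ms = onset_ms,
                 duration_ms = duration_ms, shape = shape,
                 active_roi = active_roi),
            class = "response_model")
}

#' Scanner drift model
#'
#' Linear multiplicative drift applied identically to all voxels:
#' the signal at absolute time `t` seconds is scaled by
#' `1 + rate_pct_per_min * (t - t0_s) / 60 / 100`.
#'
#' @param rate_pct_per_min Drift rate in percent per minute.
#' @param t0_s Reference time in seconds (drift factor 1 there).
#' @return An object of class `drift_model`.
#' @export
drift_model <- function(rate_pct_per_min = 0, t0_s = 0) {
  structure(list(rate_pct_per_min = rate_pct_per_min, t0_s = t0_s),
            class = "drift_model")
}

#' Noise model
#'
#' Thermal noise is white Gaussian, added per sample with a standard deviation
#' expressed as a percent of each voxel's baseline. Low-frequency
#' physiological fluctuations are modelled as additive sinusoids (fraction of
#' baseline) at fixed frequencies and phases. Draws are reproducible given
#' `seed`; the per-trial stream is seeded with `seed + trial_index`.
#'
#' The default model is silent (no thermal, no physiological component) so
#' that noise is always an explicit choice; [physio_default()] supplies a
#' plausible respiratory + cardiac pair for realism-oriented runs.
#'
#' @param thermal_sigma_pct White-noise SD as percent of baseline (>= 0).
#' @param physio `NULL` or a data.frame with columns `freq_hz`,
#'   `amplitude_pct`, `phase_rad`.
#' @param seed Integer random seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(thermal_sigma_pct = 0, physio = NULL, seed = 1L) {
  if (thermal_sigma_pct < 0) stop("thermal_sigma_pct must be >= 0", call. = FALSE)
  if (!is.null(physio)) {
    need <- c("freq_hz", "amplitude_pct", "phase_rad")
    if (!is.data.frame(physio) || !all(need %in% names(physio)))
      stop("physio must be a data.frame with freq_hz, amplitude_pct, phase_rad",
           call. = FALSE)
    if (any(physio$freq_hz < 0)) stop("physio frequencies must be >= 0", call. = FALSE)
  }
  structure(list(thermal_sigma_pct = thermal_sigma_pct, physio = physio,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Default physiological fluctuation components
#'
#' One respiratory (0.3 Hz) and one cardiac (1.0 Hz) sinusoid at 0.05%
#' amplitude each. These are plausibility placeholders for property tests,
#' not measured spectra.
#'
#' @return A data.frame usable as the `physio` argument of [noise_model()].
#' @export
physio_default <- function() {
  data.frame(freq_hz = c(0.3, 1.0), amplitude_pct = c(0.05, 0.05),
             phase_rad = c(0, pi / 3))
}

#' Rigid in-plane motion model
#'
#' Either a fixed table of per-trial rigid parameters or a seeded random walk.
#'
#' @param type `"none"`, `"fixed"` or `"random_walk"`.
#' @param per_trial For `"fixed"`: data.frame with columns `dx_px`, `dy_px`,
#'   `theta_deg`, one row per trial.
#' @param step_px Random-walk step SD in pixels per trial.
#' @param step_deg Random-walk step SD in degrees per trial.
#' @param seed Integer seed for the random walk.
#' @return An object of class `motion_model`.
#' @export
motion_model <- function(type = c("none", "fixed", "random_walk"),
                         per_trial = NULL, step_px = 0.2, step_deg = 0.05,
                         seed = 1L) {
  type <- match.arg(type)
  if (type == "fixed") {
    need <- c("dx_px", "dy_px", "theta_deg")
    if (!is.data.frame(per_trial) || !all(need %in% names(per_trial)))
      stop("per_trial must be a data.frame with dx_px, dy_px, theta_deg",
           call. = FALSE)
  }
  structure(list(type = type, per_trial = per_trial, step_px = step_px,
                 step_deg = step_deg, seed = as.integer(seed)),
            class = "motion_model")
}

#' Realize per-trial motion parameters
#'
#' @param motion A [motion_model()].
#' @param n_trials Number of trials to realize.
#' @return data.frame with `dx_px`, `dy_px`, `theta_deg`, one row per trial;
#'   deterministic given the model's seed.
#' @export
realize_motion <- function(motion, n_trials) {
  if (is.null(motion) || motion$type == "none")
    return(data.frame(dx_px = rep(0, n_trials), dy_px = rep(0, n_trials),
                      theta_deg = rep(0, n_trials)))
  if (motion$type == "fixed") {
    pt <- motion$per_trial
    if (nrow(pt) < n_trials)
      stop("fixed motion table has fewer rows than trials", call. = FALSE)
    return(pt[seq_len(n_trials), c("dx_px", "dy_px", "theta_deg")])
  }
  with_seed(motion$seed, {
    data.frame(dx_px = cumsum(stats::rnorm(n_trials, 0, motion$step_px)),
               dy_px = cumsum(stats::rnorm(n_trials, 0, motion$step_px)),
               theta_deg = cumsum(stats::rnorm(n_trials, 0, motion$step_deg)))
  })
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Steady-state baseline image of a phantom
#'
#' Per-voxel ideal-spoiling SPGRE signal
#' `pd * sin(alpha) * Mss(T1) * exp(-TE/T2*)`; background voxels are 0.
#'
#' @param phantom A [digital_phantom()].
#' @param seq A [seq_params()].
#' @return Numeric matrix.
#' @export
baseline_image <- function(phantom, seq) {
  stopifnot(inherits(phantom, "digital_phantom"))
  img <- matrix(0, nrow(phantom$grid), ncol(phantom$grid))
  for (lab in names(phantom$compartments)) {
    m <- phantom$grid == as.integer(lab)
    if (any(m)) img[m] <- spgre_signal(seq, phantom$compartments[[lab]])
  }
  img
}

# response gain (multiplicative factor - 1) at a vector of trial phases (ms)
.response_gain <- function(response, phase_ms) {
  if (is.null(response) || response$amplitude_pct == 0)
    return(rep(0, length(phase_ms)))
  inside <- phase_ms >= response$onset_ms &
    phase_ms < response$onset_ms + response$duration_ms
  g <- rep(0, length(phase_ms))
  if (response$shape == "boxcar") {
    g[inside] <- response$amplitude_pct / 100
  } else {
    u <- (phase_ms[inside] - response$onset_ms) / response$duration_ms
    g[inside] <- response$amplitude_pct / 100 * sin(pi * u)
  }
  g
}

.drift_factor <- function(drift, t_s) {
  if (is.null(drift)) return(rep(1, length(t_s)))
  1 + drift$rate_pct_per_min * (t_s - drift$t0_s) / 60 / 100
}

.physio_term <- function(noise, t_s) {
  if (is.null(noise) || is.null(noise$physio) || nrow(noise$physio) == 0L)
    return(rep(0, length(t_s)))
  out <- rep(0, length(t_s))
  for (i in seq_len(nrow(noise$physio)))
    out <- out + noise$physio$amplitude_pct[i] / 100 *
      sin(2 * pi * noise$physio$freq_hz[i] * t_s + noise$physio$phase_rad[i])
  out
}

.active_mask <- function(phantom, response) {
  if (is.null(response)) return(matrix(FALSE, nrow(phantom$grid), ncol(phantom$grid)))
  if (identical(response$active_roi, "all")) return(phantom$grid > 0L)
  m <- phantom$rois[[response$active_roi]]
  if (is.null(m))
    stop(sprintf("phantom has no ROI named '%s'", response$active_roi),
         call. = FALSE)
  m
}

#' Per-voxel signal of one trial
#'
#' Evaluates the phantom's instantaneous image at each of the M time points of
#' trial `trial_index` (0-based) of a loop-swapped run. Sample m (0-based) of
#' trial k occurs at absolute time
#' `run_start_s + (n_dummy + k*M + m) * TR` and at trial phase `m * TR`, with
#' the stimulus onset anchored at trial phase 0. The signal is
#' `baseline * (1 + response_gain) * drift_factor + baseline * physio + thermal`.
#'
#' @param phantom A [digital_phantom()].
#' @param seq A [seq_params()] (supplies TR, TE, FA and `n_dummy`).
#' @param paradigm A [paradigm()] (supplies M).
#' @param response A [response_model()] or `NULL`.
#' @param drift A [drift_model()] or `NULL`.
#' @param noise A [noise_model()] or `NULL`.
#' @param trial_index 0-based trial index within the run.
#' @param run_start_s Absolute start time of the run's dummy period, seconds.
#' @return Numeric array `matrix_size x matrix_size x M`.
#' @export
voxel_timeseries <- function(phantom, seq, paradigm, response = NULL,
                             drift = NULL, noise = NULL, trial_index = 0L,
                             run_start_s = 0) {
  stopifnot(inherits(phantom, "digital_phantom"), inherits(seq, "seq_params"),
            inherits(paradigm, "paradigm"))
  m_tp <- paradigm$trial_timepoints_m
  if (trial_index < 0 || trial_index >= paradigm$matrix_n)
    stop("trial_index must lie in [0, N)", call. = FALSE)
  tr_s <- seq$tr_ms / 1000
  mvec <- 0:(m_tp - 1L)
  t_abs <- run_start_s + (seq$n_dummy + trial_index * m_tp + mvec) * tr_s
  phase_ms <- mvec * seq$tr_ms
  base <- baseline_image(phantom, seq)
  act <- .active_mask(phantom, response)
  gain <- .response_gain(response, phase_ms)
  dfac <- .drift_factor(drift, t_abs)
  pfac <- .physio_term(noise, t_abs)
  n <- nrow(base)
  out <- array(0, dim = c(n, n, m_tp))
  sigma <- if (is.null(noise)) 0 else noise$thermal_sigma_pct
  frames <- lapply(seq_len(m_tp), function(j) {
    img <- base * (1 + gain[j] * act) * dfac[j] + base * pfac[j]
    img
  })
  if (sigma > 0) {
    frames <- with_seed(noise$seed + as.integer(trial_index), {
      lapply(frames, function(img) img + base * sigma / 100 *
               matrix(stats::rnorm(n * n), n, n))
    })
  }
  for (j in seq_len(m_tp)) out[, , j] <- frames[[j]]
  out
}
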