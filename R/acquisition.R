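#' Number of time points per trial
#'
#' One trial spans one stimulus plus one interstimulus interval; with the
#' measurement loop innermost it is sampled every TR, so
#' `M = (stim_ms + isi_ms) / tr_ms`. The trial duration must be divisible by
#' TR.
#'
#' @param stim_ms Stimulus duration in ms.
#' @param isi_ms Interstimulus interval in ms.
#' @param tr_ms Repetition time in ms.
#' @return Integer M.
#' @examples
#' trial_timepoints(100, 600, 5)  # 140
#' trial_timepoints(50, 550, 5)   # 120
#' @export
trial_timepoints <- function(stim_ms, isi_ms, tr_ms) {
  tot <- stim_ms + isi_ms
  if (tot <= 0 || tr_ms <= 0) stop("durations must be positive", call. = FALSE)
  m <- tot / tr_ms
  if (abs(m - round(m)) > 1e-9)
    stop("stim_ms + isi_ms must be divisible by tr_ms", call. = FALSE)
  as.integer(round(m))
}

#' Duration of one fully sampled loop-swapped run
#'
#' `N * M * TR`, the minimum time to collect one fully sampled dataset when
#' each of the N trials contributes one phase-encode line for each of the M
#' images.
#'
#' @param N Number of phase-encoding lines.
#' @param M Number of time points per trial.
#' @param tr_ms Repetition time in ms.
#' @return Duration in seconds.
#' @examples
#' run_duration_s(96, 140, 5)  # 67.2
#' @export
run_duration_s <- function(N, M, tr_ms) {
  if (N < 1 || M < 1 || tr_ms <= 0) stop("inputs must be positive", call. = FALSE)
  N * M * tr_ms / 1000
}

#' Duration of a scan (dummy period plus consecutive runs)
#'
#' `n_dummy * TR + n_runs * N * M * TR`, in seconds.
#'
#' @param n_runs Number of runs in the scan.
#' @param n_dummy Number of dummy excitations at the start of the scan.
#' @param N,M,tr_ms As in [run_duration_s()].
#' @return Duration in seconds.
#' @examples
#' scan_duration_s(11, 2000, 96, 140, 5)  # 749.2 s, about 12.5 min
#' @export
scan_duration_s <- function(n_runs, n_dummy, N, M, tr_ms) {
  if (n_runs < 0 || n_dummy < 0 || tr_ms <= 0)
    stop("invalid inputs", call. = FALSE)
  (n_dummy + n_runs * N * M) * tr_ms / 1000
}

#' Initial conventional SPGRE images to discard
#'
#' Given a settling budget expressed in TRs, the number of whole images
#' (N lines each) that must be dropped: `ceiling(n_settle_trs / N)`.
#'
#' @param n_settle_trs Number of TRs needed to reach steady state.
#' @param N Lines per image.
#' @return Integer count.
#' @examples
#' spgre_discard_count(2000, 96)  # 21
#' @export
spgre_discard_count <- function(n_settle_trs, N) {
  if (n_settle_trs < 0 || N < 1) stop("invalid inputs", call. = FALSE)
  as.integer(ceiling(n_settle_trs / N))
}

#' Functional paradigm definition
#'
#' Stimulus timing, run/scan structure and matrix size of one experimental
#' paradigm. `trial_timepoints_m` is derived as
#' `(stim_ms + isi_ms) / tr_ms`, which must be an integer.
#'
#' @param name Paradigm label.
#' @param stim_ms Stimulus duration (ms).
#' @param isi_ms Interstimulus interval (ms).
#' @param tr_ms Repetition time (ms).
#' @param matrix_n Number of phase-encode lines N (= matrix size).
#' @param n_runs_per_scan Runs acquired per scan.
#' @param n_scans Number of scans.
#' @param n_subjects Number of subjects (metadata).
#' @param resolution Resolution label (metadata), e.g. `"2x2x5mm"`.
#' @return An object of class `paradigm`.
#' @export
paradigm <- function(name, stim_ms, isi_ms, tr_ms = 5, matrix_n = 96,
                     n_runs_per_scan = 11, n_scans = 3, n_subjects = 1,
                     resolution = "2x2x5mm") {
  m <- trial_timepoints(stim_ms, isi_ms, tr_ms)
  structure(list(name = name, stim_ms = stim_ms, isi_ms = isi_ms,
                 tr_ms = tr_ms, matrix_n = as.integer(matrix_n),
                 trial_timepoints_m = m,
                 n_runs_per_scan = as.integer(n_runs_per_scan),
                 n_scans = as.integer(n_scans),
                 n_subjects = as.integer(n_subjects),
                 resolution = resolution),
            class = "paradigm")
}

#' @export
print.paradigm <- function(x, ...) {
  cat(sprintf("paradigm '%s': stim %g ms + ISI %g ms at TR %g ms -> M = %d; N = %d; %d runs x %d scans; %s\n",
              x$name, x$stim_ms, x$isi_ms, x$tr_ms, x$trial_timepoints_m,
              x$matrix_n, x$n_runs_per_scan, x$n_scans, x$resolution))
  invisible(x)
}

#' Named paradigm presets
#'
#' The five visual paradigms (I-V): flickering-noise or naturalistic-image
#' stimuli of 50-200 ms with 500-600 ms ISIs at TR = 5 ms, matrix 96 (2 x 2 x
#' 5 mm) or 192 (1 x 1 x 5 mm). Paradigm V is generated fully sampled at
#' matrix 192 (parallel-imaging acceleration is out of scope). A
#' `"phantom_tubes"` preset mirrors the tube-phantom stability protocol
#' (700 ms trials, 4 runs per scan, 2 scans).
#'
#' @param name One of `"paradigm_I"` ... `"paradigm_V"`, `"phantom_tubes"`.
#' @return A [paradigm()].
#' @examples
#' paradigm_preset("paradigm_III")
#' @export
paradigm_preset <- function(name) {
  switch(name,
    paradigm_I = paradigm("paradigm_I", stim_ms = 50, isi_ms = 550,
                          matrix_n = 96, n_runs_per_scan = 11, n_scans = 3,
                          n_subjects = 1, resolution = "2x2x5mm"),
    paradigm_II = paradigm("paradigm_II", stim_ms = 200, isi_ms = 500,
                           matrix_n = 96, n_runs_per_scan = 10, n_scans = 3,
                           n_subjects = 1, resolution = "2x2x5mm"),
    paradigm_III = paradigm("paradigm_III", stim_ms = 100, isi_ms = 600,
                            matrix_n = 96, n_runs_per_scan = 11, n_scans = 3,
                            n_subjects = 3, resolution = "2x2x5mm"),
    paradigm_IV = paradigm("paradigm_IV", stim_ms = 100, isi_ms = 600,
                           matrix_n = 96, n_runs_per_scan = 11, n_scans = 4,
                           n_subjects = 3, resolution = "2x2x5mm"),
    paradigm_V = paradigm("paradigm_V", stim_ms = 100, isi_ms = 600,
                          matrix_n = 192, n_runs_per_scan = 11, n_scans = 4,
                          n_subjects = 3, resolution = "1x1x5mm"),
    phantom_tubes = paradigm("phantom_tubes", stim_ms = 100, isi_ms = 600,
                             matrix_n = 96, n_runs_per_scan = 4, n_scans = 2,
                             n_subjects = 0, resolution = "2x2x5mm"),
    stop(sprintf("unknown paradigm preset '%s'", name), call. = FALSE)
  )
}

.line_order <- function(N, line_order) {
  if (line_order == "sequential") return(seq_len(N))
  # centric: start at the center line, alternate outwards
  ctr <- N %/% 2 + 1L
  off <- c(0L, as.vector(rbind(seq_len(N), -seq_len(N))))
  ord <- as.integer(ctr + off)
  ord <- ord[ord >= 1L & ord <= N]
  unique(ord)[seq_len(N)]
}

.new_schedule <- function(events, mode, N, M, n_dummy, tr_ms, line_order) {
  structure(list(events = events, mode = mode, N = as.integer(N),
                 M = as.integer(M), n_dummy = as.integer(n_dummy),
                 tr_ms = tr_ms, line_order = line_order),
            class = "acq_schedule")
}

#' @export
print.acq_schedule <- function(x, ...) {
  cat(sprintf("%s schedule: N = %d, M = %d, %d dummies, %d events, TR = %g ms\n",
              toupper(x$mode), x$N, x$M, x$n_dummy, nrow(x$events), x$tr_ms))
  invisible(x)
}

#' Loop-swapped (DIANA) acquisition schedule
#'
#' With the phase and measurement loops swapped, trial `k` (one stimulus +
#' ISI cycle) samples one phase-encode line at all M trial time points
#' consecutively; N trials fill the N lines of each of the M images. The
#' k-space center line is therefore crossed M times in quick succession within
#' a single trial and not revisited until `N * M * TR` later.
#'
#' @param N Number of phase-encode lines (>= 1).
#' @param M Time points per trial (>= 1).
#' @param n_dummy Dummy excitations preceding the first event.
#' @param tr_ms Repetition time (ms).
#' @param line_order `"sequential"` (default) or `"centric"`.
#' @param start_time_s Absolute time at which the dummy period starts.
#' @return An `acq_schedule` whose `events` data.frame has columns
#'   `phase_line`, `time_point`, `trial_index` (1-based) and
#'   `absolute_time_s`, in acquisition order (times increase by TR).
#' @examples
#' s <- diana_schedule(96, 140, n_dummy = 2000)
#' nrow(s$events)  # 13440
#' @export
diana_schedule <- function(N, M, n_dummy = 0, tr_ms = 5,
                           line_order = c("sequential", "centric"),
                           start_time_s = 0) {
  line_order <- match.arg(line_order)
  if (N < 1 || M < 1) stop("N and M must be >= 1", call. = FALSE)
  ord <- .line_order(N, line_order)
  trial <- rep(seq_len(N), each = M)
  ev <- data.frame(
    phase_line = rep(ord, each = M),
    time_point = rep(seq_len(M), times = N),
    trial_index = trial,
    absolute_time_s = start_time_s +
      (n_dummy + seq_len(N * M) - 1) * tr_ms / 1000
  )
  .new_schedule(ev, "diana", N, M, n_dummy, tr_ms, line_order)
}

#' Conventional SPGRE acquisition schedule
#'
#' Phase loop innermost: each image collects its N lines consecutively, so
#' the k-space center is crossed once every `N * TR`.
#'
#' @param N Number of phase-encode lines.
#' @param n_images Number of sequential images.
#' @param n_dummy Dummy excitations preceding the first event.
#' @param tr_ms Repetition time (ms).
#' @param line_order `"sequential"` or `"centric"`.
#' @param start_time_s Absolute time at which the dummy period starts.
#' @return An `acq_schedule`; `time_point` indexes the image.
#' @export
spgre_schedule <- function(N, n_images, n_dummy = 0, tr_ms = 5,
                           line_order = c("sequential", "centric"),
                           start_time_s = 0) {
  line_order <- match.arg(line_order)
  if (N < 1 || n_images < 1) stop("N and n_images must be >= 1", call. = FALSE)
  ord <- .line_order(N, line_order)
  ev <- data.frame(
    phase_line = rep(ord, times = n_images),
    time_point = rep(seq_len(n_images), each = N),
    trial_index = rep(seq_len(n_images), each = N),
    absolute_time_s = start_time_s +
      (n_dummy + seq_len(N * n_images) - 1) * tr_ms / 1000
  )
  .new_schedule(ev, "spgre", N, n_images, n_dummy, tr_ms, line_order)
}

#' Sample k-space from the phantom along an acquisition schedule
#'
#' For every scheduled event the instantaneous phantom image at that event's
#' absolute time and trial phase is formed, the trial's rigid motion applied,
#' and the scheduled row of its 2D discrete Fourier transform stored. The
#' readout direction is fully sampled at the matrix size. Trial phase is the
#' event time relative to its trial start (loop-swapped mode; stimulus onset
#' at phase 0); conventional SPGRE events carry no functional response unless
#' `sync_response = TRUE`, in which case phase is the absolute time modulo the
#' trial duration.
#'
#' A closed-form fast path (no per-voxel noise, no motion) exploits the
#' linearity of the DFT: the k-space row is assembled from the transforms of
#' the baseline image and of the response-carrying voxels, scaled by the
#' event's drift/response/physiological factors.
#'
#' @param phantom A [digital_phantom()]; grid size must equal the schedule N.
#' @param seq A [seq_params()].
#' @param schedule An `acq_schedule` from [diana_schedule()] or
#'   [spgre_schedule()].
#' @param response,drift,noise,motion Optional model objects.
#' @param sync_response Apply the response to SPGRE schedules by absolute-time
#'   trial phase (default `FALSE`).
#' @return An object of class `kspace_series`: complex array `k` of dimension
#'   `N x N x n_timepoints` (phase line x readout sample x time point), plus
#'   the schedule and sequence.
#' @export
simulate_acquisition <- function(phantom, seq, schedule, response = NULL,
                                 drift = NULL, noise = NULL, motion = NULL,
                                 sync_response = FALSE) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(schedule, "acq_schedule"))
  N <- schedule$N
  if (nrow(phantom$grid) != N)
    stop("phantom matrix size does not match schedule N", call. = FALSE)
  ev <- schedule$events
  n_tp <- max(ev$time_point)
  tr_s <- schedule$tr_ms / 1000
  trial_dur_ms <- schedule$M * schedule$tr_ms

  # trial phase in ms per event
  if (schedule$mode == "diana") {
    phase_ms <- (ev$time_point - 1) * schedule$tr_ms
    use_response <- !is.null(response)
  } else {
    phase_ms <- (ev$absolute_time_s * 1000) %% trial_dur_ms
    use_response <- !is.null(response) && sync_response
  }
  resp <- if (use_response) response else NULL

  base <- baseline_image(phantom, seq)
  act <- .active_mask(phantom, resp)
  gain <- .response_gain(resp, phase_ms)
  dfac <- .drift_factor(drift, ev$absolute_time_s)
  pfac <- .physio_term(noise, ev$absolute_time_s)
  mot <- realize_motion(motion, max(ev$trial_index))
  moving <- any(mot$dx_px != 0 | mot$dy_px != 0 | mot$theta_deg != 0)
  sigma <- if (is.null(noise)) 0 else noise$thermal_sigma_pct

  k <- array(NA_complex_, dim = c(N, N, n_tp))
  if (!moving && sigma == 0) {
    f_base <- stats::fft(base)
    f_act <- if (any(act)) stats::fft(base * act) else NULL
    for (i in seq_len(nrow(ev))) {
      row <- ev$phase_line[i]
      line <- (dfac[i] + pfac[i]) * f_base[row, ]
      if (!is.null(f_act) && gain[i] != 0)
        line <- line + dfac[i] * gain[i] * f_act[row, ]
      k[row, , ev$time_point[i]] <- line
    }
  } else {
    sim_one <- function(i) {
      img <- base * (1 + gain[i] * act) * dfac[i] + base * pfac[i]
      if (sigma > 0)
        img <- img + base * sigma / 100 * matrix(stats::rnorm(N * N), N, N)
      tr_i <- ev$trial_index[i]
      if (moving && (mot$dx_px[tr_i] != 0 || mot$dy_px[tr_i] != 0 ||
                     mot$theta_deg[tr_i] != 0))
        img <- apply_rigid2d(img, mot$dx_px[tr_i], mot$dy_px[tr_i],
                             mot$theta_deg[tr_i])
      stats::fft(img)[ev$phase_line[i], ]
    }
    lines <- if (sigma > 0) {
      with_seed(if (is.null(noise)) 1L else noise$seed,
                lapply(seq_len(nrow(ev)), sim_one))
    } else lapply(seq_len(nrow(ev)), sim_one)
    for (i in seq_len(nrow(ev)))
      k[ev$phase_line[i], , ev$time_point[i]] <- lines[[i]]
  }
  structure(list(k = k, schedule = schedule, seq = seq, mode = schedule$mode),
            class = "kspace_series")
}

#' @export
print.kspace_series <- function(x, ...) {
  d <- dim(x$k)
  cat(sprintf("k-space series (%s): %d lines x %d readout x %d time points; fully sampled: %s\n",
              x$mode, d[1], d[2], d[3], !anyNA(x$k)))
  invisible(x)
}

#' Simulate a scan of consecutive loop-swapped runs
#'
#' One dummy period followed by `n_runs` back-to-back runs; absolute time is
#' continuous across run boundaries so slow drift accumulates between runs
#' (the inter-run step signature).
#'
#' @param phantom,seq,response,drift,noise,motion As in
#'   [simulate_acquisition()].
#' @param paradigm A [paradigm()] giving N and M.
#' @param n_runs Number of runs (default: the paradigm's runs per scan).
#' @param line_order Passed to [diana_schedule()].
#' @param start_time_s Scan start time.
#' @return List of `kspace_series`, one per run.
#' @export
simulate_scan <- function(phantom, seq, paradigm, n_runs = NULL,
                          response = NULL, drift = NULL, noise = NULL,
                          motion = NULL, line_order = "sequential",
                          start_time_s = 0) {
  stopifnot(inherits(paradigm, "paradigm"))
  if (is.null(n_runs)) n_runs <- paradigm$n_runs_per_scan
  N <- paradigm$matrix_n
  M <- paradigm$trial_timepoints_m
  tr_s <- paradigm$tr_ms / 1000
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sched <- diana_schedule(N, M,
                            n_dummy = if (r == 1L) seq$n_dummy else 0L,
                            tr_ms = paradigm$tr_ms, line_order = line_order,
                            start_time_s = start_time_s +
                              (r - 1L) * N * M * tr_s +
                              if (r == 1L) 0 else seq$n_dummy * tr_s)
    # each run draws from its own noise stream
    nz <- noise
    if (!is.null(nz)) nz$seed <- nz$seed + (r - 1L) * 10007L
    out[[r]] <- simulate_acquisition(phantom, seq, sched, response = response,
                                     drift = drift, noise = nz,
                                     motion = motion)
  }
  out
}
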