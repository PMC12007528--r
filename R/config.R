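## Experiment configuration: a flat, serializable description of one
## simulated experiment, round-trippable through YAML.

.config_fields <- list(
  paradigm = c("preset", "name", "stim_ms", "isi_ms", "tr_ms", "matrix_n",
               "n_runs_per_scan", "n_scans", "n_subjects", "resolution"),
  sequence = c("tr_ms", "te_ms", "fa_deg", "rf_phase_increment_deg", "n_dummy"),
  phantom = c("preset", "matrix_size"),
  response = c("amplitude_pct", "onset_ms", "duration_ms", "shape", "active_roi"),
  drift = c("rate_pct_per_min", "t0_s"),
  noise = c("thermal_sigma_pct", "physio_preset", "seed"),
  motion = c("type", "step_px", "step_deg", "seed"),
  run = c("n_runs", "seed", "quantize_16bit", "discard_first_run")
)

#' Build an experiment configuration
#'
#' A fully serializable description of one simulated experiment: paradigm,
#' sequence, phantom preset, response/drift/noise/motion models and seeds.
#' Unknown fields are rejected by name.
#'
#' @param paradigm Either a preset name (see [paradigm_preset()]) or a list of
#'   explicit [paradigm()] arguments.
#' @param sequence List of [seq_params()] arguments.
#' @param phantom List with `preset` and `matrix_size`.
#' @param response,drift,noise,motion Model argument lists (`noise$physio_preset`
#'   may be `"default"` to use [physio_default()], or `"none"`).
#' @param run List: `n_runs` (runs simulated; default 3), `seed`,
#'   `quantize_16bit`, `discard_first_run` (drop the first run before the
#'   trial-averaged analysis, default `TRUE`).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(paradigm = "paradigm_III",
                              sequence = list(),
                              phantom = list(),
                              response = list(),
                              drift = list(),
                              noise = list(),
                              motion = list(),
                              run = list()) {
  cfg <- list(
    paradigm = if (is.character(paradigm)) list(preset = paradigm) else paradigm,
    sequence = utils::modifyList(
      list(tr_ms = 5, te_ms = 2.4, fa_deg = 4, rf_phase_increment_deg = 50,
           n_dummy = 2000), sequence),
    phantom = utils::modifyList(list(preset = "brain_slice", matrix_size = 96),
                                phantom),
    response = utils::modifyList(
      list(amplitude_pct = 0.05, onset_ms = 75, duration_ms = 150,
           shape = "boxcar", active_roi = "target_v1"), response),
    drift = utils::modifyList(list(rate_pct_per_min = 0, t0_s = 0), drift),
    noise = utils::modifyList(
      list(thermal_sigma_pct = 0, physio_preset = "none", seed = 1L), noise),
    motion = utils::modifyList(
      list(type = "none", step_px = 0.2, step_deg = 0.05, seed = 1L), motion),
    run = utils::modifyList(
      list(n_runs = 3L, seed = 1L, quantize_16bit = FALSE,
           discard_first_run = TRUE), run)
  )
  validate_config(cfg)
}

#' Validate an experiment configuration
#'
#' Checks section and field names and basic types; unknown fields are rejected
#' with a message naming the offending field.
#'
#' @param cfg A named list (as from [experiment_config()] or
#'   [load_config()]).
#' @return The validated config, classed `experiment_config`.
#' @export
validate_config <- function(cfg) {
  cfg <- unclass(cfg)
  bad_sec <- setdiff(names(cfg), names(.config_fields))
  if (length(bad_sec))
    stop(sprintf("unknown config section(s): %s",
                 paste(bad_sec, collapse = ", ")), call. = FALSE)
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), .config_fields[[sec]])
    if (length(bad))
      stop(sprintf("unknown field(s) in section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  num <- function(sec, fld)
    if (!is.null(cfg[[sec]][[fld]]) && !is.numeric(cfg[[sec]][[fld]]))
      stop(sprintf("field %s.%s must be numeric", sec, fld), call. = FALSE)
  for (f in c("tr_ms", "te_ms", "fa_deg", "n_dummy")) num("sequence", f)
  for (f in c("amplitude_pct", "onset_ms", "duration_ms")) num("response", f)
  num("drift", "rate_pct_per_min")
  num("noise", "thermal_sigma_pct")
  num("run", "n_runs")
  # normalize numeric scalars so YAML round-trips compare equal
  cfg <- rapply(cfg, function(x) if (is.numeric(x)) as.numeric(x) else x,
                how = "replace")
  structure(cfg, class = "experiment_config")
}

#' Load / save an experiment configuration (YAML)
#'
#' `load_config(save_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param path YAML file path.
#' @return `load_config` returns a validated `experiment_config`;
#'   `save_config` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @param cfg An `experiment_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(validate_config(cfg)), path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical YAML serialization; recorded in every output artifact
#' for provenance.
#'
#' @param cfg An `experiment_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

# materialize model objects from a config
.build_models <- function(cfg) {
  pd <- cfg$paradigm
  par <- if (!is.null(pd$preset)) paradigm_preset(pd$preset) else
    do.call(paradigm, pd)
  sq <- do.call(seq_params, cfg$sequence)
  ph <- make_default_phantom(cfg$phantom$matrix_size, cfg$phantom$preset)
  if (par$matrix_n != nrow(ph$grid))
    stop("config: phantom matrix_size must equal the paradigm matrix size",
         call. = FALSE)
  resp <- do.call(response_model, cfg$response)
  dr <- do.call(drift_model, cfg$drift)
  phys <- switch(cfg$noise$physio_preset, none = NULL,
                 default = physio_default(),
                 stop("noise.physio_preset must be 'none' or 'default'",
                      call. = FALSE))
  nz <- noise_model(cfg$noise$thermal_sigma_pct, physio = phys,
                    seed = cfg$noise$seed + cfg$run$seed)
  mo <- motion_model(cfg$motion$type, step_px = cfg$motion$step_px,
                     step_deg = cfg$motion$step_deg,
                     seed = cfg$motion$seed + cfg$run$seed)
  list(paradigm = par, seq = sq, phantom = ph, response = resp, drift = dr,
       noise = nz, motion = mo)
}

#' Run a full simulated experiment from a configuration
#'
#' Simulates `run$n_runs` consecutive loop-swapped runs of the configured
#' paradigm on the digital phantom, applies per-trial normalization,
#' reconstructs each run, optionally motion-corrects, runs the trial-averaged
#' analysis chain for every phantom ROI and writes the artifact bundle:
#' reconstructed NIfTI series (first retained run), per-ROI TSV time courses
#' with confidence intervals, a JSON summary with all derived timing numbers,
#' and a plain-text log with seeds and the config hash. Deterministic given
#' the config's seeds.
#'
#' @param cfg An `experiment_config` or path to a YAML config.
#' @param output_dir Output directory (created if missing); `NULL` to skip
#'   writing files.
#' @return A list with `summary` (named list of derived numbers), `responses`
#'   (per-ROI `roi_response`), `runs` (reconstructed, retained
#'   [image_series()] list), `config_hash`.
#' @export
run_experiment <- function(cfg, output_dir = NULL) {
  if (is.character(cfg)) cfg <- load_config(cfg)
  cfg <- validate_config(cfg)
  mdl <- .build_models(cfg)
  par <- mdl$paradigm
  hash <- config_hash(cfg)
  n_runs <- as.integer(cfg$run$n_runs)

  ks <- simulate_scan(mdl$phantom, mdl$seq, par, n_runs = n_runs,
                      response = mdl$response, drift = mdl$drift,
                      noise = mdl$noise, motion = mdl$motion)
  ks <- normalize_scan(ks)
  runs <- lapply(ks, reconstruct, quantize_16bit = isTRUE(cfg$run$quantize_16bit))
  motion_logs <- NULL
  if (cfg$motion$type != "none") {
    ref <- run_mean(runs[[1]])
    mc <- lapply(runs, motion_correct, reference = ref)
    runs <- lapply(mc, `[[`, "series")
    motion_logs <- lapply(mc, `[[`, "transforms")
  }
  discard <- isTRUE(cfg$run$discard_first_run) && n_runs > 1L
  retained <- if (discard) runs[-1L] else runs

  responses <- list()
  if (length(retained) >= 2L) {
    for (nm in names(mdl$phantom$rois))
      responses[[nm]] <- analyze_runs(retained, mdl$phantom$rois[[nm]],
                                      roi = nm)
  }
  summary <- list(
    paradigm = par$name,
    matrix_n = par$matrix_n,
    m_timepoints = par$trial_timepoints_m,
    n_dummy = mdl$seq$n_dummy,
    n_runs_simulated = n_runs,
    n_runs_retained = length(retained),
    run_duration_s = run_duration_s(par$matrix_n, par$trial_timepoints_m,
                                    par$tr_ms),
    scan_duration_s = scan_duration_s(n_runs, mdl$seq$n_dummy, par$matrix_n,
                                      par$trial_timepoints_m, par$tr_ms),
    spgre_discard_images = spgre_discard_count(mdl$seq$n_dummy, par$matrix_n),
    seed = cfg$run$seed,
    config_hash = hash
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    vx <- if (identical(par$resolution, "1x1x5mm")) c(1, 1, 5) else c(2, 2, 5)
    if (length(retained))
      write_image_series_nifti(retained[[1]],
                               file.path(output_dir, "run1.nii.gz"),
                               voxel_mm = vx)
    for (nm in names(responses))
      write_roi_response_tsv(responses[[nm]],
                             file.path(output_dir, paste0("roi_", nm, ".tsv")))
    if (!is.null(motion_logs))
      write_motion_tsv(motion_logs[[1]], file.path(output_dir, "motion_run1.tsv"))
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    save_config(cfg, file.path(output_dir, "config.yaml"))
    writeLines(c(sprintf("dianasim %s", as.character(utils::packageVersion("dianasim"))),
                 sprintf("config_hash: %s", hash),
                 sprintf("seed: %d", as.integer(cfg$run$seed)),
                 sprintf("runs simulated: %d, retained: %d (first run discarded: %s)",
                         n_runs, length(retained), discard),
                 sprintf("dummies: %d", mdl$seq$n_dummy)),
               file.path(output_dir, "log.txt"))
  }
  list(summary = summary, responses = responses, runs = retained,
       config_hash = hash)
}
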