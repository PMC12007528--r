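#' Write an image series as single-slice 4D NIfTI
#'
#' Stores the series as (x, y, 1, t) with the in-plane voxel size and slice
#' thickness in the header and the time step set to TR.
#'
#' @param series An [image_series()] or 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_mm Length-3 voxel size in mm (default `c(2, 2, 5)`).
#' @return `path`, invisibly.
#' @export
write_image_series_nifti <- function(series, path, voxel_mm = c(2, 2, 5)) {
  x <- if (inherits(series, "image_series")) series$data else series
  tr_s <- if (inherits(series, "image_series")) series$tr_ms / 1000 else 1
  d <- dim(x)
  arr <- array(x, dim = c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_mm, tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a single-slice NIfTI series
#'
#' @param path NIfTI file path.
#' @param tr_ms Repetition time to attach (ms); if `NULL`, taken from the
#'   header's time step.
#' @return An [image_series()].
#' @export
read_image_series_nifti <- function(path, tr_ms = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L) {
    if (d[3] != 1L) stop("expected a single-slice series", call. = FALSE)
    arr <- array(as.numeric(img), dim = c(d[1], d[2], d[4]))
  } else if (length(d) == 3L) {
    arr <- array(as.numeric(img), dim = d)
  } else stop("expected a 3D or 4D NIfTI", call. = FALSE)
  if (is.null(tr_ms)) {
    pd <- RNifti::pixdim(img)
    tr_ms <- if (length(pd) >= 4 && pd[4] > 0) pd[4] * 1000 else 5
  }
  image_series(pmax(arr, 0), tr_ms = tr_ms, mode = "external")
}

#' Write an ROI mask as a NIfTI byte mask
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @param voxel_mm Voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_roi_mask_nifti <- function(mask, path, voxel_mm = c(2, 2, 5)) {
  arr <- array(as.integer(mask), dim = c(dim(mask), 1L))
  img <- RNifti::asNifti(arr, pixdim = c(voxel_mm, 1), datatype = "uint8")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an ROI response as TSV
#'
#' Columns: `time_ms`, `mean_pct`, `ci_lo`, `ci_hi`, `n_runs`.
#'
#' @param rr An `roi_response`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_response_tsv <- function(rr, path) {
  stopifnot(inherits(rr, "roi_response"))
  df <- data.frame(time_ms = (seq_along(rr$mean) - 1) * rr$tr_ms,
                   mean_pct = rr$mean,
                   ci_lo = rr$mean - rr$ci_halfwidth,
                   ci_hi = rr$mean + rr$ci_halfwidth,
                   n_runs = rr$n_runs)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write motion parameters as TSV
#'
#' Columns: `time_point`, `dx_px`, `dy_px`, `theta_deg`, `failed`.
#'
#' @param transforms The `transforms` data.frame from [motion_correct()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motion_tsv <- function(transforms, path) {
  utils::write.table(transforms, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Per-T1 dummy-pulse planning table as CSV
#'
#' Writes the `t1_ms, mss, n_dummy` table of
#' [dummy_pulses_to_steady_state()].
#'
#' @param plan Result of [dummy_pulses_to_steady_state()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bloch_table_csv <- function(plan, path) {
  utils::write.csv(plan$table, path, row.names = FALSE)
  invisible(path)
}
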