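#' Reconstruct magnitude images from fully sampled k-space
#'
#' 2D inverse discrete Fourier transform per time point followed by the
#' magnitude. Optionally each run is linearly quantized to a 16-bit integer
#' range (scale = run maximum), mirroring an offline reconstruction with
#' 16-bit dynamic range.
#'
#' @param kspace A `kspace_series` from [simulate_acquisition()].
#' @param quantize_16bit Quantize magnitudes to 16-bit (default `FALSE`).
#' @return An object of class `image_series` with `data` (array
#'   `nx x ny x n_timepoints`), `tr_ms`, `mode` and `quantized`.
#' @export
reconstruct <- function(kspace, quantize_16bit = FALSE) {
  stopifnot(inherits(kspace, "kspace_series"))
  if (anyNA(kspace$k))
    stop("k-space is undersampled: some (line, time point) pairs were never acquired",
         call. = FALSE)
  d <- dim(kspace$k)
  img <- array(0, dim = d)
  for (t in seq_len(d[3]))
    img[, , t] <- Mod(stats::fft(kspace$k[, , t], inverse = TRUE)) / (d[1] * d[2])
  if (quantize_16bit) {
    mx <- max(img)
    if (mx > 0) img <- round(img / mx * 65535) * mx / 65535
  }
  image_series(img, tr_ms = kspace$schedule$tr_ms, mode = kspace$mode,
               quantized = quantize_16bit)
}

#' Construct an image series
#'
#' @param data Numeric array `nx x ny x n_timepoints` of non-negative
#'   magnitudes.
#' @param tr_ms Repetition time (ms); the image sampling interval is
#'   `tr_ms` per time point for loop-swapped data.
#' @param mode `"diana"`, `"spgre"` or `"external"`.
#' @param quantized Logical flag.
#' @return An object of class `image_series`.
#' @export
image_series <- function(data, tr_ms = 5, mode = "external",
                         quantized = FALSE) {
  if (length(dim(data)) == 2L) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    stop("data must be an nx x ny x T array", call. = FALSE)
  if (any(data < 0)) stop("magnitudes must be non-negative", call. = FALSE)
  structure(list(data = data, tr_ms = tr_ms, mode = mode,
                 quantized = quantized),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image series (%s): %d x %d x %d time points, TR = %g ms%s\n",
              x$mode, d[1], d[2], d[3], x$tr_ms,
              if (x$quantized) ", 16-bit quantized" else ""))
  invisible(x)
}

#' A 2D rigid transform
#'
#' Translation (pixels) plus rotation (degrees) about the image center;
#' identity is `(0, 0, 0)`.
#'
#' @param dx_px,dy_px Translation along the first/second array index.
#' @param theta_deg Rotation angle in degrees.
#' @param failed Flag set by [estimate_rigid2d()] on degenerate input.
#' @return An object of class `rigid2d`.
#' @export
rigid2d <- function(dx_px = 0, dy_px = 0, theta_deg = 0, failed = FALSE) {
  structure(list(dx_px = unname(dx_px), dy_px = unname(dy_px),
                 theta_deg = unname(theta_deg), failed = failed),
            class = "rigid2d")
}

#' @export
print.rigid2d <- function(x, ...) {
  cat(sprintf("rigid2d: dx = %.4f px, dy = %.4f px, theta = %.4f deg%s\n",
              x$dx_px, x$dy_px, x$theta_deg,
              if (x$failed) " (estimation failed)" else ""))
  invisible(x)
}

#' Apply a 2D rigid transform to an image
#'
#' The image content is rotated by `theta_deg` about the image center and then
#' translated by `(dx_px, dy_px)`; resampling uses bilinear interpolation with
#' zero fill outside the field of view (the slice background is air).
#'
#' @param img Numeric matrix.
#' @param dx_px,dy_px,theta_deg Transform parameters (or pass a `rigid2d` as
#'   `dx_px`).
#' @return Transformed matrix of the same dimensions.
#' @export
apply_rigid2d <- function(img, dx_px = 0, dy_px = 0, theta_deg = 0) {
  if (inherits(dx_px, "rigid2d")) {
    tr <- dx_px
    dx_px <- tr$dx_px; dy_px <- tr$dy_px; theta_deg <- tr$theta_deg
  }
  nx <- nrow(img); ny <- ncol(img)
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- -theta_deg * pi / 180     # inverse rotation for pull-back sampling
  xs <- matrix(seq_len(nx), nx, ny) - cx - dx_px
  ys <- matrix(seq_len(ny), nx, ny, byrow = TRUE) - cy - dy_px
  sx <- cos(th) * xs - sin(th) * ys + cx
  sy <- sin(th) * xs + cos(th) * ys + cy
  .bilinear(img, sx, sy)
}

# vectorized bilinear sampling with zero fill
.bilinear <- function(img, sx, sy) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  out <- numeric(length(sx))
  gval <- function(ix, iy) {
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
    v <- numeric(length(ix))
    v[ok] <- img[cbind(ix[ok], iy[ok])]
    v
  }
  out <- gval(x0, y0) * (1 - fx) * (1 - fy) +
    gval(x0 + 1, y0) * fx * (1 - fy) +
    gval(x0, y0 + 1) * (1 - fx) * fy +
    gval(x0 + 1, y0 + 1) * fx * fy
  matrix(out, nx, ny)
}

#' Estimate the 2D rigid transform aligning one image to a reference
#'
#' Returns the transform `T` such that `apply_rigid2d(moving, T)` best matches
#' `reference` in the least-squares sense. A coarse integer translation is
#' found by phase correlation and refined together with the rotation by
#' Nelder-Mead minimization of the sum of squared differences. Constant
#' (degenerate) inputs return the identity with `failed = TRUE`.
#'
#' @param moving,reference Numeric matrices of equal dimensions.
#' @return A [rigid2d()].
#' @export
estimate_rigid2d <- function(moving, reference) {
  if (!identical(dim(moving), dim(reference)))
    stop("images must have identical dimensions", call. = FALSE)
  if (stats::sd(moving) == 0 || stats::sd(reference) == 0)
    return(rigid2d(failed = TRUE))
  nx <- nrow(moving); ny <- ncol(moving)
  # phase correlation for the integer part of the translation
  fm <- stats::fft(moving); fr <- stats::fft(reference)
  cp <- fr * Conj(fm)
  cp <- cp / (Mod(cp) + 1e-12)
  corr <- Re(stats::fft(cp, inverse = TRUE))
  pk <- which(corr == max(corr), arr.ind = TRUE)[1, ]
  sx <- pk[1] - 1; sy <- pk[2] - 1
  if (sx > nx / 2) sx <- sx - nx
  if (sy > ny / 2) sy <- sy - ny
  ssd <- function(p) {
    w <- apply_rigid2d(moving, p[1], p[2], p[3])
    sum((w - reference)^2)
  }
  fit <- stats::optim(c(sx, sy, 0), ssd, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 1000))
  rigid2d(fit$par[1], fit$par[2], fit$par[3], failed = FALSE)
}

#' Motion-correct an image time series
#'
#' A reference image is computed by averaging the series over time (or taken
#' from `reference`); every image is then coregistered to it with a 2D rigid
#' transform and resampled onto the reference frame. Estimation failures are
#' propagated as flags in the transform log, never silently.
#'
#' @param series An [image_series()].
#' @param reference Optional reference matrix; default is the temporal mean of
#'   `series` (conventionally, of the designated reference run).
#' @return A list with `series` (corrected [image_series()]) and `transforms`
#'   (data.frame: `time_point`, `dx_px`, `dy_px`, `theta_deg`, `failed`).
#' @export
motion_correct <- function(series, reference = NULL) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$data)
  if (is.null(reference)) reference <- run_mean(series)
  out <- series$data
  tf <- data.frame(time_point = seq_len(d[3]), dx_px = 0, dy_px = 0,
                   theta_deg = 0, failed = FALSE)
  for (t in seq_len(d[3])) {
    est <- estimate_rigid2d(series$data[, , t], reference)
    tf$dx_px[t] <- est$dx_px; tf$dy_px[t] <- est$dy_px
    tf$theta_deg[t] <- est$theta_deg; tf$failed[t] <- est$failed
    if (!est$failed)
      out[, , t] <- pmax(apply_rigid2d(series$data[, , t], est), 0)
  }
  list(series = image_series(out, tr_ms = series$tr_ms, mode = series$mode,
                             quantized = series$quantized),
       transforms = tf)
}

#' Temporal mean image of a run
#'
#' @param series An [image_series()].
#' @return Numeric matrix.
#' @export
run_mean <- function(series) {
  stopifnot(inherits(series, "image_series"))
  d <- dim(series$data)
  matrix(rowMeans(matrix(series$data, d[1] * d[2], d[3])), d[1], d[2])
}
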