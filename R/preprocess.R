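#' Remove a linear trend from a time series
#'
#' Residuals of the ordinary least-squares fit of the series on an
#' intercept and the scan index. Slow scanner drift over a 25-minute
#' session is well approximated as linear; anything slower than the
#' band of interest is removed here before statistics.
#'
#' @param series numeric vector, length >= 3.
#' @return numeric vector of residuals (mean zero).
#' @export
detrend_linear <- function(series) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 3L) stop("detrend_linear needs at least 3 timepoints")
  t <- seq_len(n)
  stats::lm.fit(cbind(1, t), series)$residuals
}

# normalized 1D truncated Gaussian kernel for a given sigma in voxels
gaussian_kernel_1d <- function(sigma_vox, radius = ceiling(3 * sigma_vox)) {
  if (sigma_vox <= 0) return(1)
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# convolve a 3D array along one axis with a kernel, renormalizing the
# truncated kernel at the boundaries so constants are preserved
convolve_axis <- function(vol, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0L) return(vol)
  d <- dim(vol)
  out <- array(0, dim = d)
  wsum <- array(0, dim = d)
  for (o in seq(-r, r)) {
    w <- kernel[o + r + 1L]
    src <- seq_len(d[axis]) + o
    ok <- src >= 1L & src <= d[axis]
    if (!any(ok)) next
    dst_idx <- which(ok)
    src_idx <- src[ok]
    if (axis == 1L) {
      out[dst_idx, , ] <- out[dst_idx, , ] + w * vol[src_idx, , ]
      wsum[dst_idx, , ] <- wsum[dst_idx, , ] + w
    } else if (axis == 2L) {
      out[, dst_idx, ] <- out[, dst_idx, ] + w * vol[, src_idx, ]
      wsum[, dst_idx, ] <- wsum[, dst_idx, ] + w
    } else {
      out[, , dst_idx] <- out[, , dst_idx] + w * vol[, , src_idx]
      wsum[, , dst_idx] <- wsum[, , dst_idx] + w
    }
  }
  out / wsum
}

#' Gaussian spatial smoothing of a 3D volume
#'
#' Separable convolution with a truncated discrete Gaussian,
#' `sigma = fwhm / (2.35482 * voxel_size)` per axis. The kernel is
#' renormalized where it overhangs the volume boundary, so constant volumes
#' are preserved exactly. `fwhm_mm = 0` is the identity. The study-scale
#' default kernel is FWHM 0.8 mm.
#'
#' @param vol 3D numeric array.
#' @param fwhm_mm full width at half maximum of the kernel, in mm (>= 0).
#' @param voxel_size voxel edge lengths in mm (length 3, recycled from 1).
#' @return smoothed 3D array.
#' @export
gaussian_smooth <- function(vol, fwhm_mm, voxel_size = c(1, 1, 1)) {
  if (length(dim(vol)) != 3L) stop("'vol' must be a 3D array")
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(vol)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  sigma <- fwhm_mm / (2.35482 * voxel_size)
  out <- vol
  for (axis in 1:3)
    out <- convolve_axis(out, gaussian_kernel_1d(sigma[axis]), axis)
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Second-order Butterworth band-pass applied forward and backward
#' (`signal::filtfilt`), giving zero phase shift and an effective
#' fourth-order magnitude response. The resting-state default band is
#' 0.01-0.1 Hz: below it, slow scanner drift; above it, respiratory and
#' cardiac physiological noise.
#'
#' @param series numeric vector.
#' @param tr_seconds sampling interval in seconds.
#' @param low_hz,high_hz band edges; `0 <= low < high < 1/(2 TR)`.
#' @return filtered series (mean approximately zero).
#' @export
bandpass <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.1) {
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyquist))
    stop(sprintf("band must satisfy 0 <= low < high < %.4g Hz (Nyquist at TR %.3g s)",
                 nyquist, tr_seconds))
  bf <- signal::butter(2, c(low_hz, high_hz) / nyquist, type = "pass")
  x <- as.numeric(series)
  # remove the mean first: the stop-band kills DC anyway, and centring
  # avoids the large edge transients filtfilt produces on offset series
  as.numeric(signal::filtfilt(bf, x - mean(x)))
}

#' Flag motion-outlier scans by framewise displacement
#'
#' Framewise displacement sums the absolute frame-to-frame change of the
#' three translations (mm) and the three rotations, the latter converted to
#' arc length on a sphere of radius 5 mm (a rodent-scale head radius). Scans
#' whose FD exceeds the threshold are flagged; flagged scans become spike
#' indicator regressors rather than being deleted, preserving the time grid.
#'
#' @param motion_params numeric matrix, time x 6: three translations (mm)
#'   then three rotations (radians).
#' @param threshold FD threshold in mm (default 0.2).
#' @param radius_mm rotation-to-arc-length radius (default 5).
#' @return integer vector of 0-based scan indices with `FD > threshold`;
#'   the full FD trace (first frame 0) is attached as attribute `"fd"`.
#' @export
find_motion_outliers <- function(motion_params, threshold = 0.2,
                                 radius_mm = 5) {
  m <- as.matrix(motion_params)
  if (nrow(m) < 2L) stop("need at least 2 frames of motion parameters")
  if (ncol(m) != 6L) stop("motion_params must have 6 columns")
  dm <- abs(diff(m))
  fd <- c(0, rowSums(dm[, 1:3, drop = FALSE]) +
               radius_mm * rowSums(dm[, 4:6, drop = FALSE]))
  out <- which(fd > threshold) - 1L
  attr(out, "fd") <- fd
  out
}

#' Bundle nuisance regressors
#'
#' Any subset of: six motion parameters, spike (motion-outlier) indicator
#' columns, mean white-matter and mean CSF series. Constant-zero columns are
#' rejected unless flagged as spike columns (an outlier-free run yields
#' all-zero indicators legitimately).
#'
#' @param regressors time x k numeric matrix.
#' @param names character vector of k column labels.
#' @param spike_cols indices of columns that are spike indicators.
#' @return object of class `nuisance_set`.
#' @export
nuisance_set <- function(regressors, names = colnames(regressors),
                         spike_cols = grep("^spike", names)) {
  x <- as.matrix(regressors)
  if (is.null(names)) names <- sprintf("reg%d", seq_len(ncol(x)))
  if (length(names) != ncol(x)) stop("one name per regressor column required")
  zero <- apply(x == 0, 2L, all)
  bad <- which(zero & !(seq_len(ncol(x)) %in% spike_cols))
  if (length(bad))
    stop(sprintf("constant-zero non-spike regressor column(s): %s",
                 paste(names[bad], collapse = ", ")))
  structure(list(regressors = x, names = names,
                 spike_cols = as.integer(spike_cols)),
            class = "nuisance_set")
}

#' Spike indicator regressors from outlier scan indices
#'
#' @param outliers 0-based scan indices (from [find_motion_outliers()]).
#' @param n_acquisitions series length.
#' @return time x length(outliers) 0/1 matrix (possibly 0 columns).
#' @export
spike_regressors <- function(outliers, n_acquisitions) {
  out <- matrix(0, n_acquisitions, length(outliers))
  for (j in seq_along(outliers)) out[outliers[j] + 1L, j] <- 1
  colnames(out) <- if (length(outliers)) sprintf("spike%d", seq_along(outliers))
  out
}

#' Regress nuisance signals out of a time series
#'
#' Ordinary least-squares residuals of the series on an intercept plus the
#' nuisance columns; residuals are orthogonal to every regressor.
#'
#' @param series numeric vector.
#' @param nuisance a [nuisance_set()] (or plain matrix) with
#'   `length(series)` rows.
#' @return residual series.
#' @export
nuisance_regress <- function(series, nuisance) {
  x <- if (inherits(nuisance, "nuisance_set")) nuisance$regressors
       else as.matrix(nuisance)
  series <- as.numeric(series)
  if (nrow(x) != length(series))
    stop("nuisance rows must match the series length")
  keep <- !apply(x == 0, 2L, all)       # all-zero spike columns drop out
  X <- cbind(intercept = 1, x[, keep, drop = FALSE])
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop(sprintf("nuisance design is rank deficient; collinear column(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  stats::lm.fit(X, series)$residuals
}

#' Standard resting-state cleanup of one region series
#'
#' Band-pass, then detrend, then nuisance regression — the simplified
#' equivalent of the resting-state preprocessing chain.
#'
#' @param series numeric vector.
#' @param tr_seconds sampling interval.
#' @param nuisance optional [nuisance_set()].
#' @param low_hz,high_hz band edges.
#' @return residual series.
#' @export
clean_series <- function(series, tr_seconds, nuisance = NULL,
                         low_hz = 0.01, high_hz = 0.1) {
  out <- bandpass(series, tr_seconds, low_hz, high_hz)
  out <- detrend_linear(out)
  if (!is.null(nuisance)) out <- nuisance_regress(out, nuisance)
  out
}
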