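# Temporal and spatial conditioning of 4D data: volume discarding, ideal
# band-pass filtering, separable Gaussian smoothing, nuisance regression,
# head-motion QC. Processing order used by run_study():
#   discard -> smooth -> band-pass -> nuisance regression
# (realignment/slice timing/normalization are assumed already done upstream).

#' Discard leading volumes
#'
#' Drops the first `n_discard` volumes of a 4D acquisition (scanner signal
#' stabilization / magnetic-saturation period); the remaining volumes are
#' unchanged.
#'
#' @param img a [timeseries_image()].
#' @param n_discard number of initial volumes to drop (default 10).
#' @return A [timeseries_image()] with `n_volumes - n_discard` volumes.
#' @export
discard_volumes <- function(img, n_discard = 10) {
  if (n_discard < 0) stopf("`n_discard` must be >= 0")
  if (n_discard >= img$n_volumes)
    stopf("cannot discard %d of %d volumes", n_discard, img$n_volumes)
  if (n_discard == 0) return(img)
  keep <- (n_discard + 1L):img$n_volumes
  timeseries_image(img$values[, , , keep, drop = FALSE], img$grid,
                   img$tr_seconds)
}

#' Ideal band-pass filter
#'
#' Linearly detrends each voxel row (unless already recorded as detrended),
#' then applies a rectangular frequency-domain filter: discrete-spectrum bins
#' whose frequency lies in `[low_hz, high_hz]` are retained, all others
#' (including the 0 Hz mean) are zeroed. Because detrending is recorded in
#' the matrix's provenance, a second application reduces to the ideal filter
#' alone, which is an exact projection — the operation is idempotent.
#'
#' @param vm a [voxel_matrix()].
#' @param low_hz,high_hz pass-band edges in Hz; defaults 0.01-0.08 Hz, the
#'   conventional resting-state low-frequency band.
#' @param detrend remove each row's least-squares linear trend before
#'   filtering (skipped automatically if `vm$detrended`).
#' @return A filtered [voxel_matrix()] flagged `detrended`.
#' @export
bandpass <- function(vm, low_hz = 0.01, high_hz = 0.08, detrend = TRUE) {
  Tn <- ncol(vm$data)
  tr <- vm$tr_seconds
  nyq <- 1 / (2 * tr)
  if (low_hz < 0 || low_hz >= high_hz) stopf("need 0 <= low_hz < high_hz")
  if (high_hz > nyq + 1e-12)
    stopf("high_hz (%.4g Hz) exceeds the Nyquist frequency %.4g Hz", high_hz, nyq)
  X <- vm$data
  if (detrend && !vm$detrended) {
    tc <- seq_len(Tn) - (Tn + 1) / 2
    slope <- (X %*% tc) / sum(tc^2)
    X <- X - rowMeans(X) - tcrossprod(as.numeric(slope), tc)
  }
  freqs <- (seq_len(Tn) - 1) / (Tn * tr)
  fold <- pmin(freqs, 1 / tr - freqs)            # two-sided spectrum
  keep <- fold >= low_hz - 1e-12 & fold <= high_hz + 1e-12
  keep[1] <- FALSE                               # 0 Hz always excluded
  S <- t(stats::mvfft(t(X)))
  S[, !keep] <- 0
  Y <- Re(t(stats::mvfft(t(S), inverse = TRUE))) / Tn
  voxel_matrix(Y, vm$mask, tr_seconds = tr,
               standardized = FALSE, detrended = TRUE)
}

# 1D Gaussian kernel sampled at voxel offsets, sigma in voxel units
gauss_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# shift array `a` by `s` positions along `axis`, zero-filling
shift_array <- function(a, axis, s) {
  if (s == 0) return(a)
  d <- dim(a)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  idx_src <- rep(list(quote(expr = )), length(d))
  idx_dst <- idx_src
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out_call <- as.call(c(list(quote(`[<-`), quote(out)), idx_dst,
                        as.call(c(list(quote(`[`), quote(a)), idx_src))))
  eval(out_call)
}

# separable convolution of a 3D or 4D array with per-axis kernels (zero pad)
conv_separable <- function(a, kernels) {
  for (axis in seq_along(kernels)) {
    k <- kernels[[axis]]
    if (length(k) == 1L) next
    r <- (length(k) - 1L) / 2L
    acc <- array(0, dim = dim(a))
    for (j in seq_along(k))
      acc <- acc + k[j] * shift_array(a, axis, j - r - 1L)
    a <- acc
  }
  a
}

#' Spatial Gaussian smoothing
#'
#' Convolves each volume with a separable isotropic-in-mm Gaussian of
#' `sigma = fwhm_mm / (2 sqrt(2 log 2))` per axis, converted to voxel units
#' through the grid's voxel size. Smoothing is renormalized by the smoothed
#' support (the whole volume, or the mask when one is supplied), so a
#' constant field stays constant and no intensity is diluted at edges; with
#' a mask, values do not bleed across the mask boundary and out-of-mask
#' voxels are set to `fill`. `fwhm_mm = 0` is the identity.
#'
#' @param img a [timeseries_image()] or [volume_image()].
#' @param fwhm_mm kernel full width at half maximum in mm (default 6).
#' @param mask optional [brain_mask()] restricting the smoothing support.
#' @param fill value outside the mask (when a mask is given).
#' @return An object of the same class as `img`.
#' @export
smooth_gaussian <- function(img, fwhm_mm = 6, mask = NULL, fill = 0) {
  if (fwhm_mm < 0) stopf("`fwhm_mm` must be >= 0")
  if (fwhm_mm == 0) return(img)
  grid <- img$grid
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  kernels <- lapply(grid$voxel_size, function(vs) gauss_kernel_1d(sigma_mm / vs))
  is4d <- inherits(img, "timeseries_image")
  vals <- img$values
  if (!is.null(mask)) {
    if (!same_grid(grid, mask$grid)) stopf("image and mask grids differ")
    w <- array(as.numeric(mask$indicator), dim = grid$shape)
    if (is4d) vals <- vals * array(w, dim = dim(vals))
    else vals <- vals * w
  } else {
    w <- array(1, dim = grid$shape)
  }
  den3 <- conv_separable(w, kernels)
  num <- conv_separable(vals, kernels)
  den <- if (is4d) array(den3, dim = dim(vals)) else den3
  ok <- den > 1e-12
  out <- vals
  out[ok] <- num[ok] / den[ok]
  out[!ok] <- fill
  if (!is.null(mask)) {
    outside <- !mask$indicator
    if (is4d) out[array(outside, dim = dim(out))] <- fill else out[outside] <- fill
  }
  if (is4d) timeseries_image(out, grid, img$tr_seconds)
  else volume_image(out, grid)
}

#' Nuisance regression
#'
#' Replaces each voxel row by the residuals of an ordinary least-squares fit
#' on intercept + white-matter signal + CSF signal + six motion parameters.
#' Collinear columns are dropped with a warning (never silently). Residuals
#' are orthogonal to every retained regressor, and reapplying the same
#' design is a no-op (projection).
#'
#' @param vm a [voxel_matrix()].
#' @param nuisance list with `wm`, `csf` (numeric T-vectors, either may be
#'   `NULL`) and `motion` (T x 6 matrix, may be `NULL`).
#' @return A [voxel_matrix()] of residuals.
#' @export
regress_nuisance <- function(vm, nuisance) {
  Tn <- ncol(vm$data)
  X <- cbind(intercept = rep(1, Tn))
  if (!is.null(nuisance$wm)) X <- cbind(X, wm = nuisance$wm)
  if (!is.null(nuisance$csf)) X <- cbind(X, csf = nuisance$csf)
  if (!is.null(nuisance$motion)) {
    m <- as.matrix(nuisance$motion)
    if (nrow(m) != Tn) stopf("motion table has %d rows; expected %d", nrow(m), Tn)
    colnames(m) <- colnames(m) %||% paste0("motion", seq_len(ncol(m)))
    X <- cbind(X, m)
  }
  if (any(sapply(list(nuisance$wm, nuisance$csf), function(v)
    !is.null(v) && length(v) != Tn)))
    stopf("nuisance signal lengths must equal the number of volumes (%d)", Tn)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    warnf("dropping collinear nuisance column(s): %s", paste(drop, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  Q <- qr.Q(qx)
  R <- vm$data - (vm$data %*% Q) %*% t(Q)
  voxel_matrix(R, vm$mask, tr_seconds = vm$tr_seconds,
               detrended = vm$detrended)
}

#' Head-motion summary and exclusion check
#'
#' `mean_displacement_mm` is the mean, over volumes 2..T, of the Euclidean
#' norm of the volume-to-volume translation difference (the translation-based
#' mean-motion summary conventional in resting-state QC; rotations are
#' reported separately). A scan is flagged `excluded` when any absolute
#' translation reaches 2 mm or any absolute rotation reaches 2 degrees.
#'
#' @param motion T x 6 matrix: three translations (mm), three rotations
#'   (degrees).
#' @return List with `mean_displacement_mm`, `max_translation_mm`,
#'   `max_rotation_deg`, `excluded`.
#' @export
motion_summary <- function(motion) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2L) stopf("motion table needs at least 2 volumes")
  if (ncol(motion) != 6L) stopf("motion table must have 6 columns")
  dtr <- diff(motion[, 1:3, drop = FALSE])
  disp <- sqrt(rowSums(dtr^2))
  max_t <- max(abs(motion[, 1:3]))
  max_r <- max(abs(motion[, 4:6]))
  list(mean_displacement_mm = mean(disp),
       max_translation_mm = max_t,
       max_rotation_deg = max_r,
       excluded = max_t >= 2 || max_r >= 2)
}
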