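#' Voxel grid geometry
#'
#' An `image_grid` records the shape of a 3D voxel lattice and the physical
#' voxel size in mm per axis. All volumes, masks and maps in voxcent carry
#' one, and operations that combine objects require their grids to agree.
#'
#' Voxel ordering convention: whenever in-mask voxels are listed as a vector
#' (rows of a [voxel_matrix()], values of a centrality map), they are ordered
#' by ascending column-major linear index — the first axis varies fastest,
#' exactly as R stores arrays. Voxel indices are 1-based.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param voxel_size numeric voxel edge length(s) in mm; a single value is
#'   recycled to the three axes. Default 3 mm isotropic.
#' @return An object of class `image_grid` with fields `shape` and
#'   `voxel_size`.
#' @examples
#' g <- image_grid(c(10, 12, 8), 3)
#' voxel_volume_mm3(g)  # 27
#' @export
image_grid <- function(shape, voxel_size = c(3, 3, 3)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stopf("`shape` must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stopf("`voxel_size` must be 3 positive mm values")
  structure(list(shape = shape, voxel_size = voxel_size), class = "image_grid")
}

#' @rdname image_grid
#' @param grid an `image_grid`.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size)

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && all(abs(a$voxel_size - b$voxel_size) < tol)
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %s voxels, %s mm\n",
              paste(x$shape, collapse = " x "),
              paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' Binary brain/network mask
#'
#' @param indicator logical or 0/1 numeric 3D array marking in-mask voxels.
#' @param grid an [image_grid()]; defaults to the array's dimensions with
#'   3 mm voxels.
#' @return Object of class `brain_mask` with fields `grid`, `indicator`
#'   (logical array), `indices` (ascending column-major linear indices of the
#'   in-mask voxels — the canonical voxel ordering) and `n_voxels`.
#' @export
brain_mask <- function(indicator, grid = NULL) {
  if (is.null(dim(indicator)) || length(dim(indicator)) != 3L)
    stopf("mask indicator must be a 3D array")
  if (is.null(grid)) grid <- image_grid(dim(indicator))
  if (!identical(as.integer(dim(indicator)), grid$shape))
    stopf("mask indicator dimensions do not match the grid shape")
  vals <- as.vector(indicator)
  if (!is.logical(vals)) {
    if (any(!vals %in% c(0, 1)))
      stopf("mask values must be 0/1 or logical")
    vals <- vals != 0
  }
  ind <- array(vals, dim = grid$shape)
  idx <- which(ind)                      # ascending column-major order
  if (length(idx) < 1L) stopf("mask must contain at least one voxel")
  structure(list(grid = grid, indicator = ind,
                 indices = idx, n_voxels = length(idx)),
            class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: %d voxels in a %s grid (%s mm)\n",
              x$n_voxels, paste(x$grid$shape, collapse = " x "),
              paste(signif(x$grid$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' In-mask voxel coordinates
#'
#' @param mask a [brain_mask()].
#' @return `mask_coords()`: an `n_voxels` x 3 integer matrix of 1-based
#'   (i, j, k) indices in canonical order. `mask_coords_mm()`: the same
#'   positions in mm, with the center of voxel (1,1,1) at the origin of a
#'   diagonal voxel-size affine.
#' @export
mask_coords <- function(mask) {
  arrayInd(mask$indices, mask$grid$shape)
}

#' @rdname mask_coords
#' @export
mask_coords_mm <- function(mask) {
  ijk <- mask_coords(mask)
  sweep(ijk - 1L, 2L, mask$grid$voxel_size, `*`)
}

#' Masked 4D time-series image
#'
#' @param values 4D numeric array (x, y, z, time); all values must be finite.
#' @param grid an [image_grid()] matching the first three dimensions.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @return Object of class `timeseries_image` with fields `values`, `grid`,
#'   `n_volumes`, `tr_seconds`.
#' @export
timeseries_image <- function(values, grid = NULL, tr_seconds = 2) {
  d <- dim(values)
  if (is.null(d) || length(d) != 4L)
    stopf("time-series values must be a 4D array")
  if (d[4] < 2L) stopf("a time series needs at least 2 volumes")
  if (is.null(grid)) grid <- image_grid(d[1:3])
  if (!identical(as.integer(d[1:3]), grid$shape))
    stopf("array dimensions do not match the grid shape")
  if (!all(is.finite(values))) stopf("time-series values must all be finite")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stopf("`tr_seconds` must be a positive scalar")
  structure(list(values = values, grid = grid,
                 n_volumes = as.integer(d[4]), tr_seconds = tr_seconds),
            class = "timeseries_image")
}

#' @export
print.timeseries_image <- function(x, ...) {
  cat(sprintf("timeseries_image: %s x %d volumes, TR %.3g s\n",
              paste(x$grid$shape, collapse = " x "), x$n_volumes, x$tr_seconds))
  invisible(x)
}

#' Single 3D scalar volume (e.g. a map or tissue-probability image)
#'
#' @param values 3D numeric array.
#' @param grid an [image_grid()]; defaults to the array's dimensions.
#' @return Object of class `volume_image` with fields `values`, `grid`.
#' @export
volume_image <- function(values, grid = NULL) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L) stopf("volume values must be a 3D array")
  if (is.null(grid)) grid <- image_grid(d)
  if (!identical(as.integer(d), grid$shape))
    stopf("array dimensions do not match the grid shape")
  structure(list(values = values, grid = grid), class = "volume_image")
}

#' Masked voxel-by-time matrix
#'
#' Rows are in-mask voxels in canonical order (see [image_grid()]), columns
#' are volumes. The `standardized` flag records that rows have been centered
#' and scaled so that the dot product of two rows divided by (T - 1) is their
#' Pearson correlation; `detrended` records that linear detrending has been
#' applied (see [bandpass()]).
#'
#' @param data numeric matrix, `n_voxels` x T.
#' @param mask the [brain_mask()] whose voxels the rows represent.
#' @param tr_seconds sampling interval in seconds.
#' @param standardized,detrended provenance flags.
#' @return Object of class `voxel_matrix`.
#' @export
voxel_matrix <- function(data, mask, tr_seconds = 2,
                         standardized = FALSE, detrended = FALSE) {
  if (!is.matrix(data)) stopf("`data` must be a matrix")
  if (nrow(data) != mask$n_voxels)
    stopf("row count (%d) must equal mask$n_voxels (%d)",
          nrow(data), mask$n_voxels)
  if (ncol(data) < 2L) stopf("a voxel matrix needs at least 2 time points")
  structure(list(data = data, mask = mask, tr_seconds = tr_seconds,
                 standardized = isTRUE(standardized),
                 detrended = isTRUE(detrended)),
            class = "voxel_matrix")
}

#' @export
print.voxel_matrix <- function(x, ...) {
  cat(sprintf("voxel_matrix: %d voxels x %d volumes (TR %.3g s)%s%s\n",
              nrow(x$data), ncol(x$data), x$tr_seconds,
              if (x$standardized) ", standardized" else "",
              if (x$detrended) ", detrended" else ""))
  invisible(x)
}
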