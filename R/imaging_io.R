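# NIfTI-1 reading/writing and conversion between 4D grids and the masked
# voxel x time matrix. Masks are stored as uint8, everything else as float32.

#' Read a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI-1 file. 4D files become a [timeseries_image()]
#' (the repetition time is taken from the 4th pixdim entry); 3D files become
#' a [brain_mask()] when `what = "mask"` (or when `what = "auto"` and every
#' value is 0 or 1), otherwise a [volume_image()].
#'
#' @param path file path to a `.nii` or `.nii.gz` file.
#' @param what one of `"auto"`, `"timeseries"`, `"mask"`, `"volume"`.
#' @return A `timeseries_image`, `brain_mask` or `volume_image`.
#' @export
read_volume <- function(path, what = c("auto", "timeseries", "mask", "volume")) {
  what <- match.arg(what)
  if (!file.exists(path)) stopf("file not found: %s", path)
  im <- tryCatch(RNifti::readNifti(path),
                 error = function(e) stopf("not a readable NIfTI file: %s (%s)",
                                           path, conditionMessage(e)))
  d <- dim(im)
  pd <- RNifti::pixdim(im)
  if (length(d) == 4L) {
    if (what %in% c("mask", "volume"))
      stopf("%s is 4D but a 3D %s was expected", path, what)
    tr <- if (length(pd) >= 4L && is.finite(pd[4]) && pd[4] > 0) pd[4] else 2
    return(timeseries_image(array(as.numeric(im), dim = d),
                            image_grid(d[1:3], pd[1:3]), tr_seconds = tr))
  }
  if (length(d) != 3L) stopf("%s has %d dimensions; expected 3 or 4", path, length(d))
  if (what == "timeseries") stopf("%s is 3D but a 4D time series was expected", path)
  grid <- image_grid(d, pd[1:3])
  vals <- array(as.numeric(im), dim = d)
  if (what == "mask" || (what == "auto" && all(vals %in% c(0, 1))))
    return(brain_mask(vals, grid))
  volume_image(vals, grid)
}

#' Write a volume, mask or map as NIfTI
#'
#' Masks are written as unsigned 8-bit integers (bit-identical round trip);
#' time series, volumes and centrality/stat maps as 32-bit floats (round trip
#' within single precision). Voxel sizes — and, for 4D data, the repetition
#' time — are stored in the pixdim header fields.
#'
#' @param x a [timeseries_image()], [brain_mask()], [volume_image()], or a
#'   centrality/stat map (which is inserted into its mask grid first, with
#'   out-of-mask voxels at `fill`).
#' @param path output path (`.nii` or `.nii.gz`).
#' @param fill out-of-mask fill value used when writing masked maps.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, fill = 0) {
  if (inherits(x, "centrality_map") || inherits(x, "stat_map"))
    x <- insert_map(x$values, x$mask, fill = fill)
  if (inherits(x, "brain_mask")) {
    im <- RNifti::asNifti(array(as.integer(x$indicator), dim = x$grid$shape))
    RNifti::pixdim(im) <- x$grid$voxel_size
    RNifti::writeNifti(im, path, datatype = "uint8")
  } else if (inherits(x, "timeseries_image")) {
    im <- RNifti::asNifti(x$values)
    RNifti::pixdim(im) <- c(x$grid$voxel_size, x$tr_seconds)
    RNifti::writeNifti(im, path, datatype = "float")
  } else if (inherits(x, "volume_image")) {
    im <- RNifti::asNifti(x$values)
    RNifti::pixdim(im) <- x$grid$voxel_size
    RNifti::writeNifti(im, path, datatype = "float")
  } else stopf("don't know how to write an object of class %s", class(x)[1])
  invisible(path)
}

#' Extract the masked voxel x time matrix from a 4D image
#'
#' Row i of the result is the time course of the i-th in-mask voxel in
#' canonical (ascending column-major) order. [insert_matrix()] is the exact
#' inverse within the mask.
#'
#' @param img a [timeseries_image()].
#' @param mask a [brain_mask()] on the same grid.
#' @return A [voxel_matrix()].
#' @export
extract_matrix <- function(img, mask) {
  if (!same_grid(img$grid, mask$grid))
    stopf("image and mask are on different grids")
  flat <- matrix(img$values, nrow = prod(img$grid$shape))
  voxel_matrix(flat[mask$indices, , drop = FALSE], mask,
               tr_seconds = img$tr_seconds)
}

#' Insert masked values back into the full grid
#'
#' `insert_map()` places one value per in-mask voxel into a 3D volume;
#' `insert_matrix()` places a whole voxel x time matrix into a 4D image.
#' Out-of-mask voxels take `fill` (0 by default, `NA` available).
#'
#' @param values numeric vector of length `mask$n_voxels`, in canonical order.
#' @param mask a [brain_mask()].
#' @param fill value for out-of-mask voxels.
#' @return A [volume_image()].
#' @export
insert_map <- function(values, mask, fill = 0) {
  if (length(values) != mask$n_voxels)
    stopf("value count (%d) must equal mask$n_voxels (%d)",
          length(values), mask$n_voxels)
  arr <- array(fill, dim = mask$grid$shape)
  arr[mask$indices] <- values
  volume_image(arr, mask$grid)
}

#' @rdname insert_map
#' @param vm a [voxel_matrix()].
#' @return `insert_matrix()`: a [timeseries_image()].
#' @export
insert_matrix <- function(vm, fill = 0) {
  shape <- vm$mask$grid$shape
  Tn <- ncol(vm$data)
  flat <- matrix(fill, nrow = prod(shape), ncol = Tn)
  flat[vm$mask$indices, ] <- vm$data
  timeseries_image(array(flat, dim = c(shape, Tn)), vm$mask$grid,
                   tr_seconds = vm$tr_seconds)
}
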