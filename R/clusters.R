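# Cluster formation under a millimetre-radius neighborhood and Monte-Carlo
# cluster-size correction (AlphaSim style): simulate smoothed Gaussian null
# fields in the mask, record the maximal supra-threshold cluster size per
# iteration, and read off the minimal cluster extent whose family-wise
# occurrence is below alpha.

#' Voxel neighborhood from a millimetre radius
#'
#' All voxel offsets whose center-to-center distance is at most `rmm`
#' (excluding the zero offset). For 3 mm isotropic voxels, `rmm = 5` yields
#' 18-connectivity (faces at 3 mm and edges at 4.24 mm included, corners at
#' 5.20 mm excluded) and `rmm = 3` faces-only 6-connectivity.
#'
#' @param grid an [image_grid()] (or a numeric voxel-size vector).
#' @param rmm maximum center-to-center distance in mm (default 5).
#' @return Integer matrix of offsets (rows are (di, dj, dk)).
#' @export
neighbors_from_rmm <- function(grid, rmm = 5) {
  vs <- if (inherits(grid, "image_grid")) grid$voxel_size else as.numeric(grid)
  if (length(vs) == 1L) vs <- rep(vs, 3L)
  if (rmm <= 0) stopf("`rmm` must be positive")
  rng <- pmax(0L, floor(rmm / vs))
  offs <- as.matrix(expand.grid(di = -rng[1]:rng[1],
                                dj = -rng[2]:rng[2],
                                dk = -rng[3]:rng[3]))
  dist <- sqrt(colSums((t(offs) * vs)^2))
  keep <- dist <= rmm + 1e-9 & dist > 0
  if (!any(keep))
    stopf("rmm = %g mm is smaller than the smallest voxel dimension", rmm)
  offs[keep, , drop = FALSE]
}

# Connected components of a voxel set. coords: n x 3 integer matrix; dims:
# grid shape; offsets: K x 3 integer matrix. Returns integer component id
# per voxel (1-based, arbitrary order).
connected_components <- function(coords, dims, offsets) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  lin <- coords[, 1] + (coords[, 2] - 1L) * dims[1] +
    (coords[, 3] - 1L) * dims[1] * dims[2]
  lookup <- integer(prod(dims))
  lookup[lin] <- seq_len(n)
  comp <- integer(n)
  cur <- 0L
  K <- nrow(offsets)
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    comp[i] <- cur
    frontier <- i
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      m <- nrow(fc)
      cand <- fc[rep(seq_len(m), each = K), , drop = FALSE] +
        offsets[rep(seq_len(K), m), , drop = FALSE]
      ok <- cand[, 1] >= 1L & cand[, 1] <= dims[1] &
        cand[, 2] >= 1L & cand[, 2] <= dims[2] &
        cand[, 3] >= 1L & cand[, 3] <= dims[3]
      cand <- cand[ok, , drop = FALSE]
      cl <- cand[, 1] + (cand[, 2] - 1L) * dims[1] +
        (cand[, 3] - 1L) * dims[1] * dims[2]
      j <- lookup[cl]
      j <- unique(j[j > 0L])
      j <- j[comp[j] == 0L]
      comp[j] <- cur
      frontier <- j
    }
  }
  comp
}

# statistic threshold with per-voxel exceedance probability voxel_p
stat_threshold <- function(stat, voxel_p) {
  if (stat$type == "t") stats::qt(1 - voxel_p, df = stat$dof)
  else stats::qf(1 - voxel_p, df1 = stat$dof[1], df2 = stat$dof[2])
}

#' Label supra-threshold clusters of a statistic map
#'
#' Thresholds the map at the statistic value whose per-voxel exceedance
#' probability is `voxel_p` (one-tailed per direction for t maps; upper tail
#' for F maps) and labels connected components under the given neighborhood.
#' Positive and negative tails are labeled separately. Clusters are ordered
#' by descending size, ties broken by the smallest member voxel linear index.
#'
#' @param stat a `stat_map` carrying its mask.
#' @param voxel_p per-voxel probability threshold (default 0.01).
#' @param tail `"both"` (default for t), `"pos"` or `"neg"`.
#' @param rmm neighborhood radius in mm (see [neighbors_from_rmm()]).
#' @param mask [brain_mask()] if the map does not carry one.
#' @return Object of class `cluster_result`: `table` (data.frame with label,
#'   tail, size, peak statistic, peak voxel index and mm coordinates),
#'   `members` (list of mask-row index vectors) and `params`.
#' @export
label_clusters <- function(stat, voxel_p = 0.01, tail = c("both", "pos", "neg"),
                           rmm = 5, mask = NULL) {
  tail <- match.arg(tail)
  mask <- mask %||% stat$mask
  if (is.null(mask)) stopf("a mask is required to place statistics in space")
  if (length(stat$values) != mask$n_voxels)
    stopf("stat map length does not match the mask voxel count")
  if (stat$type == "F" && tail != "pos") tail <- "pos"
  thr <- stat_threshold(stat, voxel_p)
  offsets <- neighbors_from_rmm(mask$grid, rmm)
  coords <- mask_coords(mask)
  vals <- stat$values
  collect <- function(which_tail) {
    sel <- if (which_tail == "pos") which(vals > thr) else which(vals < -thr)
    if (!length(sel)) return(NULL)
    comp <- connected_components(coords[sel, , drop = FALSE], mask$grid$shape,
                                 offsets)
    lapply(seq_len(max(comp)), function(cid) {
      vox <- sel[comp == cid]
      pk <- vox[which.max(abs(vals[vox]))]
      list(tail = which_tail, members = vox, size = length(vox),
           peak_stat = vals[pk], peak_index = pk,
           min_lin = min(mask$indices[vox]))
    })
  }
  cl <- list()
  if (tail %in% c("both", "pos")) cl <- c(cl, collect("pos"))
  if (stat$type == "t" && tail %in% c("both", "neg")) cl <- c(cl, collect("neg"))
  if (!length(cl)) {
    tab <- data.frame(label = integer(0), tail = character(0), size = integer(0),
                      peak_stat = numeric(0), peak_index = integer(0),
                      peak_x_mm = numeric(0), peak_y_mm = numeric(0),
                      peak_z_mm = numeric(0))
    return(structure(list(table = tab, members = list(), mask = mask,
                          params = list(voxel_p = voxel_p, threshold = thr,
                                        rmm = rmm, tail = tail)),
                     class = "cluster_result"))
  }
  ord <- order(-vapply(cl, `[[`, integer(1), "size"),
               vapply(cl, `[[`, numeric(1), "min_lin"))
  cl <- cl[ord]
  mm <- mask_coords_mm(mask)
  tab <- data.frame(
    label = seq_along(cl),
    tail = vapply(cl, `[[`, character(1), "tail"),
    size = vapply(cl, `[[`, integer(1), "size"),
    peak_stat = vapply(cl, `[[`, numeric(1), "peak_stat"),
    peak_index = vapply(cl, `[[`, integer(1), "peak_index"))
  tab$peak_x_mm <- mm[tab$peak_index, 1]
  tab$peak_y_mm <- mm[tab$peak_index, 2]
  tab$peak_z_mm <- mm[tab$peak_index, 3]
  structure(list(table = tab, members = lapply(cl, `[[`, "members"),
                 mask = mask,
                 params = list(voxel_p = voxel_p, threshold = thr,
                               rmm = rmm, tail = tail)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s) at voxel p = %g, rmm = %g mm\n",
              nrow(x$table), x$params$voxel_p, x$params$rmm))
  if (nrow(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo cluster-size threshold (AlphaSim style)
#'
#' Each iteration fills the mask bounding box with unit Gaussian white noise,
#' smooths it to `fwhm_mm`, restricts it to the mask, re-standardizes the
#' in-mask values to zero mean and unit variance (so kernel-edge variance
#' loss cannot deflate the voxel threshold), thresholds at the one-tailed
#' normal quantile for `voxel_p`, and records the maximal cluster size under
#' the `rmm` neighborhood. The critical size for a corrected level alpha is
#' the smallest k such that the fraction of iterations whose maximum reaches
#' k is at most alpha.
#'
#' @param mask a [brain_mask()].
#' @param fwhm_mm smoothness of the simulated null fields in mm (use the
#'   smoothing actually applied to the data; 0 for unsmoothed fields).
#' @param voxel_p per-voxel one-tailed probability threshold.
#' @param rmm neighborhood radius in mm.
#' @param iterations Monte-Carlo iterations (>= 100).
#' @param alpha corrected family-wise level(s) to tabulate (0.05 always
#'   included).
#' @param seed RNG seed; results are reproducible.
#' @return Object of class `alphasim_result`: `alpha_to_k` (data.frame),
#'   `null_max_sizes`, and the simulation parameters.
#' @export
alphasim_threshold <- function(mask, fwhm_mm = 6, voxel_p = 0.01, rmm = 5,
                               iterations = 1000, alpha = 0.05, seed = NULL) {
  if (iterations < 100) stopf("`iterations` must be >= 100")
  if (voxel_p <= 0 || voxel_p >= 1) stopf("`voxel_p` must be in (0, 1)")
  if (any(alpha <= 0 | alpha > 1)) stopf("`alpha` must be in (0, 1]")
  grid <- mask$grid
  coords <- mask_coords(mask)
  lo <- apply(coords, 2, min)
  hi <- apply(coords, 2, max)
  bdims <- hi - lo + 1L
  bgrid <- image_grid(bdims, grid$voxel_size)
  bind <- array(FALSE, dim = bdims)
  bcoords <- sweep(coords, 2, lo - 1L)
  bind[bcoords] <- TRUE
  if (fwhm_mm > 0) {
    sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / grid$voxel_size
    if (any(bdims < 2 * ceiling(4 * sigma_vox) + 1))
      warnf(paste0("mask bounding box is smaller than the smoothing kernel ",
                   "support; proceeding with a truncated kernel"))
  }
  zcrit <- stats::qnorm(1 - voxel_p)
  offsets <- neighbors_from_rmm(grid, rmm)
  max_sizes <- with_seed(seed, {
    ms <- integer(iterations)
    for (it in seq_len(iterations)) {
      arr <- array(stats::rnorm(prod(bdims)), dim = bdims)
      if (fwhm_mm > 0)
        arr <- smooth_gaussian(volume_image(arr, bgrid), fwhm_mm)$values
      v <- arr[bind]
      v <- (v - mean(v)) / stats::sd(v)
      sel <- which(v > zcrit)
      if (!length(sel)) next
      comp <- connected_components(bcoords[sel, , drop = FALSE], bdims, offsets)
      ms[it] <- max(tabulate(comp))
    }
    ms
  })
  alphas <- sort(unique(c(alpha, 0.05)), decreasing = TRUE)
  kmax <- max(max_sizes, 1L)
  exceed <- vapply(seq_len(kmax + 1L), function(k)
    mean(max_sizes >= k), numeric(1))
  k_for <- vapply(alphas, function(a) {
    which(exceed <= a)[1]                     # exceed is nonincreasing in k
  }, integer(1))
  structure(list(voxel_p = voxel_p, fwhm_mm = fwhm_mm, rmm = rmm,
                 iterations = iterations,
                 alpha_to_k = data.frame(alpha = alphas, k = k_for),
                 null_max_sizes = max_sizes, seed = seed),
            class = "alphasim_result")
}

#' @export
print.alphasim_result <- function(x, ...) {
  cat(sprintf(paste0("alphasim_result: voxel p = %g, FWHM = %g mm, rmm = %g, ",
                     "%d iterations\n"),
              x$voxel_p, x$fwhm_mm, x$rmm, x$iterations))
  print(x$alpha_to_k, row.names = FALSE)
  invisible(x)
}

#' Critical cluster size at a corrected level
#'
#' @param asr an `alphasim_result`.
#' @param alpha corrected family-wise level.
#' @return The minimal cluster size k (integer).
#' @export
critical_k <- function(asr, alpha = 0.05) {
  hit <- asr$alpha_to_k$k[abs(asr$alpha_to_k$alpha - alpha) < 1e-12]
  if (length(hit)) return(hit[1])
  kmax <- max(asr$null_max_sizes, 1L)
  exceed <- vapply(seq_len(kmax + 1L), function(k)
    mean(asr$null_max_sizes >= k), numeric(1))
  which(exceed <= alpha)[1]
}

#' Apply the Monte-Carlo cluster-size correction
#'
#' Flags each cluster as surviving when its size reaches the critical size
#' for `alpha`. The cluster result and the simulation must have been formed
#' with the same voxel-wise threshold probability and neighborhood radius.
#'
#' @param clusters a `cluster_result`.
#' @param asr an `alphasim_result`.
#' @param alpha corrected family-wise level (default 0.05).
#' @return The `cluster_result` with a `surviving` column and `critical_k`
#'   recorded in `params`.
#' @export
apply_cluster_correction <- function(clusters, asr, alpha = 0.05) {
  if (abs(clusters$params$voxel_p - asr$voxel_p) > 1e-12 ||
      abs(clusters$params$rmm - asr$rmm) > 1e-9)
    stopf(paste0("cluster result (voxel_p = %g, rmm = %g) and simulation ",
                 "(voxel_p = %g, rmm = %g) were formed with different ",
                 "parameters"),
          clusters$params$voxel_p, clusters$params$rmm, asr$voxel_p, asr$rmm)
  k <- critical_k(asr, alpha)
  clusters$table$surviving <- clusters$table$size >= k
  clusters$params$critical_k <- k
  clusters$params$alpha <- alpha
  clusters
}
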