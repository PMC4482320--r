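# Morphometry (brain parenchymal fraction, white-matter lesion load) and
# cluster-level regression of centrality on clinical metrics.

tissue_volume_ml <- function(x, grid = NULL) {
  if (inherits(x, "brain_mask"))
    return(x$n_voxels * voxel_volume_mm3(x$grid) / 1000)
  if (inherits(x, "volume_image")) {
    if (any(x$values < -1e-9 | x$values > 1 + 1e-9))
      stopf("tissue probabilities must lie in [0, 1]")
    return(sum(x$values) * voxel_volume_mm3(x$grid) / 1000)
  }
  stopf("tissue inputs must be brain_mask or volume_image objects")
}

grid_of <- function(x) x$grid

#' Brain parenchymal fraction
#'
#' BPF = (gray + white matter volume) / (gray + white + CSF volume), the
#' standard whole-brain atrophy index. Inputs may be binary masks or
#' tissue-probability volumes; probabilities are integrated as probability
#' mass times voxel volume rather than thresholded.
#'
#' @param gm,wm,csf tissue masks ([brain_mask()]) or probability volumes
#'   ([volume_image()]), all on the same grid.
#' @return The parenchymal fraction (scalar in (0, 1]).
#' @export
compute_bpf <- function(gm, wm, csf) {
  g <- grid_of(gm)
  if (!same_grid(g, grid_of(wm)) || !same_grid(g, grid_of(csf)))
    stopf("tissue volumes must share one grid")
  v_gm <- tissue_volume_ml(gm)
  v_wm <- tissue_volume_ml(wm)
  v_csf <- tissue_volume_ml(csf)
  icv <- v_gm + v_wm + v_csf
  if (icv <= 0) stopf("degenerate input: zero intracranial volume")
  (v_gm + v_wm) / icv
}

#' Total white-matter lesion load
#'
#' Summed lesion volume in ml from a binary lesion mask:
#' voxel count x voxel volume / 1000.
#'
#' @param lesion_mask a [brain_mask()] of lesion voxels, or `NULL`/a mask
#'   with zero voxels for a lesion-free scan.
#' @return Lesion load in ml.
#' @export
compute_twmll <- function(lesion_mask) {
  if (is.null(lesion_mask)) return(0)
  lesion_mask$n_voxels * voxel_volume_mm3(lesion_mask$grid) / 1000
}

#' Mean centrality per cluster per subject
#'
#' @param Y subjects x voxels matrix of (converted) centrality values, or a
#'   list of `centrality_map`s.
#' @param clusters a `cluster_result`; only clusters listed in its table are
#'   extracted (pass a corrected result to restrict to survivors upstream).
#' @return Matrix subjects x clusters of arithmetic means over each
#'   cluster's voxels; columns named `cluster_<label>`.
#' @export
cluster_mean_extract <- function(Y, clusters) {
  if (is.list(Y) && !is.matrix(Y)) Y <- stack_maps(Y)
  if (!nrow(clusters$table)) stopf("no clusters to extract")
  if (any(vapply(clusters$members, length, integer(1)) == 0L))
    stopf("empty cluster in the cluster result")
  out <- vapply(clusters$members, function(vox)
    rowMeans(Y[, vox, drop = FALSE]), numeric(nrow(Y)))
  out <- matrix(out, nrow = nrow(Y))
  colnames(out) <- paste0("cluster_", clusters$table$label)
  out
}

#' Cluster-level clinical regression with Bonferroni correction
#'
#' For each cluster and clinical metric, fits ordinary least squares of the
#' cluster-mean centrality on [intercept, metric, age, gender] and reports
#' the metric coefficient: slope, t, partial correlation (sign matching the
#' slope), uncorrected p, and Bonferroni-corrected p over the declared
#' family. The default family is (number of clusters) x (number of metrics).
#'
#' @param cluster_means subjects x clusters matrix (see
#'   [cluster_mean_extract()]) or a vector for a single cluster.
#' @param metrics data frame (or named list) of clinical metric columns, one
#'   value per subject; or a single numeric vector.
#' @param covariates data frame with `age` and `gender` columns (may be
#'   `NULL` for an unadjusted fit).
#' @param family_size number of tests in the correction family; defaults to
#'   clusters x metrics.
#' @return Data frame with one row per cluster x metric: `cluster`, `metric`,
#'   `n`, `slope`, `t`, `partial_r`, `p_uncorrected`, `p_bonferroni`;
#'   attribute `family_size` declares the family used.
#' @export
clinical_regression <- function(cluster_means, metrics, covariates = NULL,
                                family_size = NULL) {
  if (is.null(dim(cluster_means)))
    cluster_means <- matrix(cluster_means, ncol = 1,
                            dimnames = list(NULL, "cluster_1"))
  if (is.numeric(metrics)) metrics <- data.frame(metric = metrics)
  metrics <- as.data.frame(metrics)
  n <- nrow(cluster_means)
  if (nrow(metrics) != n)
    stopf("metrics have %d rows; expected %d", nrow(metrics), n)
  Xcov <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    Xcov <- as.matrix(covariates)
  }
  p_model <- 2L + if (is.null(Xcov)) 0L else ncol(Xcov)
  family_size <- family_size %||% (ncol(cluster_means) * ncol(metrics))
  rows <- list()
  for (ci in seq_len(ncol(cluster_means))) {
    for (mi in seq_len(ncol(metrics))) {
      y <- cluster_means[, ci]
      x <- metrics[[mi]]
      ok <- is.finite(y) & is.finite(x)
      if (!is.null(Xcov)) ok <- ok & apply(is.finite(Xcov), 1, all)
      if (sum(ok) < p_model + 1L)
        stopf("cluster %d / metric %s: only %d complete cases for %d parameters",
              ci, names(metrics)[mi], sum(ok), p_model)
      X <- cbind(1, metric = x[ok], Xcov[ok, , drop = FALSE])
      fit <- stats::lm.fit(X, y[ok])
      dof <- sum(ok) - fit$rank
      s2 <- sum(fit$residuals^2) / dof
      XtXinv <- chol2inv(chol(crossprod(X)))
      tval <- fit$coefficients["metric"] / sqrt(s2 * XtXinv[2, 2])
      p <- 2 * stats::pt(-abs(tval), dof)
      pr <- sign(tval) * sqrt(tval^2 / (tval^2 + dof))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = colnames(cluster_means)[ci] %||% paste0("cluster_", ci),
        metric = names(metrics)[mi],
        n = sum(ok),
        slope = unname(fit$coefficients["metric"]),
        t = unname(tval),
        partial_r = unname(pr),
        p_uncorrected = unname(p),
        p_bonferroni = unname(min(1, p * family_size)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "family_size") <- family_size
  out
}
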