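# Voxel-wise network centrality within a mask.
#
# Degree centrality (DC): for voxel i, the sum over all other in-mask voxels
# of the Pearson correlation r_ij, restricted to r_ij > r0 (weighted mode) or
# the count of such voxels (binary mode). Self-correlation is excluded, so
# uncorrelated data gives DC near 0. Computed in row blocks so the full
# N x N correlation matrix is never materialized.
#
# Eigenvector centrality (EC): the principal eigenvector of A = (C + 1) / 2,
# where C is the in-mask correlation matrix. The elementwise shift makes A
# nonnegative, so the Perron-Frobenius principal eigenvector is unique and
# nonnegative. A is never formed: A v = (Z (Z' v) / (T - 1) + sum(v)) / 2 for
# the row-standardized data matrix Z.

new_centrality_map <- function(values, mask, metric, r0 = NA_real_,
                               normalization = character(0)) {
  structure(list(values = as.numeric(values), mask = mask, metric = metric,
                 r0 = r0, normalization = normalization),
            class = "centrality_map")
}

#' @export
print.centrality_map <- function(x, ...) {
  cat(sprintf("centrality_map: %s over %d voxels%s%s\n", x$metric,
              length(x$values),
              if (!is.na(x$r0)) sprintf(", r0 = %g", x$r0) else "",
              if (length(x$normalization))
                paste0(" [", paste(x$normalization, collapse = " -> "), "]")
              else " [raw]"))
  invisible(x)
}

#' Standardize voxel rows for correlation by dot product
#'
#' Centers each row and scales it to sum of squares T - 1, so that the dot
#' product of two rows divided by T - 1 equals their Pearson correlation.
#' Rows with zero variance are flagged, set to zero (hence correlation 0 with
#' everything — they drop out of centrality) and reported in the
#' `"qc_zero_variance"` attribute.
#'
#' @param vm a [voxel_matrix()].
#' @return A standardized [voxel_matrix()]; attribute `qc_zero_variance`
#'   holds the row indices that were flagged (integer(0) if none).
#' @export
standardize_rows <- function(vm) {
  X <- vm$data
  Tn <- ncol(X)
  Xc <- X - rowMeans(X)
  ss <- rowSums(Xc^2)
  bad <- which(ss < 1e-24)
  scl <- sqrt(ss / (Tn - 1))
  scl[bad] <- 1
  Z <- Xc / scl
  if (length(bad)) Z[bad, ] <- 0
  out <- voxel_matrix(Z, vm$mask, tr_seconds = vm$tr_seconds,
                      standardized = TRUE, detrended = vm$detrended)
  attr(out, "qc_zero_variance") <- bad
  out
}

check_standardized <- function(vm) {
  if (!vm$standardized)
    stopf("input must be standardized; call standardize_rows() first")
}

#' Weighted degree centrality (blockwise)
#'
#' @param vm a standardized [voxel_matrix()] (see [standardize_rows()]).
#' @param r0 correlation threshold in (0, 1) eliminating weak correlations
#'   (default 0.25).
#' @param mode `"weighted_positive"` (sum of supra-threshold correlations)
#'   or `"binary"` (count of supra-threshold neighbors).
#' @param block_size rows per block of the blockwise pass (default 1024);
#'   results are identical across block sizes.
#' @return A `centrality_map` with metric `"DC"`.
#' @export
degree_centrality <- function(vm, r0 = 0.25,
                              mode = c("weighted_positive", "binary"),
                              block_size = 1024) {
  maps <- multi_threshold_dc(vm, r0_values = r0, mode = mode,
                             block_size = block_size)
  maps[[1]]
}

#' Degree centrality at several thresholds in one pass
#'
#' Computes DC maps for every threshold in `r0_values` during a single
#' blockwise sweep over the correlation structure.
#'
#' @inheritParams degree_centrality
#' @param r0_values strictly increasing thresholds in (0, 1); the
#'   conventional exploration set is `c(0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4)`.
#' @return A named list of `centrality_map`s, one per threshold.
#' @export
multi_threshold_dc <- function(vm, r0_values = c(0.1, 0.15, 0.2, 0.25,
                                                 0.3, 0.35, 0.4),
                               mode = c("weighted_positive", "binary"),
                               block_size = 1024) {
  mode <- match.arg(mode)
  check_standardized(vm)
  if (length(r0_values) < 1L) stopf("at least one threshold is required")
  if (any(r0_values <= 0 | r0_values >= 1))
    stopf("thresholds must lie strictly in (0, 1)")
  if (is.unsorted(r0_values, strictly = TRUE))
    stopf("`r0_values` must be strictly increasing")
  Z <- vm$data
  N <- nrow(Z)
  Tn <- ncol(Z)
  dc <- matrix(0, N, length(r0_values))
  starts <- seq(1L, N, by = block_size)
  for (s in starts) {
    rows <- s:min(s + block_size - 1L, N)
    R <- tcrossprod(Z[rows, , drop = FALSE], Z) / (Tn - 1)
    R[cbind(seq_along(rows), rows)] <- 0           # exclude self-correlation
    for (k in seq_along(r0_values)) {
      M <- R > r0_values[k]
      dc[rows, k] <- if (mode == "weighted_positive") rowSums(R * M)
                     else rowSums(M)
    }
  }
  out <- lapply(seq_along(r0_values), function(k)
    new_centrality_map(dc[, k], vm$mask, "DC", r0 = r0_values[k]))
  names(out) <- sprintf("r0_%g", r0_values)
  out
}

#' Matrix-free eigenvector centrality (fast ECM)
#'
#' Power iteration on the shifted correlation matrix A = (C + 1)/2 using only
#' matrix-vector products through the standardized data matrix, so the N x N
#' correlation matrix is never stored. Iterates from the uniform vector
#' (deterministic start) until successive unit-norm iterates differ by less
#' than `tol` in Euclidean norm. The result is nonnegative with unit
#' Euclidean norm; rows flagged as zero-variance are forced to 0.
#'
#' @param vm a standardized [voxel_matrix()].
#' @param tol convergence tolerance on the successive-iterate difference
#'   (default 1e-12).
#' @param max_iter iteration cap (default 1000); non-convergence returns the
#'   last iterate with a warning and `converged = FALSE`.
#' @return A `centrality_map` with metric `"EC"` and attributes `lambda1`
#'   (principal-eigenvalue estimate), `iterations`, `converged`.
#' @export
fast_eigenvector_centrality <- function(vm, tol = 1e-12, max_iter = 1000) {
  check_standardized(vm)
  Z <- vm$data
  N <- nrow(Z)
  if (N < 2L) stopf("eigenvector centrality needs at least 2 voxels")
  Tn <- ncol(Z)
  bad <- attr(vm, "qc_zero_variance") %||% integer(0)
  amul <- function(v) (as.numeric(Z %*% crossprod(Z, v)) / (Tn - 1) + sum(v)) / 2
  v <- rep(1 / sqrt(N), N)
  lambda <- NA_real_
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- amul(v)
    lambda <- sum(v * w)                      # Rayleigh quotient
    nw <- sqrt(sum(w^2))
    if (nw == 0) stopf("power iteration collapsed to the zero vector")
    w <- w / nw
    if (sqrt(sum((w - v)^2)) < tol) {
      v <- w
      converged <- TRUE
      break
    }
    v <- w
  }
  if (!converged)
    warnf(paste0("power iteration did not converge in %d iterations ",
                 "(last step %.3g); returning the current iterate"),
          max_iter, sqrt(sum((v - amul(v) / sqrt(sum(amul(v)^2)))^2)))
  v <- pmax(v, 0)
  if (length(bad)) v[bad] <- 0
  v <- v / sqrt(sum(v^2))
  out <- new_centrality_map(v, vm$mask, "EC")
  attr(out, "lambda1") <- lambda
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  out
}

#' Divide a map by its in-mask global mean
#'
#' The individual-level normalization that expresses each voxel's centrality
#' relative to the subject's mean within the mask (k/k0 for DC, u/u0 for EC);
#' the normalized map has in-mask mean exactly 1.
#'
#' @param cm a `centrality_map`.
#' @return The normalized `centrality_map` (normalization step recorded).
#' @export
normalize_global_mean <- function(cm) {
  m <- mean(cm$values)
  if (!is.finite(m) || abs(m) < 1e-15)
    stopf("degenerate map: in-mask mean is zero")
  out <- cm
  out$values <- cm$values / m
  out$normalization <- c(cm$normalization, "global_mean")
  out
}

#' Convert a map for group comparison
#'
#' `"z_standardize"` maps values to mean 0, SD 1 over the mask. `"fisher_z"`
#' applies atanh, which is only defined for correlation-scale values strictly
#' inside (-1, 1); mean-normalized degree maps generally leave that range, in
#' which case z-standardization is the appropriate conversion.
#'
#' @param cm a `centrality_map`.
#' @param method `"z_standardize"` (default) or `"fisher_z"`.
#' @return The converted `centrality_map`.
#' @export
convert_for_group <- function(cm, method = c("z_standardize", "fisher_z")) {
  method <- match.arg(method)
  out <- cm
  if (method == "z_standardize") {
    s <- stats::sd(cm$values)
    if (!is.finite(s) || s == 0) stopf("degenerate map: zero variance")
    out$values <- (cm$values - mean(cm$values)) / s
    out$normalization <- c(cm$normalization, "z_standardized")
  } else {
    if (any(cm$values <= -1 | cm$values >= 1))
      stopf(paste0("fisher_z requires all values strictly inside (-1, 1); ",
                   "this map has values outside that range - use ",
                   "convert_for_group(cm, \"z_standardize\") instead"))
    out$values <- atanh(cm$values)
    out$normalization <- c(cm$normalization, "fisher_z")
  }
  out
}

#' Rank-Gaussian (normally distributed ranks) normalization
#'
#' Replaces values by average ranks (midranks for ties), converts them to
#' Blom plotting positions (rank - 3/8)/(N + 1/4), and applies the standard
#' normal quantile function — yielding an approximately standard-normal map
#' that preserves rank order. An all-tied map maps to all zeros.
#'
#' @param cm a `centrality_map` with at least 2 voxels.
#' @return The rank-normalized `centrality_map`.
#' @export
rank_gauss <- function(cm) {
  n <- length(cm$values)
  if (n < 2L) stopf("rank normalization needs at least 2 voxels")
  r <- rank(cm$values, ties.method = "average")
  out <- cm
  out$values <- stats::qnorm((r - 3 / 8) / (n + 1 / 4))
  out$normalization <- c(cm$normalization, "rank_gauss")
  out
}
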