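# Voxel-wise group inference: GLM contrasts with covariates, paired tests,
# ANCOVA. Maps enter as a subjects x voxels matrix (one converted centrality
# map per row); designs are ordinary model matrices.

new_stat_map <- function(values, dof, type = c("t", "F"), mask = NULL) {
  type <- match.arg(type)
  structure(list(values = as.numeric(values), dof = dof, type = type,
                 mask = mask), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map: %s over %d voxels, dof %s (%d non-finite)\n",
              x$type, length(x$values), paste(x$dof, collapse = ", "),
              sum(!is.finite(x$values))))
  invisible(x)
}

#' Stack per-subject centrality maps into a subjects x voxels matrix
#'
#' @param maps list of `centrality_map`s on the same mask.
#' @return Numeric matrix with one row per map.
#' @export
stack_maps <- function(maps) {
  n <- unique(vapply(maps, function(m) length(m$values), integer(1)))
  if (length(n) != 1L) stopf("maps have differing voxel counts")
  do.call(rbind, lapply(maps, function(m) m$values))
}

#' Build a group design matrix with covariates
#'
#' Constructs the ordinary model matrix for `~ group + covariates` with
#' treatment coding, centers numeric covariates (which leaves group
#' contrasts untouched and only moves the intercept), and returns the
#' contrast vector selecting the group-difference column.
#'
#' @param data data frame with a `group` column (2 levels) and the covariate
#'   columns (e.g. `age`, `gender`; gender coded 0/1).
#' @param covariates character vector of covariate column names.
#' @return List with `X` (model matrix), `contrast` (second group level
#'   minus first) and `group_levels`.
#' @export
build_design <- function(data, covariates = c("age", "gender")) {
  data$group <- factor(data$group)
  if (nlevels(data$group) != 2L)
    stopf("build_design() expects exactly 2 group levels; got %d",
          nlevels(data$group))
  fml <- stats::reformulate(c("group", covariates))
  X <- stats::model.matrix(fml, data)
  for (cv in covariates)
    if (is.numeric(data[[cv]]))
      X[, cv] <- X[, cv] - mean(X[, cv])
  contrast <- as.numeric(grepl("^group", colnames(X)))
  list(X = X, contrast = contrast, group_levels = levels(data$group))
}

# shared OLS machinery: returns list(coef p x N, rss N, dof, qx, X)
fit_glm_vox <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    warnf("design is rank deficient; dropping column(s): %s",
          paste(drop, collapse = ", "))
    X <- X[, qx$pivot[seq_len(qx$rank)], drop = FALSE]
    qx <- qr(X)
  }
  Q <- qr.Q(qx)
  fitted <- Q %*% (t(Q) %*% Y)
  res <- Y - fitted
  list(X = X, qx = qx, rss = colSums(res^2), dof = nrow(X) - qx$rank)
}

#' Voxel-wise GLM t-map for a contrast
#'
#' Ordinary least squares at every voxel with a common design;
#' t = c'b / sqrt(s2 c'(X'X)^-1 c), dof = n - rank(X). Voxels with zero
#' residual variance get a non-finite statistic (NaN) and are counted in the
#' `n_flagged` attribute.
#'
#' @param Y subjects x voxels matrix (see [stack_maps()]).
#' @param X design matrix (subjects x parameters), or the list returned by
#'   [build_design()].
#' @param contrast numeric contrast vector (ignored when `X` comes from
#'   [build_design()], which supplies its own).
#' @param mask optional [brain_mask()] carried on the result.
#' @return A `stat_map` of t statistics.
#' @export
glm_tmap <- function(Y, X, contrast = NULL, mask = NULL) {
  if (is.list(X) && !is.null(X$X)) {
    contrast <- contrast %||% X$contrast
    X <- X$X
  }
  if (is.null(contrast)) stopf("a contrast vector is required")
  if (length(contrast) != ncol(X))
    stopf("contrast length (%d) must equal the design column count (%d)",
          length(contrast), ncol(X))
  keep_names <- colnames(X)
  fit <- fit_glm_vox(Y, X)
  if (ncol(fit$X) != length(contrast))       # columns were pruned
    contrast <- contrast[match(colnames(fit$X), keep_names)]
  if (fit$dof < 1L) stopf("no residual degrees of freedom")
  beta <- qr.coef(fit$qx, Y)
  cb <- as.numeric(crossprod(contrast, beta))
  XtX <- crossprod(fit$X)
  quad <- as.numeric(crossprod(contrast, solve(XtX, contrast)))
  sigma2 <- fit$rss / fit$dof
  tval <- cb / sqrt(sigma2 * quad)
  out <- new_stat_map(tval, fit$dof, "t", mask)
  attr(out, "n_flagged") <- sum(!is.finite(tval))
  out
}

#' Paired t-map on matched map lists
#'
#' One-sample t on within-pair differences (rows of `Ya` minus matched rows
#' of `Yb`), dof = n - 1. Voxels whose differences are all zero are flagged
#' non-finite.
#'
#' @param Ya,Yb matched subjects x voxels matrices (same order).
#' @param mask optional [brain_mask()].
#' @return A `stat_map` of paired t statistics.
#' @export
paired_tmap <- function(Ya, Yb, mask = NULL) {
  if (!all(dim(Ya) == dim(Yb))) stopf("paired matrices must match in shape")
  n <- nrow(Ya)
  if (n < 2L) stopf("paired test needs at least 2 pairs")
  D <- Ya - Yb
  m <- colMeans(D)
  s <- sqrt(colSums(sweep(D, 2, m)^2) / (n - 1))
  tval <- m / (s / sqrt(n))                  # 0/0 -> NaN flags zero-sd voxels
  out <- new_stat_map(tval, n - 1L, "t", mask)
  attr(out, "n_flagged") <- sum(!is.finite(tval))
  out
}

#' Voxel-wise ANCOVA F-map for the group factor
#'
#' Partial F test for a multi-level group factor adjusting for covariates:
#' compares the full model `~ group + covariates` to the reduced model
#' without the group factor. Numerator dof = (number of groups - 1),
#' denominator dof = n - rank(full design).
#'
#' @param Y subjects x voxels matrix.
#' @param data data frame with `group` (>= 2 levels) and covariate columns.
#' @param covariates covariate column names (default age and gender).
#' @param mask optional [brain_mask()].
#' @return A `stat_map` of F statistics with `dof = c(df1, df2)`.
#' @export
ancova_fmap <- function(Y, data, covariates = c("age", "gender"), mask = NULL) {
  data$group <- factor(data$group)
  g <- nlevels(data$group)
  if (g < 2L) stopf("ANCOVA needs at least 2 groups")
  tab <- table(data$group)
  if (any(tab < 2L)) stopf("every group needs at least 2 subjects")
  X_full <- stats::model.matrix(stats::reformulate(c("group", covariates)), data)
  X_red <- if (length(covariates))
    stats::model.matrix(stats::reformulate(covariates), data)
  else matrix(1, nrow(Y), 1)
  fit1 <- fit_glm_vox(Y, X_full)
  fit0 <- fit_glm_vox(Y, X_red)
  q <- (ncol(fit1$X) - ncol(fit0$X))
  if (q < 1L) stopf("group factor vanished from the design")
  Fval <- ((fit0$rss - fit1$rss) / q) / (fit1$rss / fit1$dof)
  out <- new_stat_map(Fval, c(q, fit1$dof), "F", mask)
  attr(out, "n_flagged") <- sum(!is.finite(Fval))
  out
}
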