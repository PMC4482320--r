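# Seeded synthetic-data generation: masked 4D time series with latent
# community/hub correlation structure, group studies with paired sessions and
# clinical covariates, motion traces, and segmentation/lesion volumes.
#
# Latent-factor construction: voxel time courses are weighted sums of
# unit-variance community signals plus AR(1) voxel noise, so population
# correlations have the closed form
#   r_ij = (l_i . l_j) / sqrt((|l_i|^2 + sd^2) (|l_j|^2 + sd^2))
# where l_i is voxel i's loading row and sd the marginal noise SD. Two voxels
# sharing one community with weight w therefore correlate at w^2/(w^2 + sd^2).

#' Hub/community specification for synthetic time series
#'
#' @param communities list of communities, each a `list(voxels = <integer
#'   mask-row indices>, weight = <loading on that community's latent signal>)`.
#' @param hub_voxels integer mask-row indices of hub voxels, which load on
#'   every community latent with `hub_weight` (overriding their community
#'   loadings); may be empty.
#' @param hub_weight loading of hub voxels on each latent signal.
#' @param noise_sd marginal standard deviation of the voxel-specific AR(1)
#'   noise.
#' @param ar1 lag-1 autocorrelation of the noise, in [0, 1).
#' @param n_voxels number of mask voxels the indices refer to.
#' @return Object of class `hub_spec`.
#' @export
hub_spec <- function(communities, hub_voxels = integer(0), hub_weight = 1,
                     noise_sd = 1, ar1 = 0.3, n_voxels) {
  if (!is.list(communities) || length(communities) < 1L)
    stopf("at least one community must be specified")
  for (cm in communities) {
    if (is.null(cm$voxels) || length(cm$voxels) < 1L)
      stopf("each community needs a non-empty voxel set")
    if (any(cm$voxels < 1L | cm$voxels > n_voxels))
      stopf("community voxel indices must lie in 1..n_voxels")
    if (!is.finite(cm$weight)) stopf("community weights must be finite")
  }
  if (length(hub_voxels) && any(hub_voxels < 1L | hub_voxels > n_voxels))
    stopf("hub voxel indices must lie in 1..n_voxels")
  if (!is.finite(ar1) || ar1 < 0 || ar1 >= 1) stopf("`ar1` must be in [0, 1)")
  if (!is.finite(noise_sd) || noise_sd < 0) stopf("`noise_sd` must be >= 0")
  structure(list(communities = communities, hub_voxels = as.integer(hub_voxels),
                 hub_weight = hub_weight, noise_sd = noise_sd, ar1 = ar1,
                 n_voxels = as.integer(n_voxels)),
            class = "hub_spec")
}

# N x C loading matrix implied by a hub_spec, with optional per-voxel additive
# shift on the voxel's nonzero loadings (voxels with none are attached to
# community 1) and a global multiplicative scale.
loading_matrix <- function(hubs, loading_shift = NULL, loading_scale = 1) {
  C <- length(hubs$communities)
  L <- matrix(0, hubs$n_voxels, C)
  for (c in seq_len(C))
    L[hubs$communities[[c]]$voxels, c] <- hubs$communities[[c]]$weight
  if (length(hubs$hub_voxels)) L[hubs$hub_voxels, ] <- hubs$hub_weight
  L <- L * loading_scale
  if (!is.null(loading_shift)) {
    hit <- which(loading_shift != 0)
    for (i in hit) {
      nz <- which(L[i, ] != 0)
      if (!length(nz)) nz <- 1L
      L[i, nz] <- L[i, nz] + loading_shift[i]
    }
  }
  L
}

#' Population correlation and degree centrality implied by a hub spec
#'
#' Closed-form quantities of the latent-factor model, used as planted ground
#' truth: `expected_correlation()` returns the N x N population correlation
#' matrix, `expected_dc()` the population weighted degree centrality (sum of
#' supra-threshold positive correlations, self excluded).
#'
#' @param hubs a [hub_spec()].
#' @param r0 correlation threshold.
#' @inheritParams degree_centrality
#' @return A matrix, or a numeric vector of length `n_voxels`.
#' @export
expected_correlation <- function(hubs) {
  L <- loading_matrix(hubs)
  v <- rowSums(L^2) + hubs$noise_sd^2
  if (any(v <= 0))
    stopf("some voxels have zero total variance (zero loadings and zero noise)")
  C <- tcrossprod(L) / sqrt(outer(v, v))
  diag(C) <- 1
  C
}

#' @rdname expected_correlation
#' @export
expected_dc <- function(hubs, r0 = 0.25, mode = c("weighted_positive", "binary")) {
  mode <- match.arg(mode)
  C <- expected_correlation(hubs)
  diag(C) <- 0
  if (mode == "weighted_positive") rowSums(C * (C > r0)) else rowSums(C > r0)
}

#' Generate a connected blob-like toy mask
#'
#' Grows a single 6-connected region from the grid center by repeatedly
#' annexing a random frontier voxel, giving an irregular but connected blob
#' with exactly `target_voxels` voxels.
#'
#' @param shape grid shape (3 integers).
#' @param target_voxels number of in-mask voxels (>= 1, <= prod(shape)).
#' @param seed RNG seed (same seed, same mask).
#' @param voxel_size mm per axis, default 3 mm isotropic.
#' @return A [brain_mask()].
#' @export
make_toy_mask <- function(shape, target_voxels, seed = NULL,
                          voxel_size = c(3, 3, 3)) {
  grid <- image_grid(shape, voxel_size)
  n_total <- prod(grid$shape)
  if (target_voxels < 1L || target_voxels > n_total)
    stopf("`target_voxels` must be in 1..prod(shape) = %d", n_total)
  d <- grid$shape
  with_seed(seed, {
    inmask <- logical(n_total)
    infrontier <- logical(n_total)
    start <- (ceiling(d[1] / 2)) +
      (ceiling(d[2] / 2) - 1L) * d[1] +
      (ceiling(d[3] / 2) - 1L) * d[1] * d[2]
    inmask[start] <- TRUE
    frontier <- integer(0)
    push_nb <- function(lin, frontier) {
      ijk <- arrayInd(lin, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- ijk
        nb[ax] <- nb[ax] + s
        if (nb[ax] < 1L || nb[ax] > d[ax]) next
        nl <- nb[1] + (nb[2] - 1L) * d[1] + (nb[3] - 1L) * d[1] * d[2]
        if (!inmask[nl] && !infrontier[nl]) {
          infrontier[nl] <<- TRUE
          frontier <- c(frontier, nl)
        }
      }
      frontier
    }
    frontier <- push_nb(start, frontier)
    n_in <- 1L
    while (n_in < target_voxels) {
      pick <- sample.int(length(frontier), 1L)
      lin <- frontier[pick]
      frontier <- frontier[-pick]
      inmask[lin] <- TRUE
      infrontier[lin] <- FALSE
      n_in <- n_in + 1L
      frontier <- push_nb(lin, frontier)
    }
    brain_mask(array(inmask, dim = d), grid)
  })
}

#' Partition a mask into contiguous communities and build a default hub spec
#'
#' Grows `n_communities` spatially contiguous regions of roughly equal size
#' from well-separated in-mask seed voxels, assigns every in-mask voxel to its
#' growth region, and designates a small contiguous hub set (inside community
#' 1) that loads on all communities.
#'
#' @param mask a [brain_mask()].
#' @param n_communities number of communities.
#' @param weight common community loading weight.
#' @param n_hub number of hub voxels (0 for none).
#' @inheritParams hub_spec
#' @param seed RNG seed.
#' @return A [hub_spec()] covering every mask voxel.
#' @export
default_hub_spec <- function(mask, n_communities = 3, weight = 1, n_hub = 5,
                             hub_weight = weight, noise_sd = 1, ar1 = 0.3,
                             seed = NULL) {
  N <- mask$n_voxels
  coords <- mask_coords(mask)
  with_seed(seed, {
    # pick seeds greedily far apart
    seeds <- sample.int(N, 1L)
    while (length(seeds) < n_communities) {
      dmin <- rep(Inf, N)
      for (s in seeds) {
        ds <- rowSums((coords - matrix(coords[s, ], N, 3, byrow = TRUE))^2)
        dmin <- pmin(dmin, ds)
      }
      seeds <- c(seeds, which.max(dmin))
    }
    # assign each voxel to nearest seed (contiguity follows from blob shape)
    dist_to <- sapply(seeds, function(s)
      rowSums((coords - matrix(coords[s, ], N, 3, byrow = TRUE))^2))
    assign <- max.col(-dist_to, ties.method = "first")
    comms <- lapply(seq_len(n_communities), function(c)
      list(voxels = which(assign == c), weight = weight))
    hubs <- integer(0)
    if (n_hub > 0) {
      c1 <- comms[[1]]$voxels
      d1 <- rowSums((coords[c1, , drop = FALSE] -
                       matrix(coords[seeds[1], ], length(c1), 3, byrow = TRUE))^2)
      hubs <- c1[order(d1)][seq_len(min(n_hub, length(c1)))]
    }
    hub_spec(comms, hub_voxels = hubs, hub_weight = hub_weight,
             noise_sd = noise_sd, ar1 = ar1, n_voxels = N)
  })
}

# rows of AR(1) noise with stationary initialization; marginal SD = sd
ar1_noise <- function(n, Tn, sd, phi) {
  if (sd == 0) return(matrix(0, n, Tn))
  E <- matrix(0, n, Tn)
  E[, 1] <- stats::rnorm(n, sd = sd)
  if (Tn > 1L) {
    inno_sd <- sd * sqrt(1 - phi^2)
    for (t in 2:Tn) E[, t] <- phi * E[, t - 1] + stats::rnorm(n, sd = inno_sd)
  }
  E
}

#' Simulate one subject's masked 4D time series
#'
#' Each voxel time course is the weighted sum of its community latent signals
#' (iid standard normal over time) plus AR(1) noise with stationary
#' initialization. Identical seeds reproduce the data bit-identically.
#'
#' @param mask a [brain_mask()].
#' @param hubs a [hub_spec()] with `n_voxels == mask$n_voxels`.
#' @param T_volumes number of volumes (>= 20).
#' @param tr_seconds repetition time in seconds.
#' @param seed RNG seed.
#' @param loading_shift optional numeric vector (length `n_voxels`) added to
#'   each voxel's nonzero loadings — the mechanism used to plant group
#'   effects in connectivity strength.
#' @param loading_scale global multiplier on all loadings (subject-level
#'   connectivity scale).
#' @param return_type `"image"` for a [timeseries_image()], `"matrix"` for
#'   the masked [voxel_matrix()] directly.
#' @return A `timeseries_image` or `voxel_matrix`.
#' @export
simulate_subject_timeseries <- function(mask, hubs, T_volumes, tr_seconds = 2,
                                        seed = NULL, loading_shift = NULL,
                                        loading_scale = 1,
                                        return_type = c("image", "matrix")) {
  return_type <- match.arg(return_type)
  if (hubs$n_voxels != mask$n_voxels)
    stopf("hub spec is for %d voxels but mask has %d", hubs$n_voxels, mask$n_voxels)
  if (T_volumes < 20L) stopf("`T_volumes` must be >= 20")
  L <- loading_matrix(hubs, loading_shift, loading_scale)
  vm <- with_seed(seed, {
    Fm <- matrix(stats::rnorm(ncol(L) * T_volumes), ncol(L), T_volumes)
    X <- L %*% Fm + ar1_noise(nrow(L), T_volumes, hubs$noise_sd, hubs$ar1)
    voxel_matrix(X, mask, tr_seconds = tr_seconds)
  })
  if (return_type == "matrix") vm else insert_matrix(vm)
}

#' Simulate head-motion parameters
#'
#' Random-walk translations (mm) and rotations (degrees), six columns per
#' volume, with step standard deviation `amplitude_mm` / `amplitude_deg`.
#' Amplitude 0 gives an all-zero table.
#'
#' @param T_volumes number of volumes (>= 2).
#' @param amplitude_mm step SD of the translation random walks.
#' @param amplitude_deg step SD of the rotation random walks.
#' @param seed RNG seed.
#' @return A `T_volumes` x 6 matrix with columns
#'   `trans_x, trans_y, trans_z, rot_x, rot_y, rot_z`.
#' @export
simulate_motion <- function(T_volumes, amplitude_mm = 0.02,
                            amplitude_deg = amplitude_mm, seed = NULL) {
  if (T_volumes < 2L) stopf("`T_volumes` must be >= 2")
  with_seed(seed, {
    m <- cbind(
      matrix(stats::rnorm(3 * T_volumes, sd = amplitude_mm), T_volumes, 3),
      matrix(stats::rnorm(3 * T_volumes, sd = amplitude_deg), T_volumes, 3))
    m <- apply(m, 2, cumsum)
    m[1, ] <- 0
    m <- apply(m, 2, function(x) x - x[1])
    colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    m
  })
}

#' Simulate tissue segmentation and lesion masks of known volume
#'
#' Builds disjoint WM (innermost), GM and CSF (outermost) shells around the
#' grid center by distance ordering, each containing exactly the number of
#' whole voxels closest to the requested volume; the lesion mask is nested in
#' the WM. The construction is deterministic; `seed` is accepted for
#' interface uniformity only.
#'
#' @param grid an [image_grid()].
#' @param volumes_ml named list/vector with `gm`, `wm`, `csf` volumes in ml.
#' @param lesion_ml lesion volume in ml (placed inside WM).
#' @param seed unused; present so all generators share a signature.
#' @return List with `gm`, `wm`, `csf`, `lesion` ([brain_mask()] each, lesion
#'   `NULL` when `lesion_ml` rounds to zero voxels) and `voxel_volume_mm3`.
#' @export
simulate_segmentation <- function(grid, volumes_ml, lesion_ml = 0, seed = NULL) {
  vv <- voxel_volume_mm3(grid)
  n_gm <- round(volumes_ml[["gm"]] * 1000 / vv)
  n_wm <- round(volumes_ml[["wm"]] * 1000 / vv)
  n_csf <- round(volumes_ml[["csf"]] * 1000 / vv)
  n_les <- round(lesion_ml * 1000 / vv)
  n_total <- n_gm + n_wm + n_csf
  if (n_total > prod(grid$shape))
    stopf("requested volumes need %d voxels but the grid only has %d",
          n_total, prod(grid$shape))
  if (n_les > n_wm) stopf("lesion volume exceeds the white-matter volume")
  d <- grid$shape
  ctr <- (d + 1) / 2
  ijk <- arrayInd(seq_len(prod(d)), d)
  dist2 <- rowSums(sweep(ijk, 2, ctr)^2)
  ord <- order(dist2, seq_len(prod(d)))      # deterministic tie-break
  as_mask <- function(lin) {
    # zero-volume tissues come back as an all-zero probability volume, since
    # a brain_mask must contain at least one voxel
    if (!length(lin)) return(volume_image(array(0, dim = d), grid))
    a <- array(FALSE, dim = d)
    a[lin] <- TRUE
    brain_mask(a, grid)
  }
  wm_lin <- ord[seq_len(n_wm)]
  gm_lin <- ord[n_wm + seq_len(n_gm)]
  csf_lin <- ord[n_wm + n_gm + seq_len(n_csf)]
  list(gm = as_mask(gm_lin), wm = as_mask(wm_lin), csf = as_mask(csf_lin),
       lesion = if (n_les > 0) as_mask(wm_lin[seq_len(n_les)]) else NULL,
       voxel_volume_mm3 = vv)
}

clip_edss <- function(x) pmin(10, pmax(0, round(x * 2) / 2))

#' Simulate a two-phase group study with ground truth
#'
#' Generates control, remitting-only and paired relapsing/remitting subjects.
#' Each subject has a latent connectivity scale shared between their paired
#' sessions; sessions of the `effect$group` group additionally receive an
#' additive loading shift `effect$delta` at `effect$voxels`, the planted
#' connectivity-strength group difference. Clinical covariates follow the
#' typical ranges of a relapsing-remitting MS cohort (EDSS ~2-3.5 in 0.5
#' steps, BPF ~0.83 vs 0.86 in controls, lesion load ~19 ml) and are drawn
#' with a stated linear coupling to the subject connectivity scale.
#'
#' @param mask a [brain_mask()].
#' @param hubs a [hub_spec()].
#' @param design list with `n_control`, `n_remitting` (single-session
#'   subjects) and `n_paired` (subjects scanned in both phases).
#' @param effect list with `voxels` (mask-row indices), `delta` (additive
#'   loading shift) and `group` (which group carries it, default
#'   `"relapsing"`).
#' @param covariate_slopes named list of linear couplings of each clinical
#'   metric to the subject connectivity scale (centered at 1); e.g.
#'   `list(edss = -2)` lowers EDSS by 2 per unit increase in scale.
#' @param T_volumes,tr_seconds acquisition length and repetition time.
#' @param subject_sd SD of the subject-level connectivity scale around 1.
#' @param seed RNG seed; the whole study is reproducible from it.
#' @param return_type passed to [simulate_subject_timeseries()].
#' @return List with `subjects` (one row per session: id, group, pair_id,
#'   session, age, gender, edss, bpf, twmll_ml, duration_months), `data`
#'   (list of images/matrices, one per session row), `motion` (list of T x 6
#'   matrices), `nuisance` (list of `list(wm, csf)` signals) and `truth`
#'   (hub map, expected DC, planted effect, covariate slopes, subject
#'   connectivity scales, seed).
#' @export
simulate_group_study <- function(mask, hubs,
                                 design = list(n_control = 34, n_remitting = 23,
                                               n_paired = 11),
                                 effect = list(voxels = integer(0), delta = 0,
                                               group = "relapsing"),
                                 covariate_slopes = list(),
                                 T_volumes = 240, tr_seconds = 2,
                                 subject_sd = 0.1, seed = NULL,
                                 return_type = c("matrix", "image")) {
  return_type <- match.arg(return_type)
  n_c <- design$n_control %||% 0
  n_r <- design$n_remitting %||% 0
  n_p <- design$n_paired %||% 0
  n_subj <- n_c + n_r + n_p
  if (n_subj < 2L) stopf("the study needs at least 2 subjects")
  effect$group <- effect$group %||% "relapsing"
  delta_vec <- NULL
  if (length(effect$voxels) && effect$delta != 0) {
    delta_vec <- numeric(mask$n_voxels)
    delta_vec[effect$voxels] <- effect$delta
  }
  with_seed(seed, {
    ids <- sprintf("S%03d", seq_len(n_subj))
    grp1 <- c(rep("control", n_c), rep("remitting", n_r), rep("relapsing", n_p))
    age <- round(stats::runif(n_subj, 20, 58))
    gender <- stats::rbinom(n_subj, 1, 0.5)
    scale <- pmax(0.2, stats::rnorm(n_subj, 1, subject_sd))
    is_pat <- grp1 != "control"
    sl <- function(nm) covariate_slopes[[nm]] %||% 0
    edss <- ifelse(is_pat,
                   clip_edss(2.3 + sl("edss") * (scale - 1) +
                               stats::rnorm(n_subj, 0, 0.8)), NA)
    bpf <- ifelse(is_pat,
                  0.830 + sl("bpf") * (scale - 1) + stats::rnorm(n_subj, 0, 0.004),
                  0.861 + stats::rnorm(n_subj, 0, 0.003))
    twmll <- ifelse(is_pat,
                    pmax(0, 19 + sl("twmll") * (scale - 1) +
                           stats::rnorm(n_subj, 0, 6)), NA)
    dur <- ifelse(is_pat,
                  pmin(150, pmax(0.3, exp(stats::rnorm(n_subj, log(20), 0.8)))), NA)

    subjects <- data.frame(id = ids, group = grp1,
                           pair_id = ifelse(grp1 == "relapsing", ids, NA),
                           session = 1L, age = age, gender = gender,
                           edss = edss, bpf = bpf, twmll_ml = twmll,
                           duration_months = dur, stringsAsFactors = FALSE)
    if (n_p > 0) {                       # second (remitting) session of pairs
      prow <- subjects[subjects$group == "relapsing", ]
      prow$group <- "remitting"
      prow$session <- 2L
      prow$edss <- clip_edss(prow$edss - 1)   # partial recovery on remission
      subjects <- rbind(subjects, prow)
    }
    rownames(subjects) <- NULL
    subj_of_row <- match(subjects$id, ids)

    data <- vector("list", nrow(subjects))
    motion <- vector("list", nrow(subjects))
    nuisance <- vector("list", nrow(subjects))
    for (r in seq_len(nrow(subjects))) {
      s <- subj_of_row[r]
      shift <- if (!is.null(delta_vec) && subjects$group[r] == effect$group)
        delta_vec else NULL
      data[[r]] <- simulate_subject_timeseries(
        mask, hubs, T_volumes, tr_seconds, seed = NULL,
        loading_shift = shift, loading_scale = scale[s],
        return_type = return_type)
      motion[[r]] <- simulate_motion(T_volumes, amplitude_mm = 0.02, seed = NULL)
      nuisance[[r]] <- list(wm = as.numeric(ar1_noise(1, T_volumes, 1, 0.5)),
                            csf = as.numeric(ar1_noise(1, T_volumes, 1, 0.5)))
    }
    truth <- list(
      expected_dc = expected_dc(hubs),
      hub_map = rank(-expected_dc(hubs), ties.method = "min"),
      group_effect = delta_vec %||% numeric(mask$n_voxels),
      effect_voxels = as.integer(effect$voxels),
      effect_group = effect$group,
      covariate_slopes = covariate_slopes,
      subject_scale = stats::setNames(scale, ids),
      seed = seed)
    list(subjects = subjects, data = data, motion = motion,
         nuisance = nuisance, truth = truth)
  })
}
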