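# Operating-characteristic experiments: seeded simulation studies that
# measure the family-wise error, power and regression-slope recovery of the
# full centrality + cluster-correction chain on synthetic data with known
# ground truth. These are the package's calibration evidence; problem sizes
# are chosen so each experiment runs in minutes on one CPU.

# DC -> global-mean -> z-standardized map for one session
session_dc_map <- function(vm, r0 = 0.25) {
  z <- standardize_rows(vm)
  convert_for_group(normalize_global_mean(degree_centrality(z, r0 = r0)))
}

#' Family-wise error calibration on null studies
#'
#' Simulates `n_studies` two-group studies under the global null (one
#' all-mask community of weight 0, i.e. pure AR(1) noise, and no group
#' effect), runs the full chain — degree centrality, global-mean and
#' z-standardization, two-sample GLM t-map with age/gender covariates,
#' two-tailed cluster formation at `voxel_p`, Monte-Carlo cluster-size
#' correction — and reports the fraction of studies with at least one
#' surviving cluster. Because the null maps are spatially independent, the
#' Monte-Carlo null is simulated with FWHM = 0 (matched smoothness); each
#' tail is corrected at `alpha`, so the expected study-wise rate is close to
#' twice `alpha` minus the integer-size discreteness of the critical size.
#'
#' @param n_studies number of simulated studies (default 200).
#' @param n_per_group subjects per group (default 8).
#' @param mask a [brain_mask()]; default a 1,000-voxel toy mask.
#' @param T_volumes volumes per subject (default 60).
#' @param r0 DC threshold.
#' @param voxel_p,rmm,alpha cluster-formation and correction parameters.
#' @param iterations Monte-Carlo iterations for the null simulation.
#' @param seed master seed; study s uses seed + s.
#' @return List with `fwe_rate`, `n_positive`, `n_studies`, `critical_k`.
#' @export
fwe_calibration <- function(n_studies = 200, n_per_group = 8, mask = NULL,
                            T_volumes = 60, r0 = 0.25, voxel_p = 0.01,
                            rmm = 5, iterations = 200, alpha = 0.05,
                            seed = 1) {
  mask <- mask %||% make_toy_mask(c(14, 14, 14), 1000, seed = seed)
  hubs <- hub_spec(list(list(voxels = seq_len(mask$n_voxels), weight = 0)),
                   noise_sd = 1, ar1 = 0.3, n_voxels = mask$n_voxels)
  asr <- alphasim_threshold(mask, fwhm_mm = 0, voxel_p = voxel_p, rmm = rmm,
                            iterations = iterations, alpha = alpha,
                            seed = seed + 500000)
  n <- 2L * n_per_group
  positive <- logical(n_studies)
  for (s in seq_len(n_studies)) {
    st <- simulate_group_study(
      mask, hubs,
      design = list(n_control = n_per_group, n_remitting = n_per_group,
                    n_paired = 0),
      T_volumes = T_volumes, subject_sd = 0, seed = seed + s,
      return_type = "matrix")
    Y <- stack_maps(lapply(st$data, session_dc_map, r0 = r0))
    des <- build_design(st$subjects)
    tmap <- glm_tmap(Y, des, mask = mask)
    cl <- label_clusters(tmap, voxel_p = voxel_p, tail = "both", rmm = rmm)
    cl <- apply_cluster_correction(cl, asr, alpha = alpha)
    positive[s] <- any(cl$table$surviving)
  }
  list(fwe_rate = mean(positive), n_positive = sum(positive),
       n_studies = n_studies, critical_k = critical_k(asr, alpha))
}

#' Power to recover a planted connectivity effect (paired design)
#'
#' Simulates paired two-session studies in which the relapsing-phase session
#' carries an additive loading shift (`effect_delta`) at a contiguous set of
#' `n_effect` voxels, runs the paired-t cluster-corrected analysis, and
#' reports the fraction of seeds in which at least one surviving cluster
#' overlaps the planted voxels. Also returns the realized standardized
#' within-pair effect size (mean over planted voxels of |mean diff| / SD
#' diff, averaged over seeds) so the planted condition is measurable.
#'
#' @param n_seeds number of simulated studies (default 100).
#' @param n_pairs paired subjects (default 11, a typical two-phase cohort).
#' @param mask a [brain_mask()]; default a 1,000-voxel toy mask.
#' @param n_effect planted cluster extent in voxels (default 30).
#' @param effect_delta additive loading shift at the planted voxels.
#' @param T_volumes volumes per session.
#' @inheritParams fwe_calibration
#' @return List with `recovery_rate`, `n_recovered`, `n_seeds`,
#'   `mean_effect_d`, `critical_k`, `effect_voxels`.
#' @export
power_recovery <- function(n_seeds = 100, n_pairs = 11, mask = NULL,
                           n_effect = 30, effect_delta = 0.8,
                           T_volumes = 120, r0 = 0.25, voxel_p = 0.01,
                           rmm = 5, iterations = 200, alpha = 0.05,
                           seed = 1) {
  mask <- mask %||% make_toy_mask(c(14, 14, 14), 1000, seed = seed)
  hubs <- default_hub_spec(mask, n_communities = 3, weight = 1, n_hub = 0,
                           noise_sd = 1, ar1 = 0.3, seed = seed)
  # a contiguous planted cluster: the n_effect voxels of community 1 closest
  # to its own first voxel
  c1 <- hubs$communities[[1]]$voxels
  coords <- mask_coords(mask)
  d1 <- rowSums((coords[c1, , drop = FALSE] -
                   matrix(coords[c1[1], ], length(c1), 3, byrow = TRUE))^2)
  effect_voxels <- c1[order(d1)][seq_len(min(n_effect, length(c1)))]
  asr <- alphasim_threshold(mask, fwhm_mm = 0, voxel_p = voxel_p, rmm = rmm,
                            iterations = iterations, alpha = alpha,
                            seed = seed + 500000)
  recovered <- logical(n_seeds)
  dsum <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    st <- simulate_group_study(
      mask, hubs,
      design = list(n_control = 0, n_remitting = 0, n_paired = n_pairs),
      effect = list(voxels = effect_voxels, delta = effect_delta,
                    group = "relapsing"),
      T_volumes = T_volumes, subject_sd = 0.1, seed = seed + s,
      return_type = "matrix")
    rel <- which(st$subjects$session == 1L & st$subjects$group == "relapsing")
    s2 <- which(st$subjects$session == 2L)
    rem <- s2[match(st$subjects$id[rel], st$subjects$id[s2])]
    Ya <- stack_maps(lapply(st$data[rel], session_dc_map, r0 = r0))
    Yb <- stack_maps(lapply(st$data[rem], session_dc_map, r0 = r0))
    tmap <- paired_tmap(Ya, Yb, mask = mask)
    D <- Ya - Yb
    dvox <- abs(colMeans(D)) / apply(D, 2, stats::sd)
    dsum[s] <- mean(dvox[effect_voxels])
    cl <- label_clusters(tmap, voxel_p = voxel_p, tail = "both", rmm = rmm)
    cl <- apply_cluster_correction(cl, asr, alpha = alpha)
    surv <- which(cl$table$surviving)
    recovered[s] <- any(vapply(surv, function(i)
      length(intersect(cl$members[[i]], effect_voxels)) > 0, logical(1)))
  }
  list(recovery_rate = mean(recovered), n_recovered = sum(recovered),
       n_seeds = n_seeds, mean_effect_d = mean(dsum),
       critical_k = critical_k(asr, alpha), effect_voxels = effect_voxels)
}

#' Slope recovery and null calibration of the clinical regression
#'
#' Generates cluster-mean centrality linearly coupled to a clinical metric
#' (centrality = intercept + slope x metric + age and gender terms + noise,
#' the same model [clinical_regression()] fits), fits the regression over
#' `n_seeds` replicates, and reports the mean estimated slope, its relative
#' bias, and the null false-positive rate when `null_seeds > 0` replicates
#' are run with slope 0.
#'
#' @param n_seeds replicates for the recovery arm (default 200).
#' @param n subjects per replicate (default 34).
#' @param slope true slope of centrality on the metric.
#' @param snr ratio of slope-induced SD to residual SD (default 1).
#' @param null_seeds replicates for the null arm (default 500).
#' @param seed master seed.
#' @return List with `mean_slope`, `bias_pct`, `mc_se`, `null_fp_rate`.
#' @export
slope_recovery <- function(n_seeds = 200, n = 34, slope = 0.5, snr = 1,
                           null_seeds = 500, seed = 1) {
  one <- function(s, b) {
    with_seed(s, {
      metric <- clip_edss(stats::rnorm(n, 2.3, 1))     # EDSS-like predictor
      age <- round(stats::runif(n, 20, 58))
      gender <- stats::rbinom(n, 1, 0.5)
      noise_sd <- if (b != 0) abs(b) * stats::sd(metric) / snr else 0.5
      y <- 1 + b * metric + 0.005 * (age - mean(age)) + 0.05 * gender +
        stats::rnorm(n, 0, noise_sd)
      fit <- clinical_regression(y, data.frame(edss = metric),
                                 covariates = data.frame(age = age,
                                                         gender = gender),
                                 family_size = 1)
      c(slope = fit$slope, p = fit$p_uncorrected)
    })
  }
  est <- vapply(seq_len(n_seeds), function(s) one(seed + s, slope), numeric(2))
  null_fp <- NA_real_
  if (null_seeds > 0) {
    pnull <- vapply(seq_len(null_seeds), function(s)
      one(seed + 100000 + s, 0)["p"], numeric(1))
    null_fp <- mean(pnull < 0.05)
  }
  mean_slope <- mean(est["slope", ])
  list(mean_slope = mean_slope,
       bias_pct = 100 * (mean_slope - slope) / slope,
       mc_se = stats::sd(est["slope", ]) / sqrt(n_seeds),
       null_fp_rate = null_fp)
}
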