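# Generator properties: determinism, planted correlation structure,
# segmentation volumes, motion traces, paired structure.

test_that("make_toy_mask grows a connected blob of the requested size", {
  m <- make_toy_mask(c(30, 30, 30), 1000, seed = 3)
  expect_identical(m$n_voxels, 1000L)
  offs <- neighbors_from_rmm(m$grid, 3)          # 6-connectivity
  comp <- component_oracle(mask_coords(m), offs)
  expect_equal(max(comp), 1)

  full <- make_toy_mask(c(4, 4, 4), 64, seed = 1)
  expect_true(all(full$indicator))

  expect_identical(make_toy_mask(c(8, 8, 8), 100, seed = 9)$indices,
                   make_toy_mask(c(8, 8, 8), 100, seed = 9)$indices)
  expect_error(make_toy_mask(c(3, 3, 3), 28, seed = 1), "target_voxels")
})

test_that("simulated time series realize the planted correlation structure", {
  mask <- flat_mask(6, c(3, 3, 3))
  # two disjoint communities, zero noise: shared latent => within r = 1
  h <- hub_spec(list(list(voxels = 1:3, weight = 1),
                     list(voxels = 4:6, weight = 1)),
                noise_sd = 0, ar1 = 0, n_voxels = 6)
  vm <- simulate_subject_timeseries(mask, h, 40, seed = 1,
                                    return_type = "matrix")
  C <- cor(t(vm$data))
  expect_equal(C[1, 2], 1)
  expect_equal(C[4, 6], 1)
  expect_lt(abs(C[1, 4]), 0.5)  # independent latents, finite-T fluctuation

  # noise-dominated: DC at r0 = 0.25 stays near 0
  hn <- hub_spec(list(list(voxels = 1:6, weight = 0.01)),
                 noise_sd = 10, ar1 = 0, n_voxels = 6)
  vn <- simulate_subject_timeseries(mask, hn, 200, seed = 2,
                                    return_type = "matrix")
  dc <- dc_oracle(vn$data, 0.25)
  expect_lt(mean(dc), 0.5)      # ~N * E[r; r > .25] for r ~ N(0, 1/sqrt(T))

  expect_error(simulate_subject_timeseries(mask, h, 10, seed = 1), "T_volumes")
  expect_error(hub_spec(list(), n_voxels = 6), "one community")
})

test_that("a hub loading on all communities ranks top in brute-force DC", {
  mask <- flat_mask(31, c(4, 4, 4))
  comms <- list(list(voxels = 1:10, weight = 1),
                list(voxels = 11:20, weight = 1),
                list(voxels = 21:30, weight = 1))
  h <- hub_spec(comms, hub_voxels = 31L, hub_weight = 1,
                noise_sd = 0.5, ar1 = 0, n_voxels = 31)
  hits <- vapply(1:20, function(s) {
    vm <- simulate_subject_timeseries(mask, h, 120, seed = 100 + s,
                                      return_type = "matrix")
    which.max(dc_oracle(vm$data, 0.25)) == 31L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # population ranking places the hub first
  expect_identical(which.max(expected_dc(h)), 31L)
})

test_that("zero-noise data recover the planted hub as top-ranked in every seed", {
  mask <- flat_mask(25, c(3, 3, 3))
  comms <- list(list(voxels = 1:8, weight = 1),
                list(voxels = 9:16, weight = 1),
                list(voxels = 17:24, weight = 1))
  h <- hub_spec(comms, hub_voxels = 25L, hub_weight = 1,
                noise_sd = 0, ar1 = 0, n_voxels = 25)
  expect_identical(which(h$hub_voxels == 25L), 1L)
  expect_identical(unname(which(rank(-expected_dc(h),
                                     ties.method = "min") == 1L)), 25L)
  for (s in 1:10) {
    vm <- simulate_subject_timeseries(mask, h, 60, seed = 200 + s,
                                      return_type = "matrix")
    dc <- dc_oracle(vm$data, 0.25)
    expect_identical(which.max(dc), 25L)
    # within-community correlations are exactly 1, so members tie exactly
    expect_equal(dc[1], dc[2], tolerance = 1e-12)
  }
})

test_that("motion traces are seeded random walks with controllable amplitude", {
  expect_true(all(simulate_motion(50, amplitude_mm = 0, seed = 1) == 0))
  m1 <- simulate_motion(50, amplitude_mm = 0.05, seed = 7)
  expect_identical(m1, simulate_motion(50, amplitude_mm = 0.05, seed = 7))
  expect_identical(dim(m1), c(50L, 6L))
  expect_true(all(m1[1, ] == 0))
  big <- simulate_motion(200, amplitude_mm = 1.5, seed = 3)
  expect_true(motion_summary(big)$excluded)
})

test_that("segmentation masks hit requested volumes exactly and nest lesions", {
  g <- image_grid(c(12, 12, 12), 1)
  seg <- simulate_segmentation(g, list(gm = 0.5, wm = 0.4, csf = 0.1),
                               lesion_ml = 0.02)
  expect_identical(seg$gm$n_voxels, 500L)
  expect_identical(seg$wm$n_voxels, 400L)
  expect_identical(seg$csf$n_voxels, 100L)
  expect_identical(seg$lesion$n_voxels, 20L)
  # disjoint tissues, lesion inside WM
  expect_length(intersect(seg$gm$indices, seg$wm$indices), 0)
  expect_length(intersect(seg$gm$indices, seg$csf$indices), 0)
  expect_true(all(seg$lesion$indices %in% seg$wm$indices))

  g3 <- image_grid(c(10, 10, 10), 3)
  seg3 <- simulate_segmentation(g3, list(gm = 5, wm = 54 * 0.027, csf = 1),
                                lesion_ml = 54 * 0.027)
  expect_equal(compute_twmll(seg3$lesion), 1.458)
  expect_error(simulate_segmentation(g, list(gm = 2, wm = 1, csf = 1)),
               "voxels")
})

test_that("group studies are seed-reproducible with shared pair structure", {
  mask <- make_toy_mask(c(8, 8, 8), 120, seed = 5)
  hubs <- default_hub_spec(mask, n_communities = 2, n_hub = 3, seed = 5)
  des <- list(n_control = 3, n_remitting = 2, n_paired = 3)
  a <- simulate_group_study(mask, hubs, design = des, T_volumes = 40,
                            seed = 77)
  b <- simulate_group_study(mask, hubs, design = des, T_volumes = 40,
                            seed = 77)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$data[[1]]$data, b$data[[1]]$data)
  expect_identical(a$truth$subject_scale, b$truth$subject_scale)

  # paired rows: same id, age, gender; different session; EDSS in [0,10]
  s2 <- a$subjects[a$subjects$session == 2L, ]
  s1 <- a$subjects[match(s2$id, a$subjects$id), ]
  expect_identical(s1$age, s2$age)
  expect_identical(s1$gender, s2$gender)
  expect_true(all(s1$group == "relapsing" & s2$group == "remitting"))
  ed <- a$subjects$edss
  expect_true(all(is.na(ed) | (ed >= 0 & ed <= 10 & (ed * 2) %% 1 == 0)))
  # controls carry no lesion/EDSS values
  expect_true(all(is.na(a$subjects$edss[a$subjects$group == "control"])))
})

test_that("paired sessions are more alike than unrelated subjects", {
  mask <- flat_mask(40, c(4, 4, 4))
  hubs <- default_hub_spec(mask, n_communities = 2, n_hub = 0,
                           noise_sd = 1, seed = 1)
  within <- c()
  between <- c()
  for (s in 1:50) {
    st <- simulate_group_study(
      mask, hubs, design = list(n_control = 0, n_remitting = 0, n_paired = 2),
      T_volumes = 40, subject_sd = 0.4, seed = 1000 + s,
      return_type = "matrix")
    dcs <- vapply(st$data, function(v) mean(dc_oracle(v$data, 0.25)),
                  numeric(1))
    # rows: P1s1, P2s1, P1s2, P2s2
    within <- c(within, abs(dcs[1] - dcs[3]), abs(dcs[2] - dcs[4]))
    between <- c(between, abs(dcs[1] - dcs[4]), abs(dcs[2] - dcs[3]))
  }
  expect_lt(mean(within), mean(between))
})
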