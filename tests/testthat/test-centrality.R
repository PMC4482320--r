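# Core centrality computations against dense-matrix oracles, plus the
# normalization/conversion steps.

test_that("standardize_rows enables correlation by dot product", {
  mask <- flat_mask(1, c(2, 2, 2))
  vm <- voxel_matrix(matrix(c(1, 2, 3, 4), 1), mask)
  z <- standardize_rows(vm)
  expect_equal(mean(z$data), 0)
  expect_equal(sum(z$data^2), 3)         # T - 1

  vm2 <- voxel_matrix(rbind(c(1, 2, 3, 4), c(10, 20, 30, 40)),
                      flat_mask(2, c(2, 2, 2)))
  z2 <- standardize_rows(vm2)
  expect_equal(sum(z2$data[1, ] * z2$data[2, ]) / 3, 1)

  vm3 <- random_vm(20, 50, seed = 31)
  z3 <- standardize_rows(vm3)
  R <- tcrossprod(z3$data) / 49
  expect_lt(max(abs(R - cor(t(vm3$data)))), 1e-10)

  # zero-variance row: flagged, zeroed
  vm4 <- voxel_matrix(rbind(rnorm(10), rep(2, 10)), flat_mask(2, c(2, 2, 2)))
  z4 <- standardize_rows(vm4)
  expect_identical(attr(z4, "qc_zero_variance"), 2L)
  expect_true(all(z4$data[2, ] == 0))
})

test_that("degree centrality follows the thresholded positive-sum definition", {
  # r12 = 1, r13 = r23 = -1: negatives are excluded, DC = (1, 1, 0)
  f <- rnorm(30)
  vm <- voxel_matrix(rbind(f, 2 * f, -f), flat_mask(3, c(2, 2, 2)))
  z <- standardize_rows(vm)
  dc <- degree_centrality(z, r0 = 0.25)
  expect_equal(dc$values, c(1, 1, 0), tolerance = 1e-12)

  # all identical time series: DC = N - 1 (self excluded)
  vm2 <- voxel_matrix(matrix(rep(f, 5), 5, byrow = TRUE),
                      flat_mask(5, c(2, 2, 2)))
  dc2 <- degree_centrality(standardize_rows(vm2), 0.25)
  expect_equal(dc2$values, rep(4, 5), tolerance = 1e-12)

  expect_error(degree_centrality(z, r0 = 1.2), "\\(0, 1\\)")
  expect_error(degree_centrality(vm, 0.25), "standardize")
})

test_that("blockwise DC equals the dense-matrix oracle at any block size", {
  for (s in 1:5) {
    vm <- random_vm(50, 60, seed = 40 + s)
    z <- standardize_rows(vm)
    oracle <- dc_oracle(vm$data, 0.25)
    for (bs in c(7, 50, 1024)) {
      dc <- degree_centrality(z, 0.25, block_size = bs)
      expect_lt(max(abs(dc$values - oracle)), 1e-10)
    }
    bor <- dc_oracle(vm$data, 0.25, mode = "binary")
    expect_equal(degree_centrality(z, 0.25, mode = "binary")$values, bor)
  }
})

test_that("multi-threshold DC is consistent and monotone in r0", {
  vm <- random_vm(40, 60, seed = 51)
  z <- standardize_rows(vm)
  maps <- multi_threshold_dc(z, r0_values = c(0.1, 0.25, 0.4))
  single <- degree_centrality(z, 0.25)
  expect_identical(maps[["r0_0.25"]]$values, single$values)
  expect_true(all(maps[["r0_0.4"]]$values <= maps[["r0_0.1"]]$values + 1e-12))
  expect_error(multi_threshold_dc(z, r0_values = numeric(0)), "threshold")
  expect_error(multi_threshold_dc(z, r0_values = c(0.3, 0.2)), "increasing")
})

test_that("matrix-free EC matches hand and dense eigen-solver oracles", {
  # C = [[1,1,-1],[1,1,-1],[-1,-1,1]]: A = (C+1)/2 has blocks {1,2} and {3};
  # principal eigenvector (1,1,0)/sqrt(2), lambda1 = 2
  f <- rnorm(40)
  vm <- voxel_matrix(rbind(f, f, -f), flat_mask(3, c(2, 2, 2)))
  ec <- fast_eigenvector_centrality(standardize_rows(vm))
  expect_equal(ec$values, c(1, 1, 0) / sqrt(2), tolerance = 1e-10)
  expect_equal(attr(ec, "lambda1"), 2, tolerance = 1e-9)

  # identical voxels: uniform eigenvector 1/sqrt(N)
  vm2 <- voxel_matrix(matrix(rep(f, 6), 6, byrow = TRUE),
                      flat_mask(6, c(2, 2, 2)))
  ec2 <- fast_eigenvector_centrality(standardize_rows(vm2))
  expect_equal(ec2$values, rep(1 / sqrt(6), 6), tolerance = 1e-10)

  for (s in 1:5) {
    vm3 <- random_vm(40, 60, seed = 60 + s)
    ec3 <- fast_eigenvector_centrality(standardize_rows(vm3))
    or <- ec_oracle(vm3$data)
    expect_gt(sum(ec3$values * or$vector), 1 - 1e-8)
    expect_equal(attr(ec3, "lambda1"), or$lambda, tolerance = 1e-6)
    expect_true(all(ec3$values >= 0))
    expect_equal(sum(ec3$values^2), 1, tolerance = 1e-12)
  }
})

test_that("DC and EC are permutation-equivariant", {
  vm <- random_vm(30, 50, seed = 71)
  perm <- sample(30)
  vmp <- voxel_matrix(vm$data[perm, ], vm$mask)
  z <- standardize_rows(vm)
  zp <- standardize_rows(vmp)
  expect_equal(degree_centrality(zp, 0.25)$values,
               degree_centrality(z, 0.25)$values[perm], tolerance = 1e-12)
  expect_equal(fast_eigenvector_centrality(zp)$values,
               fast_eigenvector_centrality(z)$values[perm], tolerance = 1e-8)
})

test_that("hub recovery: top DC and EC voxel is the planted hub", {
  mask <- flat_mask(31, c(4, 4, 4))
  comms <- lapply(0:2, function(k) list(voxels = k * 10 + 1:10, weight = 1))
  h <- hub_spec(comms, hub_voxels = 31L, hub_weight = 1,
                noise_sd = 0, ar1 = 0, n_voxels = 31)
  for (s in 1:10) {
    vm <- simulate_subject_timeseries(mask, h, 80, seed = 300 + s,
                                      return_type = "matrix")
    z <- standardize_rows(vm)
    expect_identical(which.max(degree_centrality(z, 0.25)$values), 31L)
    expect_identical(which.max(fast_eigenvector_centrality(z)$values), 31L)
  }
})

test_that("map normalizations behave as specified", {
  mask <- flat_mask(3, c(2, 2, 2))
  cm <- voxcent:::new_centrality_map(c(1, 2, 3), mask, "DC", r0 = 0.25)
  gm <- normalize_global_mean(cm)
  expect_equal(gm$values, c(0.5, 1, 1.5))
  expect_identical(gm$normalization, "global_mean")

  set.seed(81)
  cmr <- voxcent:::new_centrality_map(rexp(100), flat_mask(100, c(5, 5, 5)),
                                      "DC", r0 = 0.25)
  expect_equal(mean(normalize_global_mean(cmr)$values), 1, tolerance = 1e-12)
  cz <- voxcent:::new_centrality_map(c(-1, 0, 1), mask, "DC")
  expect_error(normalize_global_mean(cz), "mean is zero")

  zs <- convert_for_group(cmr, "z_standardize")
  expect_equal(mean(zs$values), 0, tolerance = 1e-12)
  expect_equal(sd(zs$values), 1, tolerance = 1e-12)

  cf <- voxcent:::new_centrality_map(c(0, 0.5, -0.3), mask, "EC")
  fz <- convert_for_group(cf, "fisher_z")
  expect_equal(fz$values, c(0, log(3) / 2, atanh(-0.3)))
  expect_error(convert_for_group(gm, "fisher_z"), "z_standardize")
})

test_that("rank-Gaussian normalization hits the Blom quantiles", {
  mask3 <- flat_mask(3, c(2, 2, 2))
  rg <- rank_gauss(voxcent:::new_centrality_map(c(5, 1, 9), mask3, "DC"))
  expect_equal(rg$values, qnorm((c(2, 1, 3) - 3 / 8) / 3.25))
  expect_equal(rg$values, c(0, -0.869, 0.869), tolerance = 1e-3)

  ties <- rank_gauss(voxcent:::new_centrality_map(rep(7, 5),
                                                  flat_mask(5, c(2, 2, 2)),
                                                  "DC"))
  expect_equal(ties$values, rep(0, 5))

  set.seed(82)
  x <- sort(rnorm(50))
  mono <- rank_gauss(voxcent:::new_centrality_map(x, flat_mask(50, c(4, 4, 4)),
                                                  "DC"))
  expect_true(all(diff(mono$values) > 0))
})
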