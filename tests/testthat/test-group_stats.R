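# GLM t/F maps against closed-form and base-R oracles; cluster labeling
# against an igraph flood-fill oracle; Monte-Carlo cluster correction.

test_that("glm_tmap reduces to the pooled two-sample t without covariates", {
  set.seed(91)
  Y <- matrix(rnorm(8 * 20), 8, 20)
  grp <- rep(c("a", "b"), each = 4)
  X <- cbind(1, grp == "b")
  tm <- glm_tmap(Y, X, contrast = c(0, 1))
  expect_identical(tm$dof, 6L)
  for (v in 1:20) {
    or <- t.test(Y[grp == "b", v], Y[grp == "a", v], var.equal = TRUE)
    expect_equal(tm$values[v], unname(or$statistic), tolerance = 1e-10)
  }
  # identical group means at every voxel -> t = 0
  Y0 <- rbind(Y[1:4, ], Y[1:4, ])
  tm0 <- glm_tmap(Y0, X, contrast = c(0, 1))
  expect_equal(max(abs(tm0$values)), 0, tolerance = 1e-10)
})

test_that("t-squared for a two-level factor equals the ANCOVA partial F", {
  set.seed(92)
  n <- 14
  dat <- data.frame(group = rep(c("hc", "pat"), each = 7),
                    age = round(runif(n, 20, 58)),
                    gender = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 15), n, 15)
  des <- build_design(dat)
  tm <- glm_tmap(Y, des)
  fm <- ancova_fmap(Y, dat)
  expect_equal(fm$values, tm$values^2, tolerance = 1e-8)
  expect_identical(fm$dof, c(1L, tm$dof))
})

test_that("paired t-map matches the hand case and a fixed-effects GLM", {
  mask1 <- flat_mask(1, c(2, 2, 2))
  Ya <- matrix(c(1, 2, 3), 3, 1)
  Yb <- matrix(0, 3, 1)
  pt <- paired_tmap(Ya, Yb)
  expect_equal(pt$values, 2 / (1 / sqrt(3)), tolerance = 1e-12)  # 3.464
  expect_identical(pt$dof, 2L)

  zero <- paired_tmap(Ya, Ya)
  expect_true(all(!is.finite(zero$values)))
  expect_identical(attr(zero, "n_flagged"), 1L)

  # equivalence with a GLM containing subject fixed effects and a session term
  set.seed(93)
  n <- 6
  Ya2 <- matrix(rnorm(n * 10), n, 10)
  Yb2 <- matrix(rnorm(n * 10), n, 10)
  pt2 <- paired_tmap(Ya2, Yb2)
  Y <- rbind(Ya2, Yb2)
  X <- cbind(session_a = rep(c(1, 0), each = n),
             subject = diag(n)[rep(1:n, 2), ])
  tm <- glm_tmap(Y, X, contrast = c(1, rep(0, n)))
  expect_equal(tm$values, pt2$values, tolerance = 1e-8)
  expect_identical(tm$dof, pt2$dof)
})

test_that("ANCOVA F-map matches aov and collapses correctly", {
  set.seed(94)
  n <- 18
  dat <- data.frame(group = rep(c("hc", "rem", "rel"), each = 6),
                    age = round(runif(n, 20, 58)),
                    gender = rbinom(n, 1, 0.5))
  Y <- matrix(rnorm(n * 10), n, 10)
  # no covariates: one-way ANOVA oracle
  fm <- ancova_fmap(Y, dat, covariates = character(0))
  for (v in 1:10) {
    or <- summary(aov(Y[, v] ~ factor(dat$group)))[[1]]$`F value`[1]
    expect_equal(fm$values[v], or, tolerance = 1e-10)
  }
  # with covariates: partial F oracle via anova() model comparison
  fmc <- ancova_fmap(Y, dat)
  for (v in c(1, 5, 10)) {
    full <- lm(Y[, v] ~ group + age + gender, dat)
    red <- lm(Y[, v] ~ age + gender, dat)
    expect_equal(fmc$values[v], anova(red, full)$F[2], tolerance = 1e-8)
  }
  # identical groups -> F ~ 0
  Yc <- Y[rep(1:6, 3), ]
  datc <- dat
  datc$age <- rep(dat$age[1:6], 3)
  datc$gender <- rep(dat$gender[1:6], 3)
  f0 <- ancova_fmap(Yc, datc)
  expect_equal(max(abs(f0$values)), 0, tolerance = 1e-8)
})

test_that("rmm neighborhoods enumerate the expected offset counts", {
  g3 <- image_grid(c(5, 5, 5), 3)
  expect_identical(nrow(neighbors_from_rmm(g3, 5)), 18L)
  expect_identical(nrow(neighbors_from_rmm(g3, 3)), 6L)
  expect_identical(nrow(neighbors_from_rmm(image_grid(c(5, 5, 5), 1), 1.8)),
                   26L)
  expect_error(neighbors_from_rmm(g3, 2), "smaller")
})

test_that("cluster labeling distinguishes corner contact by neighborhood", {
  shape <- c(8, 8, 8)
  mask <- brain_mask(array(TRUE, dim = shape), image_grid(shape, 3))
  vals <- numeric(prod(shape))
  arr <- array(FALSE, shape)
  arr[2:3, 2:3, 2:3] <- TRUE           # blob A
  arr[4:5, 4:5, 4:5] <- TRUE           # blob B touches A only at a corner
  vals[which(arr)] <- 10
  sm <- voxcent:::new_stat_map(vals, 100L, "t", mask)
  cl18 <- label_clusters(sm, voxel_p = 0.01, rmm = 5)       # 18-connectivity
  expect_identical(nrow(cl18$table), 2L)
  cl26 <- label_clusters(sm, voxel_p = 0.01, rmm = 5.2)     # adds corners
  expect_identical(nrow(cl26$table), 1L)
  expect_identical(cl26$table$size, 16L)

  none <- voxcent:::new_stat_map(numeric(prod(shape)), 100L, "t", mask)
  expect_identical(nrow(label_clusters(none)$table), 0L)
})

test_that("cluster labeling agrees with an igraph flood-fill oracle", {
  skip_if_not_installed("igraph")
  set.seed(95)
  shape <- c(10, 10, 10)
  mask <- brain_mask(array(TRUE, dim = shape), image_grid(shape, 3))
  for (rep_i in 1:8) {
    vals <- ifelse(runif(prod(shape)) < 0.15, 10, 0)
    sm <- voxcent:::new_stat_map(vals, 100L, "t", mask)
    for (rmm in c(3, 5, 5.2)) {                 # 6-, 18-, 26-connectivity
      cl <- label_clusters(sm, voxel_p = 0.01, rmm = rmm)
      offs <- neighbors_from_rmm(mask$grid, rmm)
      coords <- mask_coords(mask)[vals > 0, , drop = FALSE]
      oracle <- component_oracle(coords, offs)
      expect_identical(nrow(cl$table), as.integer(max(c(oracle, 0))))
      expect_identical(sort(cl$table$size),
                       sort(unname(as.integer(table(oracle)))))
    }
  }
})

test_that("negative and positive tails are labeled separately", {
  shape <- c(6, 6, 6)
  mask <- brain_mask(array(TRUE, dim = shape), image_grid(shape, 3))
  arr <- array(0, shape)
  arr[2:3, 2, 2] <- 10
  arr[5, 5, 4:5] <- -10
  sm <- voxcent:::new_stat_map(as.vector(arr), 30L, "t", mask)
  cl <- label_clusters(sm, voxel_p = 0.01, rmm = 5)
  expect_setequal(cl$table$tail, c("pos", "neg"))
  pos_only <- label_clusters(sm, voxel_p = 0.01, rmm = 5, tail = "pos")
  expect_true(all(pos_only$table$tail == "pos"))
})

test_that("AlphaSim thresholds behave in analytically known regimes", {
  mask <- make_toy_mask(c(14, 14, 14), 1000, seed = 4)
  asr <- alphasim_threshold(mask, fwhm_mm = 0, voxel_p = 0.01, rmm = 5,
                            iterations = 500, alpha = c(0.05, 1), seed = 5)
  # alpha = 1 is always satisfied at k = 1
  expect_identical(critical_k(asr, 1), 1L)
  # independent-voxel regime: ~10 supra voxels, max cluster size small
  expect_true(critical_k(asr, 0.05) %in% 1:3)
  # alpha_to_k nonincreasing in alpha
  tab <- asr$alpha_to_k[order(asr$alpha_to_k$alpha), ]
  expect_true(all(diff(tab$k) <= 0))
  # determinism
  asr2 <- alphasim_threshold(mask, fwhm_mm = 0, voxel_p = 0.01, rmm = 5,
                             iterations = 500, alpha = c(0.05, 1), seed = 5)
  expect_identical(asr$null_max_sizes, asr2$null_max_sizes)

  # smoothing inflates null cluster sizes
  for (s in 1:3) {
    a0 <- alphasim_threshold(mask, 0, iterations = 150, seed = 10 + s)
    a6 <- alphasim_threshold(mask, 6, iterations = 150, seed = 10 + s)
    expect_gte(critical_k(a6, 0.05), critical_k(a0, 0.05))
  }
})

test_that("cluster correction applies the critical size exactly at boundary", {
  shape <- c(10, 10, 10)
  mask <- brain_mask(array(TRUE, dim = shape), image_grid(shape, 3))
  arr <- array(0, shape)
  arr[1:5, 1:4, 1] <- 10                # 20-voxel cluster
  arr[7:10, 7:10, 8] <- 10              # 16 voxels, trimmed to 15 below
  arr[7, 7, 8] <- 0
  sm <- voxcent:::new_stat_map(as.vector(arr), 30L, "t", mask)
  cl <- label_clusters(sm, voxel_p = 0.01, rmm = 5)
  asr <- structure(list(voxel_p = 0.01, fwhm_mm = 6, rmm = 5,
                        iterations = 1000,
                        alpha_to_k = data.frame(alpha = 0.05, k = 20L),
                        null_max_sizes = integer(0), seed = 1),
                   class = "alphasim_result")
  out <- apply_cluster_correction(cl, asr)
  expect_identical(out$table$surviving, out$table$size >= 20L)
  expect_true(any(out$table$size == 20L & out$table$surviving))
  expect_true(any(out$table$size == 15L & !out$table$surviving))

  asr1 <- asr
  asr1$alpha_to_k$k <- 1L
  expect_true(all(apply_cluster_correction(cl, asr1)$table$surviving))
  asr_bad <- asr
  asr_bad$voxel_p <- 0.001
  expect_error(apply_cluster_correction(cl, asr_bad), "different")
})
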