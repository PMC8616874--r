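test_that("DSNT reproduces delta, uniform and two-voxel heatmaps exactly", {
  spec <- patch_spec(c(10, 10, 10), 8, 0.5)
  N <- 8^3
  X <- lcpipe:::grid_coords(lcpipe:::patch_origin(spec), rep(8, 3), 0.5)
  delta <- matrix(0, 2, N)
  delta[1, 137] <- 1; delta[2, 200] <- 1
  co <- dsnt_coordinates(heatmap_prediction(delta, spec))
  expect_equal(co$left_mm, X[137, ])
  expect_equal(co$right_mm, X[200, ])
  unif <- matrix(1 / N, 2, N)
  co_u <- dsnt_coordinates(heatmap_prediction(unif, spec))
  expect_equal(co_u$left_mm, c(10, 10, 10))
  # equal mass on two voxels -> midpoint of their centres
  two <- matrix(0, 2, N); two[1, c(1, 10)] <- 0.5; two[2, 50] <- 1
  co_2 <- dsnt_coordinates(heatmap_prediction(two, spec))
  expect_equal(co_2$left_mm, (X[1, ] + X[10, ]) / 2)
})

test_that("heatmap predictions must be non-negative, normalised, non-zero", {
  spec <- patch_spec(c(0, 0, 0), 4, 1)
  bad <- matrix(1, 2, 64)
  expect_error(heatmap_prediction(bad, spec), "sum to 1")
  neg <- matrix(0, 2, 64); neg[, 1] <- c(2, -1)
  expect_error(heatmap_prediction(neg, spec), "non-negative")
  zero <- matrix(0, 2, 64); zero[1, 1] <- 1
  expect_error(heatmap_prediction(zero, spec), "all-zero")
})

test_that("the Euclidean loss averages per-side distances and is a metric", {
  a <- landmark_set(c(0, 0, 0), c(7, 0, 0))
  expect_equal(euclidean_loss(a, a), 0)
  b <- landmark_set(c(3, 4, 0), c(7, 0, 0))    # 3-4-5 triangle on one side
  expect_equal(euclidean_loss(b, a), 2.5)
  expect_equal(euclidean_loss(a, b), euclidean_loss(b, a))
})

test_that("training instances contain their targets; identity when unaugmented", {
  smp <- test_phantom(seed = 21)
  sched <- scale_schedule(c(1.5, 0.75), patch_size_vox = 16)
  cfg_plain <- localizer_config(augment = FALSE)
  for (s in 1:10) {
    inst <- sample_training_instance(smp, sched, cfg_plain, rng_seed = s)
    expect_identical(inst$target$left_mm, smp$true_centers$left_mm)
    org <- inst$patch$origin_mm
    hi <- org + 15 * inst$patch$spacing_mm
    for (tgt in list(inst$target$left_mm, inst$target$right_mm))
      expect_true(all(tgt >= org) && all(tgt <= hi))
  }
  cfg_aug <- localizer_config(augment = TRUE)
  for (s in 1:10) {
    inst <- sample_training_instance(smp, sched, cfg_aug, rng_seed = s)
    org <- inst$patch$origin_mm
    hi <- org + 15 * inst$patch$spacing_mm
    for (tgt in list(inst$target$left_mm, inst$target$right_mm))
      expect_true(all(tgt >= org) && all(tgt <= hi))
  }
})

test_that("a pure translation of the image shifts the target by exactly -t", {
  smp <- test_phantom(seed = 21)
  aff <- list(fwd = function(x) sweep(x, 2, c(-1.5, 0.75, 2.25), "+"),
              inv = function(s) s - c(-1.5, 0.75, 2.25))
  # emulate the augmentation contract directly: sampling the image through
  # fwd() must map a feature at s to patch coordinate inv(s)
  truth <- smp$true_centers$left_mm
  shifted <- aff$inv(truth)
  vals_t <- sample_world(smp$volume, matrix(aff$fwd(matrix(shifted, 1)), 1))
  vals_s <- sample_world(smp$volume, matrix(truth, 1))
  expect_equal(vals_t, vals_s, tolerance = 1e-9)
})

test_that("oracle multi-scale localization is exact for any schedule length", {
  smp <- test_phantom(seed = 22)
  oracle <- oracle_heatmap_model(smp$true_centers)
  schedules <- list(c(3), c(3, 1.5), c(3, 1.5, 0.75), c(6, 3, 1.5, 0.75))
  for (res in schedules) {
    sched <- scale_schedule(res, patch_size_vox = 16)
    pred <- localize_multiscale(oracle, smp$volume, sched)
    expect_equal(pred$left_mm, smp$true_centers$left_mm, tolerance = 1e-9)
    expect_equal(pred$right_mm, smp$true_centers$right_mm, tolerance = 1e-9)
    expect_length(attr(pred, "trace"), length(res))
    expect_false(attr(pred, "failed"))
  }
  # arbitrary valid start centres (targets inside the first patch)
  for (s in 1:5) {
    start <- volume_center(smp$volume) + lcpipe:::with_seed(s, runif(3, -4, 4))
    pred <- localize_multiscale(oracle, smp$volume,
                                scale_schedule(c(3, 1.5), 16), start_mm = start)
    expect_equal(pred$left_mm, smp$true_centers$left_mm, tolerance = 1e-9)
  }
  expect_error(localize_multiscale(oracle, smp$volume,
                                   structure(list(resolutions_mm = numeric(0)),
                                             class = "scale_schedule")),
               "empty schedule")
})

test_that("single-pass equals a one-entry whole-volume schedule and has a memory guard", {
  smp <- test_phantom(seed = 22)
  oracle <- oracle_heatmap_model(smp$true_centers)
  sp <- localize_singlepass(oracle, smp$volume)
  whole <- scale_schedule(smp$volume$spacing_mm, dim(smp$volume$values)[1])
  ms <- localize_multiscale(oracle, smp$volume, whole,
                            start_mm = volume_center(smp$volume))
  expect_equal(sp$left_mm, ms$left_mm, tolerance = 1e-9)
  expect_equal(sp$right_mm, ms$right_mm, tolerance = 1e-9)
  expect_equal(sp$left_mm, smp$true_centers$left_mm, tolerance = 1e-9)
  expect_error(localize_singlepass(oracle, smp$volume, max_voxels = 10),
               "memory budget")
})

test_that("integer-voxel translation of the volume translates oracle landmarks equally", {
  smp <- test_phantom(seed = 23)
  v <- smp$volume
  shift_vox <- c(2, -1, 3)
  shifted_vals <- lcpipe:::shift3(v$values, shift_vox)
  vs <- volume_grid(shifted_vals, v$spacing_mm, v$origin_mm)
  t_mm <- shift_vox * v$spacing_mm
  truth_s <- landmark_set(smp$true_centers$left_mm + t_mm,
                          smp$true_centers$right_mm + t_mm)
  pred <- localize_multiscale(oracle_heatmap_model(truth_s), vs,
                              scale_schedule(c(1.5, 0.75), 16))
  expect_equal(pred$left_mm, smp$true_centers$left_mm + t_mm, tolerance = 1e-9)
  expect_equal(pred$right_mm, smp$true_centers$right_mm + t_mm, tolerance = 1e-9)
})

test_that("patience 0 returns the untrained initial weights", {
  cohort <- lapply(1:3, function(s) test_phantom(seed = 30 + s))
  cfg <- localizer_config(mode = "multiscale", width = 2, batch_size = 1,
                          epochs = 3, steps_per_epoch = 1, patience = 0,
                          seed = 77)
  m <- train_localizer(cohort[1:2], cfg, scale_schedule(c(1.5, 0.75), 16),
                       val_cohort = cohort[3])
  init <- lcpipe:::unet3d_init(1, 2, width = 2, seed = 77)
  expect_identical(m$net$params, init$params)
})

test_that("training is deterministic given a seed", {
  cohort <- lapply(1:4, function(s) test_phantom(seed = 30 + s))
  cfg <- localizer_config(mode = "multiscale", width = 2, batch_size = 2,
                          epochs = 1, steps_per_epoch = 3, patience = 1,
                          seed = 5)
  sched <- scale_schedule(c(1.5, 0.75), 16)
  m1 <- train_localizer(cohort[1:3], cfg, sched, val_cohort = cohort[4])
  m2 <- train_localizer(cohort[1:3], cfg, sched, val_cohort = cohort[4])
  expect_identical(m1$val, m2$val)
  expect_identical(m1$net$params, m2$net$params)
  expect_error(train_localizer(list(), cfg, sched), "empty training set")
})
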