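test_that("patch tiling enumerates clamped overlapping offsets", {
  t64 <- tile_patches(c(64, 64, 64), patch_spec(64, 16))
  expect_identical(dim(t64), c(1L, 3L))
  expect_true(all(t64 == 0L))
  t96 <- tile_patches(c(96, 96, 96), patch_spec(64, 16))
  expect_identical(nrow(t96), 27L)
  expect_setequal(unique(t96[, 1]), c(0L, 16L, 32L))
  t70 <- tile_patches(c(70, 70, 70), patch_spec(64, 16))
  expect_identical(nrow(t70), 8L)
  expect_setequal(unique(t70[, 2]), c(0L, 6L))
  expect_error(tile_patches(c(32, 32, 32), patch_spec(64, 16)), "exceeds")
  expect_error(patch_spec(64, 0), "stride")
  expect_error(patch_spec(64, 65), "stride")
})

test_that("patch tiling covers every voxel at least once", {
  set.seed(21)
  for (i in 1:8) {
    shape <- sample(16:40, 3, replace = TRUE)
    spec <- patch_spec(size = 12, stride = sample(1:12, 1))
    offs <- tile_patches(shape, spec)
    cov <- array(0L, shape)
    for (r in seq_len(nrow(offs))) {
      o <- offs[r, ]
      cov[o[1] + 1:12, o[2] + 1:12, o[3] + 1:12] <-
        cov[o[1] + 1:12, o[2] + 1:12, o[3] + 1:12] + 1L
    }
    expect_true(all(cov >= 1L))
    expect_identical(anyDuplicated(offs), 0L)
  }
})

test_that("ensemble prediction averages models and is order-invariant", {
  s <- cached_sample()
  nets <- lapply(c(10, 20, 30), constant_net)
  spec <- patch_spec(size = 16, stride = 8)
  pred <- predict_volume(nets, s, spec)
  expect_equal(unique(as.vector(pred$values)), 20, tolerance = 1e-9)
  pred_rev <- predict_volume(rev(nets), s, spec)
  expect_equal(pred$values, pred_rev$values, tolerance = 1e-12)
  expect_error(predict_volume(list(), s, spec), "at least one")
})

test_that("patched prediction of a pointwise model equals full-volume output", {
  s <- cached_sample()
  net <- pointwise_net(16L)
  full <- vmatdose:::net_predict_array(net, vmatdose:::channel_stack(s))
  for (stride in c(5L, 16L)) {
    pred <- predict_volume(net, s, patch_spec(size = 16, stride = stride))
    expect_equal(pred$values, full, tolerance = 1e-12)
  }
})

test_that("D95 renormalization restores reference coverage", {
  s <- cached_sample()
  ref <- s$reference_dose
  ptv <- s$ptv_mask
  # a misscaled prediction recovers the reference exactly
  pred <- volume_grid(0.9 * ref$values, ref$spacing, ref$origin)
  out <- normalize_to_reference_d95(pred, ref, ptv)
  expect_equal(out$values, ref$values, tolerance = 1e-12)
  # generic prediction: D95 matches to 1e-6 relative
  set.seed(6)
  pred2 <- volume_grid(pmax(ref$values + stats::rnorm(length(ref$values), 0, 2), 0),
                       ref$spacing, ref$origin)
  out2 <- normalize_to_reference_d95(pred2, ref, ptv)
  expect_equal(dose_percentile(out2, ptv, 95), dose_percentile(ref, ptv, 95),
               tolerance = 1e-6)
  # identity when prediction already matches
  out3 <- normalize_to_reference_d95(ref, ref, ptv)
  expect_equal(out3$values, ref$values, tolerance = 1e-12)
  zero <- volume_grid(ref$values * 0, ref$spacing, ref$origin)
  expect_error(normalize_to_reference_d95(zero, ref, ptv), "D95")
})
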