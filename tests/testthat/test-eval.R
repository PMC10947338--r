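test_that("cumulative DVH matches counting oracles", {
  u <- array(45, c(5, 5, 4))
  m <- array(1, c(5, 5, 4))
  dvh <- compute_dvh(u, m, bin_width_Gy = 1)
  expect_equal(dvh$volume_fraction[dvh$dose_Gy <= 45], rep(1, sum(dvh$dose_Gy <= 45)))
  expect_equal(dvh$volume_fraction[dvh$dose_Gy > 45], rep(0, sum(dvh$dose_Gy > 45)))
  f <- array(0, c(10, 10, 1)); f[1:100] <- 1:100
  mm <- array(1, c(10, 10, 1))
  dvh2 <- compute_dvh(f, mm, bin_width_Gy = 0.5)
  expect_equal(dvh2$volume_fraction[dvh2$dose_Gy == 40.5], 0.60)
  expect_true(all(diff(dvh2$volume_fraction) <= 0))
  expect_equal(dvh2$volume_fraction[1], 1)  # dose 0 edge
  expect_gte(max(dvh2$dose_Gy), 100)
  expect_error(compute_dvh(f, mm * 0), "empty mask")
  expect_error(compute_dvh(f, mm, bin_width_Gy = 0), "> 0")
})

test_that("conformity index counts target and total isodose voxels", {
  d <- array(0, c(10, 10, 2))
  ptv <- array(0, c(10, 10, 2))
  ptv[1:50] <- 1            # 100 PTV voxels across both slices
  ptv[101:150] <- 1
  d[ptv == 1] <- 44
  expect_equal(conformity_index(d, ptv, 42.75), 1.0)
  d[151:175] <- 44          # 25 hot voxels outside the PTV
  expect_equal(conformity_index(d, ptv, 42.75), 100 / 125)
  expect_error(conformity_index(d, ptv, 99), "no voxel")
  expect_error(conformity_index(d, ptv, 0), "> 0")
})

test_that("homogeneity index is D5%/D95% and at least 1", {
  u <- array(45, c(4, 4, 4))
  m <- array(1, c(4, 4, 4))
  expect_equal(homogeneity_index(u, m), 1.0)
  f <- array(0, c(10, 10, 1)); f[1:100] <- 1:100
  mm <- array(1, c(10, 10, 1))
  expect_equal(homogeneity_index(f, mm), 96 / 6)
  set.seed(12)
  for (i in 1:25) {
    d <- array(stats::runif(5^3, 10, 60), c(5, 5, 5))
    msk <- array(stats::rbinom(5^3, 1, 0.5), c(5, 5, 5))
    if (sum(msk) == 0) next
    expect_gte(homogeneity_index(d, msk), 1)
  }
})

test_that("metric computations agree with brute-force oracles on random fields", {
  set.seed(40)
  for (i in 1:60) {
    dims <- c(8, 8, 8)
    dose <- array(stats::runif(prod(dims), 0, 55), dims)
    mask <- array(0, dims)
    mask[sample(prod(dims), 60)] <- 1
    vals <- dose[mask == 1]
    mx <- dose_metrics(dose, mask, vx_levels_Gy = c(20, 40))
    expect_identical(mx$Dmax, max(vals))
    expect_equal(mx$Dmean, mean(vals), tolerance = 1e-12)
    expect_identical(mx$V_20Gy, sum(vals >= 20) / length(vals))
    expect_identical(mx$V_40Gy, sum(vals >= 40) / length(vals))
    expect_gte(mx$Dmax, mx$Dmean)
    expect_gte(mx$D5, mx$D95)
    level <- stats::runif(1, 5, 50)
    if (any(dose >= level)) {
      ci <- conformity_index(dose, mask, level)
      expect_identical(ci, sum(dose >= level & mask == 1) / sum(dose >= level))
      expect_true(ci >= 0 && ci <= 1)
    }
  }
})

test_that("plan deltas follow the percentage and Gy definitions", {
  s <- cached_sample()
  ref <- s$reference_dose
  st <- vmatdose:::sample_structures(s)
  # identity: all deltas zero
  cmp0 <- plan_dose_deltas(ref, ref, st)
  expect_true(all(abs(cmp0$ptv$delta_pct) < 1e-12))
  expect_true(all(abs(cmp0$oar$delta_dmean_Gy) < 1e-12))
  expect_equal(cmp0$voxel_mean_diff_Gy, 0)
  # uniform scaling: D_V% deltas are the scaling in percent
  pred <- volume_grid(ref$values * 0.98, ref$spacing, ref$origin)
  cmp <- plan_dose_deltas(pred, ref, st)
  expect_equal(cmp$ptv$delta_pct, rep(-2, 3), tolerance = 1e-9)
  # Gy deltas: antisymmetric under swapping prediction and reference
  set.seed(3)
  pred2 <- volume_grid(pmax(ref$values + stats::rnorm(length(ref$values), 0, 1.5), 0),
                       ref$spacing, ref$origin)
  ab <- plan_dose_deltas(pred2, ref, st)
  ba <- plan_dose_deltas(ref, pred2, st)
  expect_equal(ab$oar$delta_dmean_Gy, -ba$oar$delta_dmean_Gy, tolerance = 1e-12)
  expect_equal(ab$oar$delta_dmax_Gy, -ba$oar$delta_dmax_Gy, tolerance = 1e-12)
  expect_equal(ab$voxel_mean_diff_Gy, -ba$voxel_mean_diff_Gy, tolerance = 1e-12)
  # worked example: D1% 44.5 vs 45 -> -1.111%
  expect_equal((44.5 - 45) / 45 * 100, -1.1111, tolerance = 1e-4)
})

test_that("isodose volumes are nested and threshold correctly", {
  s <- cached_sample()
  dose <- s$reference_dose
  lo <- isodose_volume(dose, 20)
  hi <- isodose_volume(dose, 40)
  expect_true(all(hi$values <= lo$values))  # mask(b) subset of mask(a), a < b
  expect_identical(lo$values, (dose$values >= 20) * 1)
  none <- isodose_volume(dose, max(dose$values) + 1)
  expect_identical(sum(none$values), 0)
  tiny <- isodose_volume(dose, 0.001)
  expect_true(all(tiny$values[s$body_mask$values == 1] == 1))
  expect_error(isodose_volume(dose, 0), "> 0")
})

test_that("flagging triggers on OAR sparing and extracts objectives", {
  s <- cached_sample()
  ref <- s$reference_dose
  st <- vmatdose:::sample_structures(s)
  # no difference: no flag, no objectives
  cmp0 <- plan_dose_deltas(ref, ref, st)
  f0 <- flag_and_extract_objectives(cmp0, ref, s$body_mask)
  expect_false(f0$flag)
  expect_length(f0$objectives, 0L)
  # predicted bladder sparing of 5 Gy mean: flag + bladder objectives
  bl <- st$bladder$values == 1
  pv <- ref$values
  pv[bl] <- pmax(pv[bl] - 5, 0)
  pred <- volume_grid(pv, ref$spacing, ref$origin)
  cmp <- plan_dose_deltas(pred, ref, st)
  fl <- flag_and_extract_objectives(cmp, pred, s$body_mask)
  expect_true(fl$flag)
  kinds <- vapply(fl$objectives, function(o) o$kind, character(1))
  strs <- vapply(fl$objectives, function(o) o$structure, character(1))
  expect_true(any(kinds == "max_dose" & strs == "bladder"))
  expect_true(any(kinds == "max_dvh" & strs == "bladder"))
  # the max-dvh objective sits at the predicted median dose
  mdvh <- fl$objectives[[which(kinds == "max_dvh" & strs == "bladder")[1]]]
  expect_equal(mdvh$dose_Gy, dose_percentile(pred, st$bladder, 50), tolerance = 1e-9)
  expect_equal(mdvh$volume_fraction, 0.5)
  # fall-off structures: body minus larger isodose contains body minus smaller
  fo <- fl$objectives[kinds == "dose_falloff_structure"]
  expect_gt(length(fo), 0L)
  lv <- vapply(fo, function(o) o$dose_Gy, numeric(1))
  m40 <- fo[[which(lv == 40)]]$mask$values
  m20 <- fo[[which(lv == 20)]]$mask$values
  expect_true(all(m20 <= m40))
})

test_that("metrics report round-trips and summarizes the cohort", {
  s <- cached_sample()
  ref <- s$reference_dose
  st <- vmatdose:::sample_structures(s)
  set.seed(9)
  cmps <- lapply(1:2, function(i) {
    pred <- volume_grid(pmax(ref$values + stats::rnorm(length(ref$values), 0, 1), 0),
                        ref$spacing, ref$origin)
    plan_dose_deltas(pred, ref, st, plan_id = sprintf("p%d", i))
  })
  dir <- withr::local_tempdir()
  rep <- write_metrics_report(cmps, dir)
  expect_true(file.exists(file.path(dir, "metrics_detail.csv")))
  expect_identical(sum(rep$detail$metric == "voxel_mean_diff_Gy"), 2L)
  # exact JSON round-trip
  back <- jsonlite::read_json(file.path(dir, "metrics.json"), simplifyVector = TRUE)
  expect_equal(back$detail$delta, rep$detail$delta, tolerance = 0)
  # summary mean of the two plans
  vm <- rep$detail$delta[rep$detail$metric == "voxel_mean_diff_Gy"]
  expect_equal(rep$summary$mean[rep$summary$metric == "voxel_mean_diff_Gy"], mean(vm))
  expect_error(write_metrics_report(list(), dir), "empty")
})
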