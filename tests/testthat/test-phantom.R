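test_that("phantom generation is seeded-deterministic and yields 16 channels", {
  cfg <- tiny_phantom_config()
  a <- generate_phantom(cfg, 42)
  b <- generate_phantom(cfg, 42)
  expect_length(a$channels, 16L)
  expect_identical(names(a$channels), channel_order())
  for (nm in channel_order())
    expect_identical(a$channels[[nm]]$values, b$channels[[nm]]$values)
  expect_identical(a$reference_dose$values, b$reference_dose$values)
  # a different seed gives a different anatomy
  c <- generate_phantom(cfg, 43)
  expect_false(identical(a$channels$ct$values, c$channels$ct$values))
})

test_that("phantom invariants: nesting, CT range, dose physicality", {
  cfg <- tiny_phantom_config()
  for (seed in c(11, 12, 13)) {
    s <- generate_phantom(cfg, seed)
    body <- s$channels$body$values
    for (nm in structure_vocabulary())
      expect_true(all(s$channels[[nm]]$values <= body), label = nm)
    expect_true(all(s$channels$ct$values >= 0 & s$channels$ct$values <= 1))
    d <- s$reference_dose$values
    rx <- cfg$prescription_Gy
    expect_gte(min(d), 0)
    expect_lte(max(d), (1 + cfg$hotspot_fraction) * rx + 1e-9)
    expect_true(all(d[body == 0] == 0))
    # the prescription isodose covers the PTV
    expect_true(all(d[s$ptv_mask$values != 0] >= rx - 1e-9))
    # target channel carries the prescription
    expect_setequal(unique(as.vector(s$channels$target$values)), c(0, rx))
  }
})

test_that("invalid geometry is rejected", {
  g <- small_organs()
  g[g$name == "ptv", c("rx", "ry", "rz")] <- g[g$name == "body", c("rx", "ry", "rz")] + 1
  expect_error(phantom_config(grid_shape = 32, organs = g), "PTV radius")
  expect_error(phantom_config(grid_shape = 32, spacing_mm = 0), "spacing")
  expect_error(phantom_config(grid_shape = 16), "grid_shape")
  expect_error(phantom_config(grid_shape = 32, organs = small_organs(),
                              hotspot_fraction = 0.2), "hotspot")
  # full-size organs cannot fit a 32^3 grid at 3 mm
  cfg <- phantom_config(grid_shape = 32, organs = default_organ_geometry())
  expect_error(generate_phantom(cfg, 1), "fit inside the grid")
})

test_that("analytic dose follows the exponential fall-off point-wise", {
  # single-voxel PTV at the centre of a large body, no sparing, no hotspot
  dims <- c(31, 31, 31)
  sp <- 3
  ptv_arr <- array(0, dims); ptv_arr[16, 16, 16] <- 1
  body_arr <- array(1, dims)
  ptv <- structure_mask("ptv", ptv_arr, sp)
  body <- structure_mask("body", body_arr, sp)
  tau <- 6 / log(2)  # half dose every 6 mm
  cfg <- tiny_phantom_config(falloff_tau_mm = tau, hotspot_fraction = 0,
                             sparing = list())
  d <- analytic_dose(ptv, list(body = body), cfg)
  expect_equal(d$values[16, 16, 16], 45)                      # inside PTV, h = 0
  expect_equal(d$values[18, 16, 16], 22.5, tolerance = 1e-12) # 6 mm = tau ln 2
  expect_equal(d$values[17, 16, 16], 45 * exp(-3 / tau), tolerance = 1e-12)
  # monotone fall-off along an axis
  line <- d$values[16:31, 16, 16]
  expect_true(all(diff(line) <= 1e-12))
  # sparing factor scales the out-of-target dose
  bl_arr <- array(0, dims); bl_arr[22:24, 14:18, 14:18] <- 1
  bladder <- structure_mask("bladder", bl_arr, sp)
  cfg_s <- tiny_phantom_config(falloff_tau_mm = tau, hotspot_fraction = 0,
                               sparing = list(bladder = 0.5),
                               sparing_influence_mm = 10)
  ds <- analytic_dose(ptv, list(body = body, bladder = bladder), cfg_s)
  expect_equal(ds$values[23, 16, 16], 0.5 * d$values[23, 16, 16], tolerance = 1e-12)
  # far from the bladder nothing changes
  expect_equal(ds$values[16, 16, 2], d$values[16, 16, 2], tolerance = 1e-12)
  # empty PTV errors
  empty <- structure_mask("ptv", array(0, dims), sp)
  expect_error(analytic_dose(empty, list(body = body), cfg), "empty PTV")
})

test_that("3:1:1 largest-remainder split reproduces the study sizes", {
  expect_identical(split_sizes(79), c(47L, 16L, 16L))
  expect_identical(split_sizes(5), c(3L, 1L, 1L))
  expect_identical(split_sizes(80), c(48L, 16L, 16L))
  expect_error(split_sizes(4), ">= 5")
  for (n in 5:200) {
    sz <- split_sizes(n)
    expect_identical(sum(sz), as.integer(n))
    expect_true(all(sz >= 1L))
    # never off by more than one from the exact quota
    expect_true(all(abs(sz - n * c(3, 1, 1) / 5) < 1))
  }
})

test_that("make_cohort partitions the cohort disjointly and reproducibly", {
  cfg <- tiny_phantom_config()
  co <- make_cohort(cfg, 7, seed = 5)
  expect_length(co$samples, 7L)
  ids <- vapply(co$samples, function(s) s$plan_id, character(1))
  all_ids <- c(co$split$train_ids, co$split$validation_ids, co$split$test_ids)
  expect_setequal(all_ids, ids)
  expect_identical(anyDuplicated(all_ids), 0L)
  # split_sizes(7): quotas (4.2, 1.4, 1.4) -> floors (4, 1, 1), remainder 1
  # goes to validation (largest fraction, train-val-test tie order)
  expect_identical(split_sizes(7), c(4L, 2L, 1L))
  expect_length(co$split$train_ids, 4L)
  co2 <- make_cohort(cfg, 7, seed = 5)
  expect_identical(co$split, co2$split)
  expect_identical(co$samples[[3]]$reference_dose$values,
                   co2$samples[[3]]$reference_dose$values)
  expect_error(make_cohort(cfg, 4, seed = 1), ">= 5")
})
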