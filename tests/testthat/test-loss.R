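# Independent oracle: D_V% as the minimum of the hottest ceil(V*N/100)
# voxels, found by explicit ascending sort and tail selection.
oracle_dvp <- function(vals, V) {
  n <- length(vals)
  k <- ceiling(V * n / 100)
  hottest <- sort(vals)[(n - k + 1):n]
  min(hottest)
}

test_that("dose percentile matches the brute-force oracle exactly", {
  f <- array(0, c(10, 10, 1)); f[1:100] <- 1:100
  m <- array(1, c(10, 10, 1))
  expect_identical(dose_percentile(f, m, 95), 6)
  expect_identical(dose_percentile(f, m, 1), 100)
  expect_identical(dose_percentile(array(45, c(4, 4, 4)), array(1, c(4, 4, 4)), 50), 45)
  set.seed(31)
  for (i in 1:200) {
    dims <- c(sample(4:8, 1), sample(4:8, 1), sample(4:8, 1))
    dose <- array(stats::runif(prod(dims), 0, 60), dims)
    mask <- array(0, dims)
    mask[sample(prod(dims), sample(1:prod(dims), 1))] <- 1
    V <- stats::runif(1, 0.5, 100)
    expect_identical(dose_percentile(dose, mask, V), oracle_dvp(dose[mask == 1], V))
  }
  expect_error(dose_percentile(f, array(0, c(10, 10, 1)), 95), "empty mask")
  expect_error(dose_percentile(f, m, 0), "V must")
})

test_that("dose percentile is monotone non-increasing in V", {
  set.seed(8)
  dose <- array(stats::rnorm(6^3, 40, 10), c(6, 6, 6))
  mask <- array(stats::rbinom(6^3, 1, 0.5), c(6, 6, 6))
  vals <- vapply(seq(1, 100, by = 1), function(V) dose_percentile(dose, mask, V),
                 numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("combined loss reproduces its analytic identities", {
  s <- cached_sample()
  ref <- s$reference_dose$values
  ptv <- s$ptv_mask$values
  expect_identical(combined_loss(ref, ref, ptv), 0)
  # +2 Gy everywhere: MSE 4, each |dD_V%| = 2 -> 4 + 0.25 * 6 = 5.5
  expect_equal(combined_loss(ref + 2, ref, ptv), 5.5, tolerance = 1e-12)
  # pure MSE with dvh weight 0
  expect_equal(combined_loss(ref + 0.5, ref, ptv, loss_config(dvh_weight = 0)), 0.25,
               tolerance = 1e-12)
  # no PTV voxels in the patch: MSE only
  expect_equal(combined_loss(ref + 2, ref, ptv * 0), 4, tolerance = 1e-12)
  expect_error(combined_loss(ref[1:8, 1:8, 1:8], ref, ptv), "geometry")
})

test_that("combined loss is non-negative and zero only at equality", {
  set.seed(14)
  for (i in 1:20) {
    d <- c(6, 6, 6)
    a <- array(stats::runif(prod(d), 0, 50), d)
    b <- array(stats::runif(prod(d), 0, 50), d)
    m <- array(stats::rbinom(prod(d), 1, 0.3), d)
    expect_gte(combined_loss(a, b, m), 0)
    expect_identical(combined_loss(a, a, m), 0)
    if (!identical(a, b)) expect_gt(combined_loss(a, b, m), 0)
  }
})

test_that("the loss gradient matches finite differences away from kinks", {
  set.seed(5)
  d <- c(5, 5, 5)
  ref <- array(stats::runif(prod(d), 0, 50), d)
  ptv <- array(stats::rbinom(prod(d), 1, 0.4), d)
  pred <- ref + array(stats::rnorm(prod(d), 0, 3), d)
  lg <- combined_loss(pred, ref, ptv, gradient = TRUE)
  eps <- 1e-7
  for (i in sample(prod(d), 12)) {
    p2 <- pred; p2[i] <- p2[i] + eps
    num <- (combined_loss(p2, ref, ptv) - lg$loss) / eps
    expect_equal(lg$grad[i], num, tolerance = 1e-3)
  }
})
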