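test_that("plateau schedule halves the learning rate after 55 stale epochs", {
  st <- list(lr = 0.001, best = Inf, counter = 0L, patience = 55L, factor = 0.5)
  st <- lr_schedule_step(st, 1.0)  # first epoch improves on Inf
  for (i in 1:54) st <- lr_schedule_step(st, 2.0)
  expect_equal(st$lr, 0.001)       # 54 stale epochs: unchanged
  st <- lr_schedule_step(st, 2.0)  # 55th stale epoch
  expect_equal(st$lr, 0.0005)
  expect_identical(st$counter, 0L)
  # improvement resets the counter without touching the lr
  st2 <- list(lr = 0.001, best = 1.0, counter = 30L, patience = 55L, factor = 0.5)
  st2 <- lr_schedule_step(st2, 0.5)
  expect_identical(st2$counter, 0L)
  expect_equal(st2$lr, 0.001)
  expect_equal(st2$best, 0.5)
})

test_that("patch sampling is uniform over valid offsets and reproducible", {
  s <- cached_sample()  # 32^3 grid
  # exact-fit patch: single valid position
  set.seed(1)
  p <- sample_training_patch(s, 32)
  expect_identical(p$offset, c(0L, 0L, 0L))
  expect_identical(dim(p$x), c(32L, 32L, 32L, 16L))
  # seeded determinism
  set.seed(77); a <- replicate(5, sample_training_patch(s, 16)$offset)
  set.seed(77); b <- replicate(5, sample_training_patch(s, 16)$offset)
  expect_identical(a, b)
  expect_error(sample_training_patch(s, 64), "exceeds")
  # offsets uniform over {0..16} per axis (chi-squared, alpha = 0.01)
  set.seed(99)
  offs <- t(replicate(4000, sample_training_patch(s, 16)$offset))
  for (axis in 1:3) {
    tab <- table(factor(offs[, axis], levels = 0:16))
    expect_gt(stats::chisq.test(tab)$p.value, 0.01)
  }
  # patch contents equal the crop at the drawn offset
  set.seed(3)
  p <- sample_training_patch(s, 16)
  expect_identical(p$dose,
                   s$reference_dose$values[p$offset[1] + 1:16, p$offset[2] + 1:16,
                                           p$offset[3] + 1:16, drop = FALSE])
})

test_that("training overfits a single phantom and records history", {
  s <- cached_sample()
  ncfg <- tiny_network_config()
  tcfg <- train_config(patch_size = 16, patches_per_epoch = 2, max_epochs = 8,
                       early_stop_patience_epochs = 20, seed = 4)
  net <- train_model(list(s), list(s), ncfg, tcfg)
  h <- net$history
  expect_identical(names(h), c("epoch", "train_loss", "val_loss", "lr"))
  expect_lte(nrow(h), 8L)
  expect_lt(min(h$val_loss), h$val_loss[1])  # validation loss improved
  expect_true(all(is.finite(h$train_loss)))
})

test_that("training is reproducible for a fixed seed", {
  s <- cached_sample()
  ncfg <- network_config(levels = 1, block_layers = 1, growth = 2, proj_channels = 4)
  tcfg <- train_config(patch_size = 16, max_epochs = 2,
                       early_stop_patience_epochs = 10, seed = 11)
  n1 <- train_model(list(s), list(s), ncfg, tcfg)
  n2 <- train_model(list(s), list(s), ncfg, tcfg)
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
})

test_that("ensembles require distinct seeds and degenerate to one model", {
  s <- cached_sample()
  ncfg <- network_config(levels = 1, block_layers = 1, growth = 2, proj_channels = 4)
  tcfg <- train_config(patch_size = 16, max_epochs = 1,
                       early_stop_patience_epochs = 5, seed = 1)
  expect_error(train_ensemble(list(s), list(s), ncfg, tcfg, n_models = 2,
                              seeds = c(3, 3)), "distinct")
  ens <- train_ensemble(list(s), list(s), ncfg, tcfg, n_models = 1, seeds = 5)
  expect_length(ens, 1L)
  single <- train_model(list(s), list(s), ncfg,
                        train_config(patch_size = 16, max_epochs = 1,
                                     early_stop_patience_epochs = 5, seed = 5))
  spec <- patch_spec(size = 16, stride = 16)
  expect_equal(predict_volume(ens, s, spec)$values,
               predict_volume(single, s, spec)$values, tolerance = 1e-12)
})
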