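#' Training configuration
#'
#' Optimization protocol for dose-prediction models: Adam with an initial
#' learning rate of 0.001, halved after every 55 epochs without
#' improvement of the validation loss, a maximum of 1000 epochs with early
#' stopping, and random 64^3 training patches.
#'
#' @param initial_lr Initial Adam learning rate.
#' @param plateau_patience_epochs Epochs of unimproved validation loss
#'   before the learning rate is multiplied by `lr_factor`.
#' @param lr_factor Learning-rate decay factor in (0, 1).
#' @param max_epochs Maximum number of epochs.
#' @param early_stop_patience_epochs Epochs of unimproved validation loss
#'   before training stops (the weights with the best validation loss are
#'   returned regardless).
#' @param patch_size Training patch edge length in voxels (per axis).
#' @param patches_per_epoch Patches drawn per training sample per epoch.
#' @param seed Seed for weight initialization and patch sampling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(initial_lr = 0.001, plateau_patience_epochs = 55L,
                         lr_factor = 0.5, max_epochs = 1000L,
                         early_stop_patience_epochs = 150L,
                         patch_size = 64L, patches_per_epoch = 1L, seed = 1L) {
  if (lr_factor <= 0 || lr_factor >= 1) stop("lr_factor must lie in (0, 1)", call. = FALSE)
  if (initial_lr <= 0) stop("initial_lr must be > 0", call. = FALSE)
  stopifnot(max_epochs >= 1, patch_size >= 1, patches_per_epoch >= 1)
  structure(
    list(initial_lr = initial_lr,
         plateau_patience_epochs = as.integer(plateau_patience_epochs),
         lr_factor = lr_factor, max_epochs = as.integer(max_epochs),
         early_stop_patience_epochs = as.integer(early_stop_patience_epochs),
         patch_size = as.integer(patch_size),
         patches_per_epoch = as.integer(patches_per_epoch),
         seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Sample a random training patch
#'
#' Draws a cubic patch with offsets uniform over all valid positions
#' (using the current RNG state) and crops every input channel, the
#' reference dose and the PTV mask identically.
#'
#' @param sample A `plan_sample`.
#' @param size Patch edge length (<= grid shape per axis).
#' @return List with `x` (patch input stack), `dose`, `ptv` (arrays) and
#'   the 0-based `offset`.
#' @export
sample_training_patch <- function(sample, size) {
  d <- dim(sample$reference_dose$values)
  if (any(size > d)) stop("patch size exceeds grid shape", call. = FALSE)
  off <- vapply(d, function(n) sample.int(n - size + 1L, 1L) - 1L, integer(1))
  ix <- off[1] + seq_len(size); iy <- off[2] + seq_len(size); iz <- off[3] + seq_len(size)
  x <- array(0, c(size, size, size, length(sample$channels)))
  for (i in seq_along(sample$channels))
    x[, , , i] <- sample$channels[[i]]$values[ix, iy, iz]
  list(x = x,
       dose = sample$reference_dose$values[ix, iy, iz, drop = FALSE],
       ptv = sample$ptv_mask$values[ix, iy, iz, drop = FALSE],
       offset = off)
}

#' Learning-rate plateau schedule
#'
#' Tracks the best validation loss seen so far; after
#' `plateau_patience_epochs` consecutive epochs without strict
#' improvement, the learning rate is multiplied by `lr_factor` and the
#' stagnation counter resets. Improvement also resets the counter.
#'
#' @param state List with `lr`, `best`, `counter`, `patience`, `factor`
#'   (see [train_model()]); create with
#'   `list(lr = , best = Inf, counter = 0L, patience = , factor = )`.
#' @param epoch_val_loss Validation loss of the finished epoch.
#' @return The updated state.
#' @export
lr_schedule_step <- function(state, epoch_val_loss) {
  if (epoch_val_loss < state$best) {
    state$best <- epoch_val_loss
    state$counter <- 0L
  } else {
    state$counter <- state$counter + 1L
    if (state$counter >= state$patience) {
      state$lr <- state$lr * state$factor
      state$counter <- 0L
    }
  }
  state
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (!identical(dim(st$m[[nm]]), dim(params[[nm]]))) dim(g) <- dim(params[[nm]])
    st$m[[nm]] <- st$m[[nm]] * beta1 + (1 - beta1) * g
    st$v[[nm]] <- st$v[[nm]] * beta2 + (1 - beta2) * g^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = st)
}

validation_loss <- function(net, samples, loss_cfg) {
  mean(vapply(samples, function(s) {
    pred <- net_predict_array(net, channel_stack(s))
    combined_loss(pred, s$reference_dose$values, s$ptv_mask$values, loss_cfg)
  }, numeric(1)))
}

#' Train one dose-prediction model
#'
#' Patch-based training with Adam, the plateau learning-rate schedule and
#' early stopping; the weights with the best validation loss are
#' returned. Fully reproducible given `train_cfg$seed`.
#'
#' @param train_samples,val_samples Non-empty lists of `plan_sample`.
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param loss_cfg A [loss_config()].
#' @param verbose Print per-epoch progress.
#' @return A `dose_net` whose `history` field is a data.frame with
#'   per-epoch `epoch`, `train_loss`, `val_loss`, `lr`.
#' @export
train_model <- function(train_samples, val_samples, net_cfg,
                        train_cfg = train_config(), loss_cfg = loss_config(),
                        verbose = FALSE) {
  if (length(train_samples) == 0 || length(val_samples) == 0)
    stop("training and validation sets must be non-empty", call. = FALSE)
  gdim <- dim(train_samples[[1]]$reference_dose$values)
  if (any(train_cfg$patch_size > gdim))
    stop("patch_size exceeds the grid shape", call. = FALSE)
  net <- build_network(net_cfg, train_cfg$seed)
  with_seed(train_cfg$seed + 7L, {
    opt <- adam_init(net$params)
    sched <- list(lr = train_cfg$initial_lr, best = Inf, counter = 0L,
                  patience = train_cfg$plateau_patience_epochs,
                  factor = train_cfg$lr_factor)
    best_val <- Inf
    best_params <- net$params
    stale <- 0L
    hist <- vector("list", train_cfg$max_epochs)
    for (epoch in seq_len(train_cfg$max_epochs)) {
      order_idx <- sample(seq_along(train_samples))
      tr_losses <- numeric(0)
      for (si in order_idx) {
        for (rep in seq_len(train_cfg$patches_per_epoch)) {
          patch <- sample_training_patch(train_samples[[si]], train_cfg$patch_size)
          pe <- new_param_env(net$params)
          fw <- net_forward(net$config, pe, patch$x)
          pred <- tp_val(fw$tape, fw$out)
          lg <- combined_loss(array(pred, dim(pred)[1:3]), patch$dose, patch$ptv,
                              loss_cfg, gradient = TRUE)
          if (!is.finite(lg$loss))
            stop("divergent loss (NaN/Inf) at epoch ", epoch, call. = FALSE)
          tr_losses <- c(tr_losses, lg$loss)
          g <- lg$grad
          dim(g) <- dim(pred)
          bk <- tape_backward(fw$tape, net$params, g)
          upd <- adam_step(net$params, bk$param_grads, opt, sched$lr)
          net$params <- upd$params
          opt <- upd$state
        }
      }
      vl <- validation_loss(net, val_samples, loss_cfg)
      if (!is.finite(vl)) stop("divergent validation loss at epoch ", epoch, call. = FALSE)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(tr_losses),
                                  val_loss = vl, lr = sched$lr)
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f lr %.2g",
                        epoch, mean(tr_losses), vl, sched$lr))
      if (vl < best_val) {
        best_val <- vl
        best_params <- net$params
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      sched <- lr_schedule_step(sched, vl)
      if (stale >= train_cfg$early_stop_patience_epochs) break
    }
    net$params <- best_params
    net$history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    net$train_config <- train_cfg
    net$loss_config <- loss_cfg
    net
  })
}

#' Train an ensemble of dose-prediction models
#'
#' Trains `n_models` independent models that differ only by their random
#' seed (weight initialization and patch sampling).
#'
#' @inheritParams train_model
#' @param n_models Number of ensemble members (>= 1; 3 in routine use).
#' @param seeds Distinct integer seeds, one per model.
#' @return List of `dose_net` objects.
#' @export
train_ensemble <- function(train_samples, val_samples, net_cfg,
                           train_cfg = train_config(), loss_cfg = loss_config(),
                           n_models = 3L, seeds = seq_len(n_models),
                           verbose = FALSE) {
  if (n_models < 1) stop("n_models must be >= 1", call. = FALSE)
  if (length(seeds) != n_models || anyDuplicated(seeds))
    stop("seeds must be distinct, one per model", call. = FALSE)
  lapply(seeds, function(s) {
    cfg_s <- train_cfg
    cfg_s$seed <- as.integer(s)
    train_model(train_samples, val_samples, net_cfg, cfg_s, loss_cfg, verbose)
  })
}
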