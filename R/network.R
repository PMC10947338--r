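# 3D dense dilated U-Net, built on im2col+GEMM convolution kernels with a
# minimal reverse-mode tape. Tensors are (x, y, z, channel) arrays.

new_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$nodes <- list()
  e
}

tp_push <- function(tape, op, value, parents = integer(), extra = NULL) {
  tape$n <- tape$n + 1L
  tape$nodes[[tape$n]] <- list(op = op, value = value, parents = parents, extra = extra)
  tape$n
}

tp_val <- function(tape, id) {
  force(id)  # nested tp_* calls push their node when the promise is forced
  tape$nodes[[id]]$value
}

tp_input <- function(tape, x) tp_push(tape, "input", x)

tp_conv <- function(tape, x_id, params, w_name, b_name, k, dil) {
  y <- .conv3d_forward(tp_val(tape, x_id), params[[w_name]], params[[b_name]], k, dil)
  tp_push(tape, "conv", y, x_id, list(w = w_name, b = b_name, k = k, dil = dil))
}

tp_relu <- function(tape, x_id) {
  x <- tp_val(tape, x_id)
  tp_push(tape, "relu", x * (x > 0), x_id)
}

tp_softplus <- function(tape, x_id) {
  x <- tp_val(tape, x_id)
  # numerically stable log(1 + exp(x))
  y <- pmax(x, 0) + log1p(exp(-abs(x)))
  dim(y) <- dim(x)
  tp_push(tape, "softplus", y, x_id)
}

tp_pool <- function(tape, x_id) {
  x <- tp_val(tape, x_id)
  tp_push(tape, "pool", .avgpool2_forward(x), x_id, list(in_dim = dim(x)))
}

tp_upsample <- function(tape, x_id) {
  tp_push(tape, "upsample", .upsample2_forward(tp_val(tape, x_id)), x_id)
}

tp_concat <- function(tape, x_ids) {
  vals <- lapply(x_ids, tp_val, tape = tape)
  nch <- vapply(vals, function(v) dim(v)[4], integer(1))
  d <- dim(vals[[1]])
  out <- array(0, c(d[1:3], sum(nch)))
  at <- 0L
  for (v in vals) {
    out[, , , at + seq_len(dim(v)[4])] <- v
    at <- at + dim(v)[4]
  }
  tp_push(tape, "concat", out, as.integer(x_ids), list(nch = nch))
}

# Reverse pass: returns list(param_grads = named list, input_grad).
tape_backward <- function(tape, params, grad_out) {
  grads <- vector("list", tape$n)
  grads[[tape$n]] <- grad_out
  pg <- list()
  input_grad <- NULL
  acc <- function(cur, g) if (is.null(cur)) g else cur + g
  for (id in seq(tape$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    switch(node$op,
      input = { input_grad <- acc(input_grad, g) },
      conv = {
        x <- tp_val(tape, node$parents)
        r <- .conv3d_backward(x, params[[node$extra$w]], g, node$extra$k, node$extra$dil)
        grads[[node$parents]] <- acc(grads[[node$parents]], r$dx)
        pg[[node$extra$w]] <- acc(pg[[node$extra$w]], r$dw)
        pg[[node$extra$b]] <- acc(pg[[node$extra$b]], r$db)
      },
      relu = {
        x <- tp_val(tape, node$parents)
        grads[[node$parents]] <- acc(grads[[node$parents]], g * (x > 0))
      },
      softplus = {
        x <- tp_val(tape, node$parents)
        grads[[node$parents]] <- acc(grads[[node$parents]], g * stats::plogis(x))
      },
      pool = {
        grads[[node$parents]] <- acc(grads[[node$parents]],
                                     .avgpool2_backward(g, node$extra$in_dim))
      },
      upsample = {
        grads[[node$parents]] <- acc(grads[[node$parents]], .upsample2_backward(g))
      },
      concat = {
        at <- 0L
        for (j in seq_along(node$parents)) {
          nc <- node$extra$nch[j]
          gj <- g[, , , at + seq_len(nc), drop = FALSE]
          grads[[node$parents[j]]] <- acc(grads[[node$parents[j]]], gj)
          at <- at + nc
        }
      },
      stop("unknown op: ", node$op)
    )
    grads[[id]] <- NULL  # free
  }
  list(param_grads = pg, input_grad = input_grad)
}

#' Network architecture configuration
#'
#' Configures the 3D dense dilated U-Net used for dose prediction: an
#' encoder-decoder over `levels` resolution levels with dense
#' (concatenative) convolution blocks, dilated convolutions in the
#' bottleneck, and a softplus output head so the predicted dose is
#' non-negative by construction. Output is a single channel (dose in Gy).
#' Dense-block inputs wider than `2 * growth` channels are first
#' compressed by a pointwise (1x1x1) transition convolution, as in
#' DenseNet transition layers.
#'
#' @param in_channels Number of input channels (16 model inputs).
#' @param levels Resolution levels (1 = no down/upsampling).
#' @param block_layers Convolutions per dense block.
#' @param growth Feature maps added by each dense-block convolution.
#' @param proj_channels Channels of the initial 1x1x1 input projection.
#' @param dilations Dilation rates cycled through the bottleneck block.
#' @param kernel Convolution kernel size (odd).
#' @param activation Hidden activation (`"relu"`).
#' @param final_activation Output mapping enforcing non-negativity
#'   (`"softplus"`).
#' @return An object of class `network_config`. The voxel receptive field
#'   per axis is reported by [build_network()].
#' @export
network_config <- function(in_channels = 16L, levels = 3L, block_layers = 4L,
                           growth = 8L, proj_channels = 2L * growth,
                           dilations = c(1L, 2L, 4L), kernel = 3L,
                           activation = "relu", final_activation = "softplus") {
  stopifnot(kernel %% 2 == 1, levels >= 1, block_layers >= 1, growth >= 1)
  activation <- match.arg(activation, "relu")
  final_activation <- match.arg(final_activation, "softplus")
  structure(
    list(in_channels = as.integer(in_channels), levels = as.integer(levels),
         block_layers = as.integer(block_layers), growth = as.integer(growth),
         proj_channels = as.integer(proj_channels),
         dilations = as.integer(dilations), kernel = as.integer(kernel),
         activation = activation, final_activation = final_activation),
    class = "network_config"
  )
}

# Parameter store: creates weights on first traversal (init = TRUE, He
# initialization from the current RNG), re-uses them afterwards. Traversal
# order is deterministic, so parameter names line up across calls.
new_param_env <- function(params = NULL) {
  e <- new.env(parent = emptyenv())
  e$init <- is.null(params)
  e$params <- if (is.null(params)) list() else params
  e$i <- 0L
  e
}

p_conv <- function(pe, cin, cout, k) {
  pe$i <- pe$i + 1L
  w <- paste0("w", pe$i); b <- paste0("b", pe$i)
  if (pe$init) {
    fan <- k^3 * cin
    pe$params[[w]] <- matrix(stats::rnorm(fan * cout, 0, sqrt(2 / fan)), fan, cout)
    pe$params[[b]] <- numeric(cout)
  } else if (nrow(pe$params[[w]]) != k^3 * cin) {
    stop("channel mismatch: input does not conform to the training layout", call. = FALSE)
  }
  list(w = w, b = b)
}

dense_block <- function(tape, pe, x_id, cin, cfg, at_bottleneck) {
  # compress wide inputs (skip concatenations) with a pointwise transition
  # so the 3^3 convolutions stay narrow
  width <- 2L * cfg$growth
  if (cin > width) {
    pt <- p_conv(pe, cin, width, 1L)
    x_id <- tp_relu(tape, tp_conv(tape, x_id, pe$params, pt$w, pt$b, 1L, 1L))
    cin <- width
  }
  feats <- list(x_id)
  ch <- cin
  for (l in seq_len(cfg$block_layers)) {
    dil <- if (at_bottleneck) cfg$dilations[(l - 1) %% length(cfg$dilations) + 1] else 1L
    inp <- if (length(feats) == 1L) feats[[1]] else tp_concat(tape, feats)
    pc <- p_conv(pe, ch, cfg$growth, cfg$kernel)
    y <- tp_relu(tape, tp_conv(tape, inp, pe$params, pc$w, pc$b, cfg$kernel, dil))
    feats <- c(feats, y)
    ch <- ch + cfg$growth
  }
  list(id = tp_concat(tape, feats), channels = ch)
}

unet_level <- function(tape, pe, x_id, cin, depth, cfg) {
  enc <- dense_block(tape, pe, x_id, cin, cfg, at_bottleneck = (depth == cfg$levels))
  if (depth == cfg$levels) return(enc)
  dn <- tp_pool(tape, enc$id)
  sub <- unet_level(tape, pe, dn, enc$channels, depth + 1L, cfg)
  up <- tp_upsample(tape, sub$id)
  cat_id <- tp_concat(tape, list(enc$id, up))
  dense_block(tape, pe, cat_id, enc$channels + sub$channels, cfg,
              at_bottleneck = FALSE)
}

# Full forward pass; returns tape, output node id and the parameter store.
net_forward <- function(cfg, pe, x) {
  tape <- new_tape()
  x_id <- tp_input(tape, x)
  pr <- p_conv(pe, cfg$in_channels, cfg$proj_channels, 1L)
  h <- tp_relu(tape, tp_conv(tape, x_id, pe$params, pr$w, pr$b, 1L, 1L))
  top <- unet_level(tape, pe, h, cfg$proj_channels, 1L, cfg)
  po <- p_conv(pe, top$channels, 1L, 1L)
  out <- tp_softplus(tape, tp_conv(tape, top$id, pe$params, po$w, po$b, 1L, 1L))
  list(tape = tape, out = out, input = x_id)
}

# Receptive field in voxels per axis at full resolution.
receptive_field_voxels <- function(cfg) {
  rf <- 1L
  reach <- function(depth) {
    scale <- 2^(depth - 1)
    r <- 0L
    for (l in seq_len(cfg$block_layers)) {
      dil <- if (depth == cfg$levels) cfg$dilations[(l - 1) %% length(cfg$dilations) + 1] else 1L
      r <- r + (cfg$kernel - 1L) * dil * scale
    }
    r
  }
  for (d in seq_len(cfg$levels)) {
    rf <- rf + reach(d)                      # encoder block at depth d
    if (d < cfg$levels) rf <- rf + reach(d)  # decoder block at depth d
    if (d < cfg$levels) rf <- rf + 2^(d - 1) # pooling/upsampling context
  }
  as.integer(rf)
}

#' Build (initialize) a dose-prediction network
#'
#' Instantiates the weights of a [network_config()] with He initialization
#' from `seed`. The returned object carries its configuration, parameters
#' and receptive field, and is used by [train_model()] and
#' [predict_volume()].
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `dose_net`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  pe <- new_param_env()
  dummy_n <- 4L * 2L^(cfg$levels - 1L)
  with_seed(seed, {
    net_forward(cfg, pe, array(0, c(dummy_n, dummy_n, dummy_n, cfg$in_channels)))
  })
  structure(
    list(config = cfg, params = pe$params, seed = as.integer(seed),
         receptive_field_voxels = receptive_field_voxels(cfg)),
    class = "dose_net"
  )
}

#' @export
print.dose_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<dose_net> %d levels, %d params, receptive field %d voxels/axis\n",
              x$config$levels, np, x$receptive_field_voxels))
  invisible(x)
}

# Forward-only prediction on an (x, y, z, in_channels) array -> 3D array (Gy).
net_predict_array <- function(net, x) {
  if (dim(x)[4] != net$config$in_channels)
    stop("channel mismatch: input does not conform to the training layout", call. = FALSE)
  div <- 2L^(net$config$levels - 1L)
  if (any(dim(x)[1:3] %% div != 0))
    stop(sprintf("input dims must be divisible by %d for a %d-level network",
                 div, net$config$levels), call. = FALSE)
  pe <- new_param_env(net$params)
  fw <- net_forward(net$config, pe, x)
  out <- tp_val(fw$tape, fw$out)
  array(out, dim(out)[1:3])
}
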