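# Shared fixtures: scaled-down phantoms and tiny networks so unit tests
# stay fast. Anything expensive is cached per session.

# Organ table shrunk by a common factor so phantoms fit a 32^3 grid (3 mm).
small_organs <- function(scale = 0.6) {
  g <- default_organ_geometry()
  g[, c("cx", "cy", "cz", "rx", "ry", "rz")] <-
    g[, c("cx", "cy", "cz", "rx", "ry", "rz")] * scale
  g
}

tiny_phantom_config <- function(grid = 32, ...) {
  phantom_config(grid_shape = grid, organs = small_organs(),
                 jitter_center_mm = 1, jitter_radius_frac = 0.03, ...)
}

tiny_network_config <- function(in_channels = 16L) {
  network_config(in_channels = in_channels, levels = 2L, block_layers = 2L,
                 growth = 4L, proj_channels = 6L)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_sample <- function() {
  if (is.null(.fixture_cache$sample))
    .fixture_cache$sample <- generate_phantom(tiny_phantom_config(), 101)
  .fixture_cache$sample
}

# A dose_net that predicts a constant value everywhere (all weights zero,
# output bias set so softplus(bias) = value).
constant_net <- function(value, in_channels = 16L) {
  cfg <- network_config(in_channels = in_channels, levels = 1L, block_layers = 1L,
                        growth = 2L, proj_channels = 2L)
  net <- build_network(cfg, 1L)
  for (nm in names(net$params)) net$params[[nm]][] <- 0
  bout <- names(net$params)[length(net$params)]
  stopifnot(length(net$params[[bout]]) == 1L)
  net$params[[bout]][] <- log(expm1(value))  # softplus inverse
  net
}

# A receptive-field-1 net: every convolution pointwise, so the output is a
# fixed voxel-wise function of the input channels.
pointwise_net <- function(in_channels = 16L, seed = 3L) {
  cfg <- network_config(in_channels = in_channels, levels = 1L, block_layers = 1L,
                        growth = 3L, proj_channels = 3L, kernel = 1L)
  build_network(cfg, seed)
}
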