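#' Structure vocabulary and model input channel order
#'
#' The fixed set of 14 normal-tissue and bony structures used as mask
#' channels, in channel order. Together with the normalized CT and the
#' target array they form the 16 model inputs.
#'
#' @return Character vector of the 14 structure names.
#' @export
structure_vocabulary <- function() {
  c("body", "bladder", "bowel_bag", "rectum",
    "femoral_head_l", "femoral_head_r", "kidney_l", "kidney_r",
    "liver", "spinal_cord", "l4", "l5", "pelvic_bone", "sacrum")
}

#' @rdname structure_vocabulary
#' @export
channel_order <- function() c("ct", "target", structure_vocabulary())

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default pelvis organ geometry
#'
#' Ellipsoid centres (mm, relative to the grid centre) and radii (mm) for
#' the body, PTV, and the 14-structure vocabulary, with a nominal CT value
#' (HU) per tissue. The pelvic bone is modelled as an ellipsoidal shell
#' (outer minus inner ellipsoid). Values are sized to a pelvis cropped to a
#' ~144 mm cube so that phantoms remain valid down to 48-voxel grids at
#' 3 mm spacing.
#'
#' @return A data.frame with one row per structure (plus `ptv`).
#' @export
default_organ_geometry <- function() {
  g <- rbind(
    data.frame(name = "body",           cx = 0,   cy = 0,  cz = 0,   rx = 62, ry = 58, rz = 68, hu = 30),
    data.frame(name = "ptv",            cx = 0,   cy = 4,  cz = 0,   rx = 20, ry = 16, rz = 18, hu = 40),
    data.frame(name = "bladder",        cx = 0,   cy = -28, cz = -14, rx = 13, ry = 11, rz = 11, hu = 10),
    data.frame(name = "bowel_bag",      cx = 0,   cy = -8, cz = 36,  rx = 32, ry = 24, rz = 22, hu = -50),
    data.frame(name = "rectum",         cx = 0,   cy = 26, cz = -10, rx = 8,  ry = 8,  rz = 22, hu = 20),
    data.frame(name = "femoral_head_l", cx = -42, cy = 0,  cz = -22, rx = 12, ry = 12, rz = 12, hu = 500),
    data.frame(name = "femoral_head_r", cx = 42,  cy = 0,  cz = -22, rx = 12, ry = 12, rz = 12, hu = 500),
    data.frame(name = "kidney_l",       cx = -28, cy = 12, cz = 52,  rx = 10, ry = 8,  rz = 13, hu = 45),
    data.frame(name = "kidney_r",       cx = 28,  cy = 12, cz = 52,  rx = 10, ry = 8,  rz = 13, hu = 45),
    data.frame(name = "liver",          cx = 30,  cy = -8, cz = 58,  rx = 18, ry = 14, rz = 10, hu = 55),
    data.frame(name = "spinal_cord",    cx = 0,   cy = 30, cz = 34,  rx = 4,  ry = 4,  rz = 32, hu = 35),
    data.frame(name = "l4",             cx = 0,   cy = 30, cz = 50,  rx = 10, ry = 8,  rz = 7,  hu = 550),
    data.frame(name = "l5",             cx = 0,   cy = 30, cz = 34,  rx = 10, ry = 8,  rz = 7,  hu = 550),
    data.frame(name = "pelvic_bone",    cx = 0,   cy = 8,  cz = -12, rx = 50, ry = 36, rz = 22, hu = 550),
    data.frame(name = "sacrum",         cx = 0,   cy = 30, cz = 4,   rx = 13, ry = 10, rz = 15, hu = 550)
  )
  g$shell_frac <- ifelse(g$name == "pelvic_bone", 0.78, NA_real_)
  g
}

#' Phantom cohort configuration
#'
#' Holds the study conditions of the synthetic cohort: grid geometry,
#' prescription (45 Gy in 25 fractions, single dose level), the organ
#' ellipsoid table, and the analytic dose model parameters.
#'
#' @param grid_shape Voxels per axis (length 1 or 3, each >= 32).
#' @param spacing_mm Voxel spacing in mm (default 3, the dose-grid spacing).
#' @param prescription_Gy Prescription dose (default 45).
#' @param n_fractions Number of fractions (default 25; bookkeeping only).
#' @param organs Organ geometry table, see [default_organ_geometry()].
#' @param falloff_tau_mm Exponential dose fall-off length outside the PTV.
#' @param hotspot_fraction Maximum in-target hotspot as a fraction of the
#'   prescription; must lie in \[0, 0.10\] (a 105% hotspot is the plausible
#'   upper end for this plan class).
#' @param sparing Named list of per-organ directional sparing factors in
#'   (0, 1\]; dose behind/inside these organs is reduced by the factor.
#' @param sparing_influence_mm An out-of-target voxel is spared only if its
#'   nearest spared organ lies within this distance.
#' @param hotspot_offset_frac Hotspot centre offset from the PTV centroid,
#'   as a fraction of the PTV radii.
#' @param jitter_center_mm,jitter_radius_frac Per-plan Gaussian jitter of
#'   organ centres (mm) and log-radii (fractional), giving the cohort its
#'   anatomical variability.
#' @param ct_noise_hu CT soft-tissue noise standard deviation (HU).
#' @param seed Base seed of the cohort.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 64),
                           spacing_mm = 3,
                           prescription_Gy = 45,
                           n_fractions = 25,
                           organs = default_organ_geometry(),
                           falloff_tau_mm = 22,
                           hotspot_fraction = 0.05,
                           sparing = list(bladder = 0.85, bowel_bag = 0.85,
                                          rectum = 0.80, femoral_head_l = 0.70,
                                          femoral_head_r = 0.70, kidney_l = 0.65,
                                          kidney_r = 0.65, spinal_cord = 0.60),
                           sparing_influence_mm = 30,
                           hotspot_offset_frac = c(0.2, -0.15, 0.1),
                           jitter_center_mm = 2,
                           jitter_radius_frac = 0.05,
                           ct_noise_hu = 12,
                           seed = 1L) {
  grid_shape <- rep_len(as.integer(grid_shape), 3L)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 3L)
  if (any(spacing_mm <= 0)) stop("config error: spacing_mm must be > 0", call. = FALSE)
  if (any(grid_shape < 32L)) stop("config error: grid_shape must be >= 32 per axis", call. = FALSE)
  if (hotspot_fraction < 0 || hotspot_fraction > 0.10)
    stop("config error: hotspot_fraction must lie in [0, 0.10]", call. = FALSE)
  if (falloff_tau_mm <= 0) stop("config error: falloff_tau_mm must be > 0", call. = FALSE)
  if (prescription_Gy <= 0) stop("config error: prescription_Gy must be > 0", call. = FALSE)
  if (length(sparing) && (any(unlist(sparing) <= 0) || any(unlist(sparing) > 1)))
    stop("config error: sparing factors must lie in (0, 1]", call. = FALSE)
  body <- organs[organs$name == "body", ]
  ptv  <- organs[organs$name == "ptv", ]
  if (nrow(body) != 1L || nrow(ptv) != 1L)
    stop("config error: organ table must contain exactly one 'body' and one 'ptv' row",
         call. = FALSE)
  if (any(c(ptv$rx, ptv$ry, ptv$rz) >= c(body$rx, body$ry, body$rz)))
    stop("geometry error: PTV radius must be smaller than the body radius on every axis",
         call. = FALSE)
  structure(
    list(grid_shape = grid_shape, spacing_mm = spacing_mm,
         prescription_Gy = prescription_Gy, n_fractions = n_fractions,
         organs = organs, falloff_tau_mm = falloff_tau_mm,
         hotspot_fraction = hotspot_fraction, sparing = sparing,
         sparing_influence_mm = sparing_influence_mm,
         hotspot_offset_frac = rep_len(hotspot_offset_frac, 3L),
         jitter_center_mm = jitter_center_mm,
         jitter_radius_frac = jitter_radius_frac,
         ct_noise_hu = ct_noise_hu, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Voxel-centre coordinates relative to the grid centre, one vector per axis.
grid_axes_mm <- function(config) {
  lapply(1:3, function(a) {
    n <- config$grid_shape[a]; s <- config$spacing_mm[a]
    (seq_len(n) - 1 - (n - 1) / 2) * s
  })
}

ellipsoid_mask <- function(axes, center, radii, shell_frac = NA_real_) {
  q <- outer(outer((axes[[1]] - center[1])^2 / radii[1]^2,
                   (axes[[2]] - center[2])^2 / radii[2]^2, `+`),
             (axes[[3]] - center[3])^2 / radii[3]^2, `+`)
  m <- q <= 1
  if (!is.na(shell_frac)) m <- m & (q >= shell_frac^2)
  m * 1
}

check_fits_grid <- function(organs, config) {
  half <- config$grid_shape * config$spacing_mm / 2
  for (i in seq_len(nrow(organs))) {
    o <- organs[i, ]
    if (any(abs(c(o$cx, o$cy, o$cz)) + c(o$rx, o$ry, o$rz) > half))
      stop(sprintf("geometry error: organ '%s' does not fit inside the grid extent",
                   o$name), call. = FALSE)
  }
  invisible(TRUE)
}

# Clamp jittered ellipsoids back inside the grid extent (keeps nesting and
# the fit precondition under extreme jitter draws).
jitter_organs <- function(organs, config) {
  half <- config$grid_shape * config$spacing_mm / 2
  for (i in seq_len(nrow(organs))) {
    ctr <- as.numeric(organs[i, c("cx", "cy", "cz")]) +
      stats::rnorm(3, 0, config$jitter_center_mm)
    rad <- as.numeric(organs[i, c("rx", "ry", "rz")]) *
      exp(stats::rnorm(3, 0, config$jitter_radius_frac))
    rad <- pmin(rad, half - 1e-6)
    ctr <- pmin(pmax(ctr, -(half - rad)), half - rad)
    organs[i, c("cx", "cy", "cz")] <- ctr
    organs[i, c("rx", "ry", "rz")] <- rad
  }
  organs
}

#' Analytic stand-in dose distribution
#'
#' A physically plausible, closed-form surrogate for a clinical VMAT dose:
#' homogeneous prescription dose with a bounded hotspot inside the PTV,
#' exponential fall-off with distance outside the PTV, direction-dependent
#' sparing of nearby organs at risk, and zero dose outside the body.
#'
#' Outside the PTV the dose is `Rx * exp(-d / tau) * s(x)`, where `d` is
#' the Euclidean distance (mm) to the nearest PTV voxel centre and `s(x)`
#' is the sparing factor of the nearest configured organ at risk when that
#' organ lies within `sparing_influence_mm` (1 otherwise). Inside the PTV
#' the dose is `Rx * (1 + h * g(x))` with a Gaussian hotspot bump
#' `g(x) in (0, 1]`, so the in-target dose lies in `[Rx, (1 + h) * Rx]`.
#'
#' @param ptv_mask PTV [structure_mask()] (non-empty).
#' @param organ_masks Named list of [structure_mask()]; `body` zeroes dose
#'   outside the patient, members of `config$sparing` drive the sparing.
#' @param config A [phantom_config()].
#' @return Dose [volume_grid()] in Gy.
#' @export
analytic_dose <- function(ptv_mask, organ_masks, config) {
  ptv <- ptv_mask$values
  if (sum(ptv) == 0) stop("empty PTV", call. = FALSE)
  rx <- config$prescription_Gy
  sp <- ptv_mask$spacing
  d <- .edt3d(ptv, sp)

  s <- array(1, dim = dim(ptv))
  best <- array(Inf, dim = dim(ptv))
  for (nm in names(config$sparing)) {
    om <- organ_masks[[nm]]
    if (is.null(om) || sum(om$values) == 0) next
    do <- .edt3d(om$values, sp)
    take <- do < best & do <= config$sparing_influence_mm
    s[take] <- config$sparing[[nm]]
    best <- pmin(best, do)
  }

  dose <- rx * exp(-d / config$falloff_tau_mm) * s

  # in-target hotspot: Gaussian bump around an off-centre point
  idx <- which(ptv != 0, arr.ind = TRUE)
  axes <- grid_axes_mm(config)
  ctr <- c(mean(axes[[1]][idx[, 1]]), mean(axes[[2]][idx[, 2]]), mean(axes[[3]][idx[, 3]]))
  hw <- pmax(c(diff(range(axes[[1]][idx[, 1]])), diff(range(axes[[2]][idx[, 2]])),
               diff(range(axes[[3]][idx[, 3]]))) / 2, sp)
  hc <- ctr + config$hotspot_offset_frac * hw
  r2 <- (axes[[1]][idx[, 1]] - hc[1])^2 + (axes[[2]][idx[, 2]] - hc[2])^2 +
    (axes[[3]][idx[, 3]] - hc[3])^2
  g <- exp(-r2 / (0.5 * mean(hw))^2)
  dose[ptv != 0] <- rx * (1 + config$hotspot_fraction * g)

  body <- organ_masks[["body"]]
  if (!is.null(body)) dose[body$values == 0] <- 0
  volume_grid(dose, sp, ptv_mask$origin)
}

#' Generate one synthetic pelvis plan
#'
#' Draws a jittered anatomy from the organ table, synthesizes a CT, builds
#' the 16 model input channels in the fixed order (normalized CT, target
#' array, then the 14 structure masks of [structure_vocabulary()]) and an
#' analytic reference dose. Bit-identical for identical `(config, plan_seed)`.
#'
#' @param config A [phantom_config()].
#' @param plan_seed Integer seed for this plan's anatomy/noise draws.
#' @return A `plan_sample`, see [assemble_inputs()].
#' @export
generate_phantom <- function(config, plan_seed) {
  stopifnot(inherits(config, "phantom_config"))
  check_fits_grid(config$organs, config)
  with_seed(plan_seed, {
    organs <- jitter_organs(config$organs, config)
    axes <- grid_axes_mm(config)
    sp <- config$spacing_mm
    origin <- -(config$grid_shape - 1) / 2 * sp  # grid centred on world 0

    mk <- function(row) {
      ellipsoid_mask(axes, as.numeric(row[c("cx", "cy", "cz")]),
                     as.numeric(row[c("rx", "ry", "rz")]), row$shell_frac)
    }
    body_arr <- mk(organs[organs$name == "body", ])
    masks <- list()
    for (nm in structure_vocabulary()) {
      arr <- if (nm == "body") body_arr else mk(organs[organs$name == nm, ]) * body_arr
      masks[[nm]] <- structure_mask(nm, arr, sp, origin)
    }
    ptv_arr <- mk(organs[organs$name == "ptv", ]) * body_arr
    ptv <- structure_mask("ptv", ptv_arr, sp, origin)

    # synthetic CT in HU: air, soft tissue with noise, organ tissues, bone on top
    hu <- array(-1000, dim = config$grid_shape)
    noise <- array(stats::rnorm(length(hu), 0, config$ct_noise_hu), dim = dim(hu))
    hu[body_arr == 1] <- 30 + noise[body_arr == 1]
    paint <- c("bowel_bag", "bladder", "rectum", "kidney_l", "kidney_r", "liver",
               "spinal_cord", "ptv", "l4", "l5", "pelvic_bone", "sacrum",
               "femoral_head_l", "femoral_head_r")
    for (nm in paint) {
      arr <- if (nm == "ptv") ptv_arr else masks[[nm]]$values
      base <- config$organs$hu[config$organs$name == nm]
      hu[arr == 1] <- base + noise[arr == 1]
    }
    ct <- normalize_ct(volume_grid(hu, sp, origin))

    dose <- analytic_dose(ptv, masks, config)
    assemble_inputs(ct, ptv, masks, config$prescription_Gy, dose,
                    plan_id = sprintf("phantom_%06d", plan_seed))
  })
}

#' Split a cohort 3:1:1 by largest-remainder allocation
#'
#' Training/validation/test quotas are `(3, 1, 1) / 5 * n`; integer sizes
#' are the floors plus one for the largest fractional remainders (ties
#' resolved in train, validation, test order). This reproduces a 47/16/16
#' split of 79 plans.
#'
#' @param n_plans Number of plans (>= 5).
#' @return Integer vector `c(train, validation, test)`.
#' @export
split_sizes <- function(n_plans) {
  if (n_plans < 5) stop("n_plans must be >= 5 so every partition is non-empty", call. = FALSE)
  quota <- c(train = 3, validation = 1, test = 1) / 5 * n_plans
  sizes <- floor(quota)
  rem <- quota - sizes
  short <- n_plans - sum(sizes)
  if (short > 0) {
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

#' Generate a seeded phantom cohort with a 3:1:1 split
#'
#' @param config A [phantom_config()].
#' @param n_plans Cohort size (>= 5).
#' @param seed Seed driving both the per-plan anatomy and the split shuffle.
#' @return A list with `samples` (list of `plan_sample`) and `split`
#'   (list of disjoint `train_ids`, `validation_ids`, `test_ids`).
#' @export
make_cohort <- function(config, n_plans, seed = config$seed) {
  sizes <- split_sizes(n_plans)  # validates n_plans
  plan_seeds <- (as.integer(seed) %% 100000L) * 10000L + seq_len(n_plans)
  samples <- lapply(plan_seeds, function(s) generate_phantom(config, s))
  ids <- vapply(samples, function(s) s$plan_id, character(1))
  perm <- with_seed(as.integer(seed) + 1L, sample.int(n_plans))
  shuffled <- ids[perm]
  split <- list(
    train_ids = shuffled[seq_len(sizes[1])],
    validation_ids = shuffled[sizes[1] + seq_len(sizes[2])],
    test_ids = shuffled[sizes[1] + sizes[2] + seq_len(sizes[3])]
  )
  list(samples = samples, split = split)
}
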