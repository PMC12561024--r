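# Synthetic B-mode bone phantom.
#
# The generator states a simple acoustic appearance model, sufficient to
# exercise the segmentation method without clinical data: a bright
# curvilinear bone echo (quadratic arc, Gaussian cross-profile) with an
# acoustic shadow beneath it, layered soft tissue with multiplicative
# speckle, and dimmer fascia-like distractor lines above the bone -- the
# structures that cause false positives in real scans. Row 0 is the
# transducer face; depth grows with the row index.

PHANTOM_ANATOMIES <- c("pelvis", "ribs_sternum", "radius_ulna",
                       "humerus", "femur", "tibia_fibula")

#' Phantom generator configuration
#'
#' Defaults emulate the acquisition regime of the clinical dataset the
#' package is designed around: 192 x 192 frames at 0.2 mm/px (a ~38 mm field
#' of view inside the 2-6 cm imaging-depth range), varying gain, and a small
#' fraction of frames with an empty label (363/4672 in the clinical set).
#'
#' @param height_px,width_px frame size in pixels.
#' @param pixel_spacing_mm physical pixel spacing (mm per pixel, isotropic).
#' @param bone_depth_range_px row range of the bone apex; default
#'   40-78% of the image height.
#' @param bone_curvature_range curvature (1/px) range of the quadratic bone
#'   arc; apex is its shallowest point (bone convex toward the probe).
#' @param bone_brightness peak echo intensity of the bone surface in `[0,1]`.
#' @param bone_thickness_px Gaussian cross-profile sigma of the echo.
#' @param shadow_attenuation multiplicative intensity factor in the acoustic
#'   shadow below the bone.
#' @param speckle_scale strength of the multiplicative Rayleigh speckle
#'   (0 disables it).
#' @param n_distractor_lines number of fascia-like bright lines rendered
#'   above the bone.
#' @param gain_range range of the global intensity multiplier.
#' @param empty_fraction probability that a frame contains no bone (and an
#'   empty label).
#' @param seed RNG seed used by [generate_phantom_dataset()].
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(height_px = 192L, width_px = 192L,
                           pixel_spacing_mm = 0.2,
                           bone_depth_range_px = NULL,
                           bone_curvature_range = c(5e-4, 4e-3),
                           bone_brightness = 0.9,
                           bone_thickness_px = 1.8,
                           shadow_attenuation = 0.25,
                           speckle_scale = 0.4,
                           n_distractor_lines = 2L,
                           gain_range = c(0.75, 1.15),
                           empty_fraction = 363 / 4672,
                           seed = NULL) {
  H <- as.integer(height_px); W <- as.integer(width_px)
  stopifnot(H > 0, W > 0, pixel_spacing_mm > 0,
            empty_fraction >= 0, empty_fraction <= 1,
            bone_brightness > 0, bone_brightness <= 1,
            shadow_attenuation >= 0, shadow_attenuation <= 1,
            speckle_scale >= 0, n_distractor_lines >= 0,
            diff(gain_range) >= 0, diff(bone_curvature_range) >= 0,
            bone_curvature_range[1] > 0)
  if (is.null(bone_depth_range_px))
    bone_depth_range_px <- c(round(0.40 * H), round(0.78 * H))
  if (bone_depth_range_px[1] < 4 || bone_depth_range_px[2] > H - 8 ||
      bone_depth_range_px[1] > bone_depth_range_px[2])
    stop("bone apex depth range must lie inside the image")
  structure(list(height_px = H, width_px = W,
                 pixel_spacing_mm = pixel_spacing_mm,
                 bone_depth_range_px = as.integer(bone_depth_range_px),
                 bone_curvature_range = bone_curvature_range,
                 bone_brightness = bone_brightness,
                 bone_thickness_px = bone_thickness_px,
                 shadow_attenuation = shadow_attenuation,
                 speckle_scale = speckle_scale,
                 n_distractor_lines = as.integer(n_distractor_lines),
                 gain_range = gain_range,
                 empty_fraction = empty_fraction,
                 seed = seed),
            class = "phantom_config")
}

# smooth 1-d noise: random walk low-pass filtered, zero mean, unit-ish range
smooth_noise <- function(n, roughness = 8) {
  k <- stats::rnorm(max(4, ceiling(n / roughness)))
  stats::spline(seq_along(k), k, n = n)$y
}

# draw a Gaussian-profile arc into img; rows_f gives the (fractional) centre
# row per column index in cols
draw_arc <- function(img, cols, rows_f, amp, sigma) {
  H <- nrow(img)
  r_lo <- pmax(1, floor(rows_f - 4 * sigma))
  r_hi <- pmin(H, ceiling(rows_f + 4 * sigma))
  for (k in seq_along(cols)) {
    rr <- r_lo[k]:r_hi[k]
    img[rr, cols[k]] <- img[rr, cols[k]] +
      amp[k] * exp(-((rr - rows_f[k])^2) / (2 * sigma^2))
  }
  img
}

#' Render one synthetic B-mode frame with its centerline label
#'
#' @param config a [phantom_config()].
#' @param seed optional integer; when given, the frame is a deterministic
#'   function of `(config, seed)`.
#' @return an object of class `phantom_sample`: list with `frame` (a
#'   `bmode_frame`: pixels in `[0,1]`, per-axis `pixel_spacing_mm`,
#'   `source_id`), `label` (0/1 matrix, one 8-connected 1-px curve or empty)
#'   and `metadata` (`anatomy`, `age_group`, `is_empty`).
#' @export
render_sample <- function(config, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  H <- config$height_px; W <- config$width_px
  is_empty <- stats::runif(1) < config$empty_fraction
  gain <- stats::runif(1, config$gain_range[1], config$gain_range[2])

  # layered soft tissue background
  depth_prof <- 0.15 + 0.05 * smooth_noise(H, roughness = 12)
  lat_prof <- 1 + 0.15 * smooth_noise(W, roughness = 16)
  img <- pmax(outer(depth_prof, lat_prof), 0.02)
  label <- matrix(0L, H, W)

  bone <- NULL
  if (!is_empty) {
    apex <- round(stats::runif(1, config$bone_depth_range_px[1],
                               config$bone_depth_range_px[2]))
    curv <- stats::runif(1, config$bone_curvature_range[1],
                         config$bone_curvature_range[2])
    c0 <- stats::runif(1, 0.40 * W, 0.60 * W)
    # half-width: slope < 1 keeps the curve 8-connected; arc stays in image
    L <- min(0.38 * W, 0.475 / curv, sqrt(max(H - 6 - apex, 0) / curv))
    if (L < 0.12 * W)
      stop("bone arc would leave the image for this configuration")
    cols <- max(1, ceiling(c0 - L)):min(W, floor(c0 + L))
    rows_f <- apex + curv * (cols - c0)^2
    label[cbind(floor(rows_f + 0.5), cols)] <- 1L
    bone <- list(cols = cols, rows_f = rows_f, apex = apex)
  }

  # fascia / muscle-boundary distractor lines, always shallower than the bone
  max_distr_row <- if (is_empty) 0.8 * H else max(4, bone$apex - 8)
  n_distr <- config$n_distractor_lines
  if (n_distr > 0 && max_distr_row - 3 > 0.10 * H) {
    for (d in seq_len(n_distr)) {
      da <- stats::runif(1, 0.10 * H, max_distr_row - 3)
      dcurv <- stats::runif(1, 0, 8e-4)
      dc0 <- stats::runif(1, 0.3 * W, 0.7 * W)
      dcols <- 1:W
      drows <- pmin(da + dcurv * (dcols - dc0)^2, max_distr_row)
      damp <- (0.12 + stats::runif(1, 0, 0.13)) *
        (1 + 0.2 * smooth_noise(W, 20))
      img <- draw_arc(img, dcols, drows, damp, 1.2)
    }
  }

  # multiplicative Rayleigh speckle, lightly smoothed into a grain
  if (config$speckle_scale > 0) {
    ray <- matrix(sqrt(-2 * log(stats::runif(H * W))), H, W)
    ray <- cpp_gauss_blur(ray, 0.8)
    rayn <- ray / mean(ray)
    f <- 1 + config$speckle_scale * (rayn - 1)
    img <- img * pmin(pmax(f, 0.45), 1.5)
  }

  if (!is_empty) {
    # acoustic shadow: smooth multiplicative attenuation below the surface
    att <- config$shadow_attenuation
    for (k in seq_along(bone$cols)) {
      r <- seq_len(H)
      s <- 1 - (1 - att) / (1 + exp(-(r - bone$rows_f[k] - 2.5) / 1.2))
      img[, bone$cols[k]] <- img[, bone$cols[k]] * s
    }
    # bright bone echo; per-column amplitude tapers mildly toward arc ends
    u <- (bone$cols - mean(bone$cols)) / (diff(range(bone$cols)) / 2 + 1e-9)
    amp <- config$bone_brightness * (1 - 0.12 * u^2) *
      (1 + 0.06 * smooth_noise(length(bone$cols), 10))
    img <- draw_arc(img, bone$cols, bone$rows_f, amp, config$bone_thickness_px)
  }

  pixels <- pmin(pmax(img * gain, 0), 1)
  frame <- structure(list(pixels = pixels,
                          pixel_spacing_mm = rep(config$pixel_spacing_mm, 2),
                          source_id = "phantom"),
                     class = "bmode_frame")
  structure(list(frame = frame, label = label,
                 metadata = list(anatomy = sample(PHANTOM_ANATOMIES, 1),
                                 age_group = sample(c("under10", "over10"), 1),
                                 is_empty = is_empty)),
            class = "phantom_sample")
}

#' Write a synthetic phantom dataset to disk
#'
#' Renders `n_images` frames, writes 8-bit grayscale PNG image/label pairs
#' and a manifest CSV. Frames are dealt round-robin over `n_groups`
#' synthetic "patients"; each group carries one anatomy tag and one age
#' group, so splits can be made group-disjoint and anatomy-stratified.
#'
#' @param config a [phantom_config()].
#' @param n_images number of frames to generate.
#' @param out_dir output directory (created if missing).
#' @param n_groups number of synthetic patient groups.
#' @param seed RNG seed; defaults to `config$seed` (or 1).
#' @return the manifest as a data frame (also written to
#'   `file.path(out_dir, "manifest.csv")`) with columns `image_path`,
#'   `label_path`, `group_id`, `anatomy`, `age_group`, `is_empty`,
#'   `pixel_spacing_mm`.
#' @export
generate_phantom_dataset <- function(config, n_images, out_dir,
                                     n_groups = 16L, seed = NULL) {
  stopifnot(inherits(config, "phantom_config"), n_images > 0, n_groups >= 1)
  if (is.null(seed)) seed <- if (is.null(config$seed)) 1L else config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  groups <- data.frame(
    group_id = sprintf("g%02d", seq_len(n_groups)),
    anatomy = PHANTOM_ANATOMIES[(seq_len(n_groups) - 1) %% length(PHANTOM_ANATOMIES) + 1],
    age_group = rep(c("under10", "over10"), length.out = n_groups),
    stringsAsFactors = FALSE)
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    g <- groups[(i - 1) %% n_groups + 1, ]
    s <- render_sample(config)
    ip <- file.path(out_dir, sprintf("image_%04d.png", i))
    lp <- file.path(out_dir, sprintf("label_%04d.png", i))
    png::writePNG(s$frame$pixels, ip)
    png::writePNG(s$label * 1.0, lp)
    rows[[i]] <- data.frame(image_path = ip, label_path = lp,
                            group_id = g$group_id, anatomy = g$anatomy,
                            age_group = g$age_group,
                            is_empty = s$metadata$is_empty,
                            pixel_spacing_mm = config$pixel_spacing_mm,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
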