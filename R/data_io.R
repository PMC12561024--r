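# Dataset loading, resizing, splitting and the augmentation recipe.

#' Load an image/label pair, resized to the network input size
#'
#' The image is loaded from PNG, resized by bilinear interpolation and
#' min-max normalised to `[0,1]`; the label is resized by nearest-neighbour
#' interpolation so it stays strictly binary. Pixel spacing is rescaled by
#' the per-axis resize factor and carried per axis, because non-square
#' resizes change the mm conversion of the distance metric.
#'
#' @param image_path,label_path PNG file paths.
#' @param target_size output (height, width).
#' @param pixel_spacing_mm spacing of the *source* image, scalar or per-axis.
#' @return list with `frame` (a `bmode_frame`) and `label` (0/1 matrix).
#' @export
load_pair <- function(image_path, label_path, target_size = c(192L, 192L),
                      pixel_spacing_mm = 0.2) {
  img <- read_gray_png(image_path)
  lab <- read_gray_png(label_path)
  if (!identical(dim(img), dim(lab)))
    stop("image and label shapes differ")
  if (length(pixel_spacing_mm) == 1) pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  d0 <- dim(img)
  img <- cpp_resize_bilinear(img, target_size[1], target_size[2])
  rng <- range(img)
  img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  lab <- cpp_resize_nearest(lab, target_size[1], target_size[2])
  if (!all(lab %in% c(0, 1))) {
    lab <- (lab >= 0.5) * 1
  }
  spacing <- pixel_spacing_mm * d0 / target_size
  frame <- structure(list(pixels = img, pixel_spacing_mm = spacing,
                          source_id = basename(image_path)),
                     class = "bmode_frame")
  list(frame = frame, label = lab)
}

read_gray_png <- function(path) {
  if (!file.exists(path)) stop("cannot read ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a
}

#' Augmentation configuration
#'
#' The recipe applied to an arbitrary quarter of the training set: Gaussian
#' blurring (sigma 5), rotation (-10 to +10 degrees), shearing (factor -0.2
#' to +0.2) and contrast adjustment (0.25 to 1.75).
#'
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param rotation_deg rotation range in degrees.
#' @param shear_factor shear range.
#' @param contrast_range contrast multiplier range (mean-anchored).
#' @param augment_fraction fraction of samples that receive augmentation.
#' @param op_prob probability that each enabled operation is applied within
#'   an augmented sample.
#' @export
augment_config <- function(blur_sigma = 5, rotation_deg = c(-10, 10),
                           shear_factor = c(-0.2, 0.2),
                           contrast_range = c(0.25, 1.75),
                           augment_fraction = 0.25, op_prob = 0.5) {
  stopifnot(diff(rotation_deg) >= 0, diff(shear_factor) >= 0,
            diff(contrast_range) >= 0,
            augment_fraction >= 0, augment_fraction <= 1)
  structure(list(blur_sigma = blur_sigma, rotation_deg = rotation_deg,
                 shear_factor = shear_factor, contrast_range = contrast_range,
                 augment_fraction = augment_fraction, op_prob = op_prob),
            class = "augment_config")
}

#' Jointly augment a frame and its label
#'
#' With probability `augment_fraction` an independently sampled subset of
#' {blur, rotate, shear, contrast} is applied (each with probability
#' `op_prob`). Geometric transforms are applied identically to image
#' (bilinear resampling) and mask (nearest-neighbour, re-binarised);
#' blur and contrast touch the image only. Border pixels are zero-filled.
#'
#' @param frame a `bmode_frame` or plain matrix in `[0,1]`.
#' @param mask binary label matrix.
#' @param cfg an [augment_config()].
#' @return list with `frame`, `mask`, and `augmented`/`became_empty` flags.
#' @export
augment_pair <- function(frame, mask, cfg = augment_config()) {
  px <- if (inherits(frame, "bmode_frame")) frame$pixels else frame
  was_empty <- sum(mask) == 0
  if (stats::runif(1) >= cfg$augment_fraction) {
    out <- frame
    return(list(frame = out, mask = mask, augmented = FALSE,
                became_empty = FALSE))
  }
  do_blur <- stats::runif(1) < cfg$op_prob
  do_rot <- stats::runif(1) < cfg$op_prob
  do_shear <- stats::runif(1) < cfg$op_prob
  do_contr <- stats::runif(1) < cfg$op_prob
  A <- diag(2)
  if (do_rot) {
    th <- stats::runif(1, cfg$rotation_deg[1], cfg$rotation_deg[2]) * pi / 180
    A <- A %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  }
  if (do_shear) {
    sh <- stats::runif(1, cfg$shear_factor[1], cfg$shear_factor[2])
    A <- A %*% matrix(c(1, 0, sh, 1), 2, 2)
  }
  if (do_rot || do_shear) {
    Ainv <- solve(A)  # inverse mapping for the warp
    px <- cpp_affine_warp(px, Ainv, c(0, 0), 0L)
    mask <- cpp_affine_warp(mask * 1.0, Ainv, c(0, 0), 1L)
    mask <- (mask >= 0.5) * 1
  }
  if (do_blur && cfg$blur_sigma > 0) px <- cpp_gauss_blur(px, cfg$blur_sigma)
  if (do_contr) {
    cf <- stats::runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
    px <- pmin(pmax(mean(px) + cf * (px - mean(px)), 0), 1)
  }
  out <- if (inherits(frame, "bmode_frame")) {
    frame$pixels <- px; frame
  } else px
  list(frame = out, mask = mask,
       augmented = TRUE,
       became_empty = !was_empty && sum(mask) == 0)
}

#' Group-aware stratified dataset split
#'
#' Assigns whole groups (synthetic patients) to train/validation/test so
#' that no group leaks across splits, while keeping the per-anatomy
#' proportions of each split close to the global proportions: groups are
#' allocated stratum by stratum in shuffled order to the split currently
#' furthest below its target share.
#'
#' @param manifest data frame with at least `group_id` and `anatomy`.
#' @param ratios length-3 numeric (train, val, test) summing to 1; entries
#'   may be zero.
#' @param seed RNG seed making the assignment deterministic.
#' @return the manifest with a `split` column
#'   (`train` / `val` / `test`).
#' @export
split_dataset <- function(manifest, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(all(c("group_id", "anatomy") %in% names(manifest)),
            length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  # a group's stratum is its (single or dominant) anatomy
  ga <- tapply(manifest$anatomy, manifest$group_id,
               function(a) names(sort(table(a), decreasing = TRUE))[1])
  gdf <- data.frame(group_id = names(ga), anatomy = unname(ga),
                    stringsAsFactors = FALSE)
  if (nrow(gdf) < sum(ratios > 0)) stop("fewer groups than splits")
  set.seed(seed)
  splits <- c("train", "val", "test")
  assigned <- stats::setNames(rep(NA_character_, nrow(gdf)), gdf$group_id)
  count <- c(train = 0, val = 0, test = 0)
  for (an in sample(unique(gdf$anatomy))) {
    gs <- sample(gdf$group_id[gdf$anatomy == an])
    for (g in gs) {
      deficit <- ratios * (sum(count) + 1) - count
      deficit[ratios == 0] <- -Inf
      pick <- splits[which.max(deficit)]
      assigned[g] <- pick
      count[pick] <- count[pick] + 1
    }
  }
  # guarantee every nonzero split holds at least one group
  for (s in splits[ratios > 0]) {
    if (count[s] == 0) {
      donor <- splits[which.max(count)]
      g <- names(assigned)[assigned == donor][1]
      assigned[g] <- s
      count[donor] <- count[donor] - 1
      count[s] <- count[s] + 1
    }
  }
  manifest$split <- unname(assigned[manifest$group_id])
  manifest
}

#' Load all pairs listed in a manifest
#'
#' @param manifest manifest data frame (rows of image/label paths).
#' @param target_size network input size.
#' @return list of `load_pair()` results, one per manifest row.
#' @export
load_manifest_pairs <- function(manifest, target_size = c(192L, 192L)) {
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- load_pair(manifest$image_path[i], manifest$label_path[i],
                   target_size = target_size,
                   pixel_spacing_mm = manifest$pixel_spacing_mm[i])
    p$meta <- manifest[i, ]
    p
  })
}
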