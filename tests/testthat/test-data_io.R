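write_pair <- function(img, lab, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ip <- file.path(dir, "img.png"); lp <- file.path(dir, "lab.png")
  png::writePNG(img, ip); png::writePNG(lab * 1.0, lp)
  c(ip, lp)
}

test_that("load_pair resizes, rescales spacing per axis and keeps labels binary", {
  img <- matrix(stats::runif(64 * 64), 64, 64)
  lab <- matrix(0, 64, 64); lab[30, 10:50] <- 1
  p <- write_pair(img, lab)
  r <- load_pair(p[1], p[2], target_size = c(32L, 32L), pixel_spacing_mm = 0.1)
  expect_equal(dim(r$frame$pixels), c(32, 32))
  expect_equal(r$frame$pixel_spacing_mm, c(0.2, 0.2))  # factor-2 downscale
  expect_true(all(r$label %in% c(0, 1)))
  expect_true(all(r$frame$pixels >= 0 & r$frame$pixels <= 1))

  # non-square resize: per-axis spacing differs
  r2 <- load_pair(p[1], p[2], target_size = c(32L, 64L), pixel_spacing_mm = 0.1)
  expect_equal(r2$frame$pixel_spacing_mm, c(0.2, 0.1))

  # an all-zero label stays all-zero at any size
  p0 <- write_pair(img, lab * 0)
  r0 <- load_pair(p0[1], p0[2], target_size = c(32L, 32L))
  expect_equal(sum(r0$label), 0)
})

test_that("resize-load is idempotent on already-sized binary labels", {
  lab <- matrix(0, 32, 32); lab[16, 4:28] <- 1
  img <- matrix(stats::runif(32 * 32), 32, 32)
  p <- write_pair(img, lab)
  r <- load_pair(p[1], p[2], target_size = c(32L, 32L))
  expect_equal(r$label, lab)
})

test_that("augmentation applies jointly to image and mask", {
  img <- matrix(stats::runif(64 * 64), 64, 64)
  mask <- matrix(0, 64, 64); mask[32, 10:54] <- 1

  # fraction 0: untouched
  set.seed(1)
  a0 <- augment_pair(img, mask, augment_config(augment_fraction = 0))
  expect_identical(a0$frame, img)
  expect_identical(a0$mask, mask)
  expect_false(a0$augmented)

  # pure +10 degree rotation keeps the mask binary, about the same length
  set.seed(2)
  cfg <- augment_config(rotation_deg = c(10, 10), shear_factor = c(0, 0),
                        contrast_range = c(1, 1), blur_sigma = 0,
                        augment_fraction = 1, op_prob = 1)
  a <- augment_pair(img, mask, cfg)
  expect_true(a$augmented)
  expect_true(all(a$mask %in% c(0, 1)))
  expect_lt(abs(sum(a$mask) - sum(mask)) / sum(mask), 0.2)
  expect_false(isTRUE(all.equal(a$frame, img)))

  # identity transforms leave the image unchanged
  set.seed(3)
  idcfg <- augment_config(rotation_deg = c(0, 0), shear_factor = c(0, 0),
                          contrast_range = c(1, 1), blur_sigma = 0,
                          augment_fraction = 1, op_prob = 1)
  ai <- augment_pair(img, mask, idcfg)
  expect_equal(ai$frame, img, tolerance = 1e-12)
  expect_equal(ai$mask, mask)
})

test_that("warping commutes with skeletonization within 2 px Hausdorff", {
  mask <- matrix(0, 64, 64); mask[30:32, 8:56] <- 1  # 3-px thick bar
  cfg <- augment_config(rotation_deg = c(8, 8), shear_factor = c(0, 0),
                        contrast_range = c(1, 1), blur_sigma = 0,
                        augment_fraction = 1, op_prob = 1)
  img <- matrix(0.5, 64, 64)
  set.seed(4)
  warped <- augment_pair(img, mask, cfg)$mask
  skel_then_warp <- {
    set.seed(4)
    augment_pair(img, skeletonize(mask) * 1, cfg)$mask
  }
  warp_then_skel <- skeletonize(warped)
  a <- which(warp_then_skel == 1, arr.ind = TRUE)
  b <- which(skel_then_warp == 1, arr.ind = TRUE)
  d_ab <- boneseg:::cpp_min_dists(matrix(as.numeric(a), ncol = 2),
                                  matrix(as.numeric(b), ncol = 2), c(1, 1))$dist
  d_ba <- boneseg:::cpp_min_dists(matrix(as.numeric(b), ncol = 2),
                                  matrix(as.numeric(a), ncol = 2), c(1, 1))$dist
  expect_lte(max(d_ab, d_ba), 2)
})

test_that("splits are group-disjoint, deterministic and anatomy-stratified", {
  # 10 equal groups: 8/1/1 groups at 80:10:10
  man <- data.frame(group_id = rep(sprintf("g%02d", 1:10), each = 4),
                    anatomy = rep("femur", 40), stringsAsFactors = FALSE)
  s1 <- split_dataset(man, seed = 7)
  gsplit <- unique(s1[, c("group_id", "split")])
  expect_equal(nrow(gsplit), 10)  # no group in two splits
  expect_equal(sort(as.vector(table(gsplit$split)), decreasing = TRUE),
               sort(c(8, 1, 1), decreasing = TRUE))
  s2 <- split_dataset(man, seed = 7)
  expect_identical(s1$split, s2$split)

  # 6 anatomies x 8 groups: every split sees every anatomy
  man2 <- data.frame(
    group_id = rep(sprintf("g%02d", 1:48), each = 3),
    anatomy = rep(rep(boneseg:::PHANTOM_ANATOMIES, each = 8), each = 3),
    stringsAsFactors = FALSE)
  s3 <- split_dataset(man2, ratios = c(0.5, 0.25, 0.25), seed = 1)
  tab <- table(s3$anatomy, s3$split)
  expect_true(all(tab > 0))
  # per-anatomy proportions within 10 points of global (1/6 each)
  prop <- prop.table(tab, margin = 2)
  expect_true(all(abs(prop - 1 / 6) <= 0.10))
  expect_error(split_dataset(man[man$group_id == "g01", ]), "fewer groups")
})
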