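test_that("rendering is seeded-deterministic and honours empty_fraction", {
  cfg <- phantom_config(height_px = 96L, width_px = 96L)
  a <- render_sample(cfg, seed = 0)
  b <- render_sample(cfg, seed = 0)
  expect_identical(a$frame$pixels, b$frame$pixels)
  expect_identical(a$label, b$label)

  cfg1 <- phantom_config(height_px = 96L, width_px = 96L, empty_fraction = 1)
  s <- render_sample(cfg1, seed = 3)
  expect_true(s$metadata$is_empty)
  expect_equal(sum(s$label), 0)

  cfg0 <- phantom_config(height_px = 96L, width_px = 96L, empty_fraction = 0)
  s0 <- render_sample(cfg0, seed = 3)
  expect_false(s0$metadata$is_empty)
  expect_gt(sum(s0$label), 0)
})

test_that("non-empty labels are single-pixel 8-connected ridge curves", {
  cfg <- phantom_config(height_px = 96L, width_px = 96L, empty_fraction = 0)
  for (s in 1:15) {
    sm <- render_sample(cfg, seed = s)
    lb <- sm$label
    pts <- which(lb == 1, arr.ind = TRUE)
    # one pixel per covered column, consecutive rows differing by <= 1
    cols <- pts[order(pts[, 2]), ]
    expect_true(all(table(pts[, 2]) == 1))
    expect_true(all(abs(diff(cols[, 1])) <= 1))
    # skeletonization is a no-op on a 1-px curve
    expect_identical(skeletonize(lb), matrix(as.integer(lb), nrow(lb)))
    # the label marks the echo ridge: column argmax within 2 px for >= 95%
    hits <- sum(vapply(seq_len(nrow(pts)), function(k) {
      abs(which.max(sm$frame$pixels[, pts[k, 2]]) - pts[k, 1]) <= 2
    }, TRUE))
    expect_gte(hits / nrow(pts), 0.95)
  }
})

test_that("acoustic shadow darkens the region below the bone (50-seed sweep)", {
  cfg <- phantom_config(height_px = 96L, width_px = 96L,
                        shadow_attenuation = 0.3, empty_fraction = 0)
  for (s in 1:50) {
    sm <- render_sample(cfg, seed = s)
    pts <- which(sm$label == 1, arr.ind = TRUE)
    bcols <- sort(unique(pts[, 2]))
    ocols <- setdiff(seq_len(96), bcols)
    r0 <- max(pts[, 1]) + 8
    if (r0 >= 96 || length(ocols) < 5) next
    shadow <- mean(sm$frame$pixels[r0:96, bcols])
    open <- mean(sm$frame$pixels[r0:96, ocols])
    expect_lt(shadow / open, 1)
  }
})

test_that("dataset generation writes consistent PNG pairs and manifest", {
  cfg <- phantom_config(height_px = 64L, width_px = 64L, empty_fraction = 0)
  out <- withr::local_tempdir()
  m <- generate_phantom_dataset(cfg, 10, out, n_groups = 4L, seed = 5)
  expect_equal(nrow(m), 10)
  expect_equal(sum(m$is_empty), 0)
  expect_true(all(file.exists(m$image_path)))
  expect_true(all(file.exists(m$label_path)))
  expect_setequal(unique(m$group_id), sprintf("g%02d", 1:4))
  # labels survive the 8-bit round trip exactly
  lab <- png::readPNG(m$label_path[1])
  expect_true(all(lab %in% c(0, 1)))

  # seeded regeneration is reproducible
  out2 <- withr::local_tempdir()
  m2 <- generate_phantom_dataset(cfg, 10, out2, n_groups = 4L, seed = 5)
  expect_identical(m$is_empty, m2$is_empty)
  expect_identical(png::readPNG(m$image_path[3]), png::readPNG(m2$image_path[3]))
})

test_that("realised empty-label count follows the seeded binomial draw", {
  f <- 363 / 4672
  cfg <- phantom_config(height_px = 64L, width_px = 64L, empty_fraction = f)
  out <- withr::local_tempdir()
  m <- generate_phantom_dataset(cfg, 400, out, n_groups = 8L, seed = 11)
  # expectation 31.1, SD 5.4: a 4-SD band
  expect_gt(sum(m$is_empty), 400 * f - 4 * sqrt(400 * f * (1 - f)))
  expect_lt(sum(m$is_empty), 400 * f + 4 * sqrt(400 * f * (1 - f)))
  out2 <- withr::local_tempdir()
  m2 <- generate_phantom_dataset(cfg, 400, out2, n_groups = 8L, seed = 11)
  expect_identical(m$is_empty, m2$is_empty)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(height_px = 96, bone_depth_range_px = c(50, 200)),
               "inside the image")
  expect_error(phantom_config(empty_fraction = 1.5))
  # arc that cannot fit: apex range at the very bottom
  cfg <- phantom_config(height_px = 96L, width_px = 96L,
                        bone_depth_range_px = c(88, 88),
                        bone_curvature_range = c(0.02, 0.02),
                        empty_fraction = 0)
  expect_error(render_sample(cfg, seed = 1), "leave the image")
})
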