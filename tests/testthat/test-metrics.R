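test_that("skeletonization thins bars and preserves thin curves", {
  line <- matrix(0L, 16, 32); line[8, 4:23] <- 1L
  expect_identical(skeletonize(line), line)
  bar <- matrix(0L, 16, 32); bar[7:9, 4:23] <- 1L
  sk <- skeletonize(bar)
  expect_true(all(rowSums(sk)[c(1:5, 11:16)] == 0))
  # a ~1-px line of about the bar's length (thinning erodes the two ends)
  expect_true(sum(sk) >= 16 && sum(sk) <= 22)
  expect_equal(unname(table(which(sk == 1, arr.ind = TRUE)[, "row"])[[1]]),
               sum(sk))  # all on one row
  empty <- matrix(0L, 8, 8)
  expect_identical(skeletonize(empty), empty)
  expect_error(skeletonize(matrix(2, 2, 2)), "binary")
})

test_that("clDice matches hand-counted fixtures and empty conventions", {
  lab <- matrix(0, 20, 20); lab[10, 3:18] <- 1
  expect_equal(cl_dice(lab, lab)$cl_dice, 1)

  # prediction covers exactly half the label: t_prec 1, t_sens 0.5 -> 2/3
  half <- matrix(0, 20, 20); half[10, 3:10] <- 1
  r <- cl_dice(half, lab)
  expect_equal(r$t_prec, 1)
  expect_equal(r$t_sens, 0.5)
  expect_equal(r$cl_dice, 2 / 3)

  empty <- matrix(0, 20, 20)
  expect_equal(cl_dice(empty, lab)$cl_dice, 0)
  expect_equal(cl_dice(lab, empty)$cl_dice, 0)
  expect_equal(cl_dice(empty, empty)$cl_dice, 1)
  expect_error(cl_dice(matrix(0, 2, 2), lab), "mismatch")
})

test_that("mean surface distance matches closed forms", {
  lab <- matrix(0, 10, 10); lab[1, 1] <- 1; lab[1, 2] <- 1
  prd <- matrix(0, 10, 10); prd[1, 1] <- 1
  r <- mean_surface_distance(prd, lab, spacing = c(1, 1))
  expect_equal(r$msd_mm, 0.5)   # (0 + 1) / 2

  # rigid 3-row shift toward the probe at 0.2 mm/px
  lab2 <- matrix(0, 32, 32); lab2[20, 5:28] <- 1
  prd2 <- matrix(0, 32, 32); prd2[17, 5:28] <- 1
  r2 <- mean_surface_distance(prd2, lab2, spacing = c(0.2, 0.2))
  expect_equal(r2$msd_mm, 0.6)
  expect_equal(r2$signed_offset_mm, 0.6)  # shallower prediction -> positive

  expect_equal(mean_surface_distance(lab2, lab2, c(0.2, 0.2))$msd_mm, 0)
  expect_false(mean_surface_distance(matrix(0, 4, 4), matrix(0, 4, 4))$defined)
})

test_that("metric invariants: padding, shift linearity, symmetry of roles", {
  set.seed(20)
  for (i in 1:20) {
    a <- random_small_mask(); b <- random_small_mask()
    r <- cl_dice(a, b)
    expect_gte(r$cl_dice, 0); expect_lte(r$cl_dice, 1)
    # padding both masks cannot change any score
    pad <- function(m) rbind(0, cbind(0, m, 0), 0)
    expect_equal(cl_dice(pad(a), pad(b))$cl_dice, r$cl_dice)
    m1 <- mean_surface_distance(a, b)
    m2 <- mean_surface_distance(pad(a), pad(b))
    expect_equal(m1$msd_mm, m2$msd_mm)
    # role swap exchanges t_prec and t_sens on skeleton-identical masks
    sa <- skeletonize(a); sb <- skeletonize(b)
    f <- cl_dice(sa, sb); g <- cl_dice(sb, sa)
    if (!is.na(f$t_prec) && !is.na(g$t_prec)) {
      expect_equal(f$t_prec, g$t_sens)
      expect_equal(f$t_sens, g$t_prec)
      expect_equal(f$cl_dice, g$cl_dice)
    }
  }
  # signed offset is exactly linear in a rigid row shift
  lab <- matrix(0, 40, 40); lab[25, 4:36] <- 1
  for (k in c(-4, -1, 2, 5)) {
    prd <- matrix(0, 40, 40)
    rows <- 25 - k
    prd[rows, 4:36] <- 1
    r <- mean_surface_distance(prd, lab, spacing = c(0.3, 0.3))
    expect_equal(r$signed_offset_mm, k * 0.3, tolerance = 1e-12)
  }
})

test_that("evaluate_set aggregates with sample SD and stratification", {
  lab <- matrix(0, 20, 20); lab[10, 3:18] <- 1
  half <- matrix(0, 20, 20); half[10, 3:10] <- 1
  # engineered clDice pair {1, 2/3}
  pairs <- list(list(pred = lab, label = lab, age_group = "under10"),
                list(pred = half, label = lab, age_group = "over10"))
  rep_ <- evaluate_set(pairs, strata_key = "age_group")
  expect_equal(rep_$aggregate$mean_cl_dice[1], mean(c(1, 2 / 3)))
  expect_equal(rep_$aggregate$sd_cl_dice[1], stats::sd(c(1, 2 / 3)))
  expect_setequal(rep_$aggregate$stratum, c("all", "under10", "over10"))

  # all-perfect set
  perf <- evaluate_set(list(list(pred = lab, label = lab),
                            list(pred = half, label = half)))
  expect_equal(perf$aggregate$mean_cl_dice[1], 1)
  expect_equal(perf$aggregate$mean_msd_mm[1], 0)

  # empty-label frames are excluded from distance aggregation and counted
  empty <- matrix(0, 20, 20)
  mix <- evaluate_set(list(list(pred = lab, label = lab),
                           list(pred = empty, label = empty),
                           list(pred = lab, label = empty)))
  expect_equal(mix$aggregate$n_msd_excluded[1], 2)
  expect_equal(mix$aggregate$n_detection_failures[1], 1)
  expect_equal(mix$per_image$cl_dice, c(1, 1, 0))
})
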