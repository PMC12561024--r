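test_that("convolution kernel matches a direct R computation", {
  set.seed(10)
  x <- array(stats::rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  w <- array(stats::rnorm(3 * 3 * 2 * 3), c(3, 3, 2, 3))
  b <- stats::rnorm(3)
  y <- boneseg:::cpp_conv2d(x, w, b, 1L, 1L)
  # naive quadruple loop oracle
  ref <- array(0, c(8, 8, 3, 2))
  for (n in 1:2) for (co in 1:3) for (j in 1:8) for (i in 1:8) {
    acc <- b[co]
    for (ci in 1:2) for (kj in 1:3) for (ki in 1:3) {
      ii <- i + ki - 2; jj <- j + kj - 2
      if (ii >= 1 && ii <= 8 && jj >= 1 && jj <= 8)
        acc <- acc + w[ki, kj, ci, co] * x[ii, jj, ci, n]
    }
    ref[i, j, co, n] <- acc
  }
  expect_equal(as.vector(y), as.vector(ref), tolerance = 1e-12)

  # stride-2 output size
  y2 <- boneseg:::cpp_conv2d(x, w, b, 2L, 1L)
  expect_equal(dim(y2), c(4, 4, 3, 2))
})

test_that("the forward pass is shape-correct, deterministic and multi-scale", {
  set.seed(3)
  m <- unext(unext_config(input_size = c(96L, 96L)))
  x <- array(stats::runif(96 * 96 * 2), c(96, 96, 1, 2))
  z <- boneseg:::unext_forward(m, x)$v
  expect_equal(dim(z), c(96, 96, 1, 2))
  expect_identical(z, boneseg:::unext_forward(m, x)$v)
  # fully convolutional: another /32-divisible size works
  x64 <- array(stats::runif(64 * 64), c(64, 64, 1, 1))
  expect_equal(dim(boneseg:::unext_forward(m, x64)$v), c(64, 64, 1, 1))
  expect_error(boneseg:::unext_forward(m, array(0, c(50, 50, 1, 1))),
               "divisible by 32")
})

test_that("every parameter receives gradient and gradients match finite differences", {
  set.seed(42)
  m <- unext(tiny_unext_cfg())
  x <- array(stats::runif(32 * 32 * 2), c(32, 32, 1, 2))
  y <- array(0, c(32, 32, 1, 2)); y[16, 5:28, 1, 1] <- 1; y[10, 8:20, 1, 2] <- 1
  sch <- loss_schedule(20)
  skp <- soft_skeleton_params(4)
  w <- c(wbce = 0.6, cldice = 0.4)
  boneseg:::ag_tape_start()
  z <- boneseg:::unext_forward(m, x, training = TRUE)
  L <- boneseg:::compound_loss_node(z, y, w, sch, skp)
  boneseg:::ag_backward(L)
  ps <- boneseg:::unext_params(m)
  expect_true(all(vapply(ps, function(p) !is.null(p$g), TRUE)))
  expect_true(all(vapply(ps, function(p) any(p$g != 0), TRUE)))

  lossfun <- function() boneseg:::with_no_tape({
    zz <- boneseg:::unext_forward(m, x, training = TRUE)
    boneseg:::compound_loss_node(zz, y, w, sch, skp)$v
  })
  eps <- 1e-6
  set.seed(1)
  for (nm in sample(names(ps), 8)) {
    p <- ps[[nm]]
    i <- sample(length(p$v), 1)
    v0 <- p$v[i]
    p$v[i] <- v0 + eps; lp <- lossfun()
    p$v[i] <- v0 - eps; lm <- lossfun()
    p$v[i] <- v0
    num <- (lp - lm) / (2 * eps)
    expect_equal(p$g[i], num, tolerance = 1e-3,
                 label = sprintf("gradient of %s", nm))
  }
  for (p in ps) p$g <- NULL
})

test_that("output is translation-consistent at pooling granularity (soft)", {
  set.seed(5)
  m <- unext(unext_config(input_size = c(96L, 96L)))
  x <- matrix(stats::runif(96 * 96), 96, 96)
  xs <- matrix(0, 96, 96); xs[33:96, ] <- x[1:64, ]
  z <- boneseg:::unext_forward(m, array(x, c(96, 96, 1, 1)))$v[, , 1, 1]
  zs <- boneseg:::unext_forward(m, array(xs, c(96, 96, 1, 1)))$v[, , 1, 1]
  a <- z[17:48, 17:80]; b <- zs[49:80, 17:80]
  expect_gt(stats::cor(as.vector(a), as.vector(b)), 0.95)
})

test_that("state save/load round-trips to identical predictions", {
  set.seed(8)
  m <- unext(tiny_unext_cfg())
  x <- matrix(stats::runif(32 * 32), 32, 32)
  p1 <- predict(m, x)[[1]]
  st <- unext_state(m)
  m2 <- unext(st$cfg)   # different random init
  unext_load_state(m2, st)
  expect_identical(predict(m2, x)[[1]], p1)
  expect_true(all(predict(m, x, type = "mask")[[1]] %in% c(0L, 1L)))
})
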