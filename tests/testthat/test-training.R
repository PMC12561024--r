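tiny_train_cfg <- function(total_epochs = 2L, n_folds = 2L, lr = 1e-3,
                           size = 32L, seed = 1L) {
  train_config(total_epochs = total_epochs, batch_size = 4L, lr = lr,
               n_folds = n_folds, seed = seed,
               schedule = loss_schedule(total_epochs,
                                        warmup_epochs = max(1L, total_epochs - 1L)),
               skel_params = soft_skeleton_params(4L),
               model_cfg = tiny_unext_cfg(size),
               augment = NULL)
}

test_that("a short training run logs history and checkpoints by val clDice", {
  pairs <- make_phantom_pairs(12, size = 32L, seed = 2)
  set.seed(1)
  fit <- train_fold(pairs[1:8], pairs[9:12], tiny_train_cfg(2L))
  expect_equal(nrow(fit$history), 2)
  expect_named(fit$history,
               c("epoch", "train_loss", "val_loss", "val_cl_dice", "lr",
                 "w_wbce", "w_cldice"))
  expect_equal(fit$best_epoch, which.max(fit$history$val_cl_dice))
  expect_equal(fit$best_val_cldice, max(fit$history$val_cl_dice))
  # same seed, same data -> identical history
  set.seed(1)
  fit2 <- train_fold(pairs[1:8], pairs[9:12], tiny_train_cfg(2L))
  expect_identical(fit$history, fit2$history)
})

test_that("plateau scheduler halves the LR after patience non-improving epochs", {
  pairs <- make_phantom_pairs(8, size = 32L, seed = 3)
  # lr ~ 0: validation loss is constant, so epochs 2..4 fail to improve
  cfg <- tiny_train_cfg(5L, lr = 1e-13)
  set.seed(2)
  fit <- train_fold(pairs[1:6], pairs[7:8], cfg)
  expect_equal(fit$history$lr, 1e-13 * c(1, 1, 1, 0.5, 0.5))
})

test_that("cross-validation folds are group-disjoint and exhaustive", {
  pairs <- make_phantom_pairs(20, size = 32L, n_groups = 10L, seed = 4)
  cfg <- tiny_train_cfg(2L, n_folds = 5L)
  ens <- crossval_unext(pairs, cfg)
  expect_s3_class(ens, "fold_ensemble")
  expect_length(ens$fold_states, 5)
  expect_length(ens$fold_scores, 5)
  folds <- ens$fold_of
  expect_equal(sort(as.vector(table(folds))), rep(2L, 5))  # 2 groups per fold
  expect_setequal(names(folds), sprintf("g%02d", 1:10))
  s <- summary(ens)
  expect_equal(nrow(s), 5)
})

test_that("ensemble prediction averages fold probabilities", {
  set.seed(9)
  m <- unext(tiny_unext_cfg())
  st <- unext_state(m)
  x <- matrix(stats::runif(32 * 32), 32, 32)
  single <- predict(m, x)[[1]]

  mk_ens <- function(states) {
    structure(list(fold_states = states, fold_scores = rep(1, length(states)),
                   combine = "uniform", threshold = 0.5),
              class = "fold_ensemble")
  }
  # identical folds: the mean is the single model's probability
  e3 <- mk_ens(list(st, st, st))
  expect_equal(ensemble_predict(e3, x)$prob[[1]], single, tolerance = 1e-12)
  # a single-fold ensemble is that fold
  expect_equal(ensemble_predict(mk_ens(list(st)), x)$prob[[1]], single)

  # 3-vs-2 near-binary disagreement -> 0.6 -> on at threshold 0.5
  mk_sat <- function(sign) {
    s <- st
    s$params$final.w[] <- 0
    s$params$final.b[] <- sign * 30
    s
  }
  e5 <- mk_ens(c(replicate(3, mk_sat(1), simplify = FALSE),
                 replicate(2, mk_sat(-1), simplify = FALSE)))
  r <- ensemble_predict(e5, x)
  expect_equal(mean(r$prob[[1]]), 0.6, tolerance = 1e-8)
  expect_true(all(r$mask[[1]] == 1))
})

test_that("training improves the surface estimate across seeds (soft check)", {
  # reduced-scale surrogate: single fold fit, 8 epochs, 64x64 phantoms
  ok <- 0
  for (s in 1:3) {
    pairs <- make_phantom_pairs(48, size = 64L, seed = 10 + s,
                                empty_fraction = 0)
    cfg <- train_config(total_epochs = 8L, batch_size = 8L, n_folds = 2L,
                        seed = s,
                        schedule = loss_schedule(8L, warmup_epochs = 5L),
                        skel_params = soft_skeleton_params(6L),
                        model_cfg = unext_config(input_size = c(64L, 64L)),
                        augment = NULL)
    set.seed(s)
    fit <- train_fold(pairs[1:36], pairs[37:48], cfg)
    h <- fit$history$val_cl_dice
    if (max(h[6:8]) > h[1] && max(h) >= 0.5) ok <- ok + 1
  }
  expect_gte(ok, 2)
})
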