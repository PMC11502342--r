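test_that("analytic gradients match finite differences", {
  cfg <- train_config(base_channels = 2L, depth = 1L, seed = 7L)
  p <- withr::with_seed(7, octskin:::.unet_init(cfg))
  withr::with_seed(1, {
    img <- matrix(runif(64), 8, 8)
    y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  })
  lossfn <- function(pp) {
    fw <- octskin:::.unet_forward(img, pp, cfg)
    octskin:::.bce_with_logits(fw$logits, y)$loss
  }
  fw <- octskin:::.unet_forward(img, p, cfg)
  lg <- octskin:::.bce_with_logits(fw$logits, y)
  g <- octskin:::.unet_backward(lg$dlogits, fw, p, cfg)
  eps <- 1e-6
  withr::with_seed(3, {
    for (nm in names(p)) {
      k <- sample(seq_along(p[[nm]]), 1)
      p_hi <- p; p_hi[[nm]][k] <- p_hi[[nm]][k] + eps
      p_lo <- p; p_lo[[nm]][k] <- p_lo[[nm]][k] - eps
      num <- (lossfn(p_hi) - lossfn(p_lo)) / (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-4)
    }
  })
})

test_that("a duplicated pair is overfit to near-zero loss", {
  r <- render_volume(tiny_spec(n_slices = 1L, n_depth = 64L, n_lateral = 64L,
                               surface_depth_px = 20L, epidermis_thickness = 96,
                               seed = 3L))
  im <- r$volume$data[, , 1]; mk <- r$truth$true_mask[, , 1]
  cfg <- train_config(learning_rate = 0.01, epochs = 80, batch_size = 1L,
                      base_channels = 4L, depth = 1L, seed = 5L)
  mod <- train_neural(list(im, im), list(mk, mk), cfg)
  expect_lt(mod$loss_history[cfg$epochs], 0.05)
  expect_lt(mod$loss_history[cfg$epochs], mod$loss_history[1])
  pm <- predict_neural(mod, im)
  expect_gte(miou(pm$labels, mk), 99)
  expect_true(mask_is_contiguous(pm))
})

test_that("invalid training inputs are rejected", {
  im <- matrix(runif(64), 8, 8)
  expect_error(train_neural(list(im, im), list(im, im)), "not binary")
  mk <- matrix(0L, 8, 8)
  expect_error(train_neural(list(im, im), list(mk, matrix(0L, 4, 4))),
               "size")
  expect_error(train_neural(list(im), list(mk)), "length")
})

test_that("saved models reload bit-exactly", {
  r <- render_volume(tiny_spec(n_slices = 1L, n_depth = 64L, n_lateral = 64L,
                               surface_depth_px = 20L, epidermis_thickness = 96,
                               seed = 8L))
  im <- r$volume$data[, , 1]; mk <- r$truth$true_mask[, , 1]
  cfg <- train_config(learning_rate = 0.01, epochs = 5, batch_size = 1L,
                      base_channels = 2L, depth = 1L, seed = 6L)
  mod <- train_neural(list(im, im), list(mk, mk), cfg)
  path <- withr::local_tempfile()
  save_neural(mod, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_neural(path)
  expect_identical(back$params, mod$params)
  expect_identical(predict_neural(back, im)$labels,
                   predict_neural(mod, im)$labels)
})

test_that("grouped splits never mix one volume across train and test", {
  groups <- rep(1:10, each = 8)
  sp <- split_train_test(groups, 0.9, seed = 11)
  expect_length(intersect(unique(groups[sp$train]), unique(groups[sp$test])), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(groups))
  expect_equal(length(unique(groups[sp$test])), 1)
})
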