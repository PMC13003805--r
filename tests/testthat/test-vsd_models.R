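# A tiny analytic signal family stands in for full GESFIDE simulation in the
# training smoke tests: s(te) = exp(-(a + b te) te) with (a, b) tied to the
# CBV and radius labels, so the mapping signal -> labels is learnable at
# desk scale.
toy_dataset <- function(n, seed = 1) {
  set.seed(seed)
  te <- seq(0.01, 0.18, by = 0.01)
  cbv <- runif(n, 0.01, 0.40)
  radius <- runif(n, 2, 15)
  signals <- t(vapply(seq_len(n), function(i) {
    exp(-(40 * cbv[i] + 2 * radius[i] * te) * te)
  }, numeric(18)))
  vsd <- matrix(0, n, 40)
  for (i in seq_len(n)) {
    b <- floor(radius[i]) + 1
    vsd[i, b] <- 1
    if (b < 40) vsd[i, b + 1] <- 0.5
  }
  list(signals = signals, cbv = cbv, vsd = vsd)
}

test_that("CBV filtering keeps only VOIs within the inclusion bounds", {
  sig <- matrix(runif(4 * 18), 4)
  cbv <- c(0.005, 0.05, 0.41, 0.20)
  ds <- filter_and_split(sig, cbv, matrix(1, 4, 40), seed = 1,
                         ratios = c(1, 1, 0))
  expect_equal(sort(ds$cbv_labels), c(0.05, 0.20))
  expect_equal(ds$provenance$n_removed, 2)
})

test_that("split sizes follow the floor / floor / remainder rule", {
  # 32,000 VOIs with 680 out of bounds -> 31,320 kept -> 25,056/3,132/3,132
  n <- 32000
  cbv <- rep(0.1, n)
  cbv[seq_len(680)] <- 0.005
  sig <- matrix(0.5, n, 18)
  sig[, 1] <- runif(n)
  ds <- filter_and_split(sig, cbv, NULL, seed = 42)
  expect_equal(as.integer(table(ds$partition)), c(25056, 3132, 3132))
  # same seed gives the identical partition
  ds2 <- filter_and_split(sig, cbv, NULL, seed = 42)
  expect_identical(ds$partition, ds2$partition)
  expect_error(filter_and_split(sig, rep(0.005, n), NULL), "no VOIs")
})

test_that("two-stage training fits a toy family and honours its contracts", {
  toy <- toy_dataset(1500, seed = 3)
  ds <- filter_and_split(toy$signals, toy$cbv, toy$vsd, seed = 3)
  spec <- model_spec(cbve_hidden = c(64, 32), vsde_hidden = c(64, 32),
                     lr = 1e-3, max_epochs = 200L, patience = 40L,
                     batch_size = 128L)
  models <- train_two_stage(ds, spec, seed = 5)
  h <- models$training_history
  # validation MSE drops by at least 10x from the first epoch
  expect_lt(min(h$cbve$val), h$cbve$val[1] / 10)
  expect_lt(min(h$vsde$val), h$vsde$val[1] / 2)
  # determinism: same data, spec and seed -> identical history
  models2 <- train_two_stage(ds, spec, seed = 5)
  expect_identical(h$cbve, models2$training_history$cbve)
  expect_identical(models$cbve$layers, models2$cbve$layers)
  # prediction ranges: CBV rectified, VSD logistic
  te <- vsdmri:::ds_part(ds, "test")
  pred <- predict(models, te$X)
  expect_true(all(pred$cbv >= 0))
  expect_true(all(pred$vsd > 0 & pred$vsd < 1))
  expect_equal(dim(pred$vsd), c(nrow(te$X), 40))
  # recovered CBV correlates strongly on held-out data
  expect_gt(pearson(te$cbv, pred$cbv), 0.9)
  # wrong input width is rejected
  expect_error(predict(models, matrix(0.5, 2, 7)), "signal values")
})

test_that("stage 2 leaves the frozen CBVE weights byte-identical", {
  toy <- toy_dataset(400, seed = 9)
  ds <- filter_and_split(toy$signals, toy$cbv, toy$vsd, seed = 9)
  spec <- model_spec(cbve_hidden = c(32, 16), vsde_hidden = c(32, 16),
                     lr = 1e-3, max_epochs = 15L, batch_size = 64L)
  models <- train_two_stage(ds, spec, seed = 2)
  # retrain stage 1 alone with the identical seed stream: the CBVE inside
  # the pair must match, proving stage 2 never touched it
  ref <- with(vsdmri:::ds_part(ds, "train"), NULL)
  tr <- vsdmri:::ds_part(ds, "train"); va <- vsdmri:::ds_part(ds, "val")
  cbve_alone <- vsdmri:::with_seed(2, {
    net <- vsdmri:::mlp_init(c(18, 32, 16, 1), "relu")
    net$layers[[length(net$layers)]]$b[] <- mean(tr$cbv)
    vsdmri:::mlp_train(net, tr$X, matrix(tr$cbv, ncol = 1),
                       va$X, matrix(va$cbv, ncol = 1), spec)$net
  })
  expect_identical(models$cbve$layers, cbve_alone$layers)
})

test_that("prediction is bit-stable for fixed weights and input", {
  toy <- toy_dataset(200, seed = 4)
  ds <- filter_and_split(toy$signals, toy$cbv, toy$vsd, seed = 4)
  spec <- model_spec(cbve_hidden = c(16, 8), vsde_hidden = c(16, 8),
                     max_epochs = 3L, batch_size = 64L)
  models <- train_two_stage(ds, spec, seed = 1)
  x <- toy$signals[7, ]
  p1 <- predict(models, x)
  p2 <- predict(models, x)
  expect_identical(p1, p2)
})

test_that("checkpoints round-trip through save and load", {
  toy <- toy_dataset(200, seed = 6)
  ds <- filter_and_split(toy$signals, toy$cbv, toy$vsd, seed = 6)
  spec <- model_spec(cbve_hidden = c(16, 8), vsde_hidden = c(16, 8),
                     max_epochs = 2L, batch_size = 64L)
  models <- train_two_stage(ds, spec, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_model_pair(models, path)
  expect_true(file.exists(paste0(path, ".json")))
  restored <- load_model_pair(path)
  expect_identical(predict(models, toy$signals[1, ]),
                   predict(restored, toy$signals[1, ]))
  unlink(c(path, paste0(path, ".json")))
})

test_that("the full-width architecture builds with its stated layer sizes", {
  spec <- model_spec()
  expect_equal(spec$cbve_hidden, c(2048, 1024, 512, 256, 128, 64, 16, 8))
  expect_equal(spec$vsde_hidden, c(2048, 1024, 512, 256, 128, 64))
  set.seed(1)
  cbve <- vsdmri:::mlp_init(c(18, spec$cbve_hidden, 1), "relu")
  vsde <- vsdmri:::mlp_init(c(19, spec$vsde_hidden, 40), "sigmoid")
  expect_equal(nrow(cbve$layers[[1]]$W), 18)
  expect_equal(ncol(cbve$layers[[length(cbve$layers)]]$W), 1)
  expect_equal(nrow(vsde$layers[[1]]$W), 19)
  expect_equal(ncol(vsde$layers[[length(vsde$layers)]]$W), 40)
})
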