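test_that("cross entropy matches its closed forms", {
  # perfect one-hot prediction -> 0
  lab <- array(sample(0:3, 64, TRUE), c(8, 8, 1))
  pred <- array(0, c(8, 8, 4, 1))
  for (k in 0:3) pred[, , k + 1, 1] <- lab[, , 1] == k
  expect_equal(cross_entropy_loss(pred, lab)$loss, 0)
  # uniform prediction, K = 4 -> ln 4
  unif <- array(0.25, c(8, 8, 4, 1))
  expect_equal(cross_entropy_loss(unif, lab)$loss, log(4), tolerance = 1e-12)
  expect_identical(cross_entropy_loss(unif, lab)$n_pixels, 64L)
})

test_that("ignore masking equals the pixel-subset oracle", {
  set.seed(10)
  scheme <- label_scheme("sa")
  lab <- array(sample(0:3, 16 * 16, TRUE), c(16, 16, 1))
  logits <- array(rnorm(16 * 16 * 4), c(16 * 16, 4))
  pred_mat <- exp(logits) / rowSums(exp(logits))
  pred <- array(0, c(16, 16, 4, 1))
  pred[, , , 1] <- array(pred_mat, c(16, 16, 4))
  masked <- cross_entropy_loss(pred, lab, scheme = scheme, ignore = "RV cavity")
  # oracle: delete RV pixels outright and recompute on the subset
  keep <- as.vector(lab) != 3L
  sub_loss <- -mean(log(pred_mat[cbind(which(keep), as.vector(lab)[keep] + 1L)]))
  expect_equal(masked$loss, sub_loss, tolerance = 1e-12)
  expect_identical(masked$n_pixels, sum(keep))
  all_rv <- array(3L, c(16, 16, 1))
  expect_error(cross_entropy_loss(pred, all_rv, scheme = scheme,
                                  ignore = "RV cavity"), "contributing")
})

test_that("augmentation identity, exact rotation and label closure", {
  set.seed(11)
  img <- array(runif(32 * 32 * 2), c(32, 32, 2))
  lab <- array(sample(0:3, 32 * 32 * 2, TRUE), c(32, 32, 2))
  zero_cfg <- train_config(translation_px = 0, rotation_deg = 0,
                           scale_range = c(1, 1), intensity_scale = c(1, 1),
                           intensity_offset = 0)
  out <- augment_batch(img, lab, zero_cfg)
  expect_identical(out$images, img)
  expect_identical(out$labels, lab)
  # exact 90-degree rotation permutes the grid: pixel count preserved
  sq <- matrix(0L, 32, 32); sq[5:12, 20:29] <- 1L
  rot <- cineseg:::.affine_resample(sq, pi / 2, 1, 0, 0, nearest = TRUE)
  expect_identical(sum(rot), sum(sq))
  expect_identical(sort(unique(as.vector(rot))), sort(unique(as.vector(sq))))
  # rotating back recovers the original
  back <- cineseg:::.affine_resample(rot, -pi / 2, 1, 0, 0, nearest = TRUE)
  expect_identical(back, sq)
  # arbitrary augmentation keeps labels in the scheme alphabet, images in [0,1]
  wild <- augment_batch(img, lab, train_config())
  expect_true(all(wild$labels %in% 0:3))
  expect_true(all(wild$images >= 0 & wild$images <= 1))
})

test_that("train with zero learning rate or zero iterations is a no-op", {
  case <- generate_phantom(small_phantom_params(frames = 2L))
  net <- tiny_net(seed = 20)
  r0 <- train(net, list(case), train_config(iterations = 0, seed = 1))
  expect_identical(r0$net$par, net$par)
  rlr <- train(net, list(case),
               train_config(iterations = 3, learning_rate = 0,
                            batch_size = 2, augment = FALSE, seed = 1))
  expect_equal(rlr$net$par, net$par, tolerance = 1e-12)
  expect_length(rlr$history, 3)
})

test_that("a short training run reduces the loss", {
  case <- generate_phantom(small_phantom_params(frames = 4L))
  net <- tiny_net(seed = 21)
  cfg <- train_config(iterations = 60, batch_size = 4, augment = FALSE, seed = 3)
  r <- train(net, list(case), cfg)
  expect_lt(mean(tail(r$history, 5)), mean(head(r$history, 5)))
  expect_true(all(is.finite(r$history)))
})

test_that("training is deterministic given the seed", {
  case <- generate_phantom(small_phantom_params(frames = 2L))
  cfg <- train_config(iterations = 5, batch_size = 2, seed = 7)
  r1 <- train(tiny_net(seed = 22), list(case), cfg)
  r2 <- train(tiny_net(seed = 22), list(case), cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$net$par, r2$net$par)
})

test_that("fine-tuning rebuilds the head and freezes nothing else", {
  case <- generate_phantom(small_phantom_params(frames = 2L))
  net <- tiny_net(seed = 23)                            # K = 4 short-axis net
  # zero-iteration fine-tune: head rebuilt to 3 features, body untouched
  cfg0 <- train_config(fine_tune_iterations = 0, seed = 1)
  r0 <- fine_tune(net, list(case), label_scheme("sa_lv"), cfg0)
  expect_identical(ncol(r0$net$par$h3_W), 3L)
  body_names <- setdiff(names(net$par), c("h3_W", "h3_bias"))
  expect_identical(r0$net$par[body_names], net$par[body_names])
  # default schedule length is 10,000 iterations
  expect_identical(train_config()$fine_tune_iterations, 10000L)
  # a short fine-tune actually trains with RV pixels ignored
  cfg <- train_config(fine_tune_iterations = 8, batch_size = 2,
                      augment = FALSE, seed = 2)
  r <- fine_tune(net, list(case), label_scheme("sa_lv"), cfg)
  expect_length(r$history, 8)
  expect_true(all(is.finite(r$history)))
  expect_identical(r$net$spec$K, 3L)
})

test_that("loss is invariant to pixel permutation and slice duplication", {
  set.seed(12)
  lab <- array(sample(0:1, 64, TRUE), c(8, 8, 1))
  pred <- array(runif(8 * 8 * 2), c(8, 8, 2, 1))
  s <- array(rep(apply(pred, c(1, 2, 4), sum), 2), c(8, 8, 1, 2))
  pred <- pred / aperm(s, c(1, 2, 4, 3))
  base <- cross_entropy_loss(pred, lab)$loss
  dup_pred <- array(0, c(8, 8, 2, 2)); dup_pred[, , , 1] <- pred[, , , 1]
  dup_pred[, , , 2] <- pred[, , , 1]
  dup_lab <- array(lab, c(8, 8, 2))
  expect_equal(cross_entropy_loss(dup_pred, dup_lab)$loss, base, tolerance = 1e-12)
})
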