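test_that("dice loss matches the smoothed formula on known configurations", {
  a <- matrix(0, 20, 20)
  b <- matrix(0, 20, 20)
  a[1:10, 1:10] <- 1 # area 100
  # identical masks: loss bounded by the smoothing term
  expect_lte(dice_loss(a, a), 1 / (2 * 100 + 1))
  # disjoint masks of area 100 each
  b[11:20, 11:20] <- 1
  expect_equal(dice_loss(a, b), 1 - 1 / 201)
  # half overlap |A| = |B| = 100, |A n B| = 50
  c <- matrix(0, 20, 20)
  c[6:15, 1:10] <- 1
  expect_equal(dice_loss(a, c), 1 - 101 / 201)
  expect_equal(dice_loss(a, c), 0.5, tolerance = 0.01)
  expect_error(dice_loss(a, matrix(0, 10, 10)),
               class = "myoinvade_shape_error")
})

test_that("IoU matches set arithmetic and handles the empty case", {
  a <- matrix(0, 20, 20)
  a[1:10, 1:10] <- 1
  expect_equal(iou(a, a), 1)
  b <- matrix(0, 20, 20)
  b[11:20, 11:20] <- 1
  expect_equal(iou(a, b), 0)
  c <- matrix(0, 20, 20)
  c[6:15, 1:10] <- 1
  expect_equal(iou(a, c), 50 / 150)
  z <- matrix(0, 20, 20)
  expect_equal(iou(z, z), 1)
})

test_that("IoU and Dice satisfy the algebraic identity IoU = D / (2 - D)", {
  set.seed(42)
  for (k in 1:25) {
    a <- random_mask(16, stats::runif(1, 0.2, 0.7))
    b <- random_mask(16, stats::runif(1, 0.2, 0.7))
    d <- dice_coefficient(a, b)
    i <- iou(a, b)
    expect_equal(i, d / (2 - d), tolerance = 1e-12)
    expect_equal(i, iou(b, a)) # symmetry
    expect_true(i >= 0 && i <= 1 && d >= 0 && d <= 1)
    expect_lte(i, d)
  }
})

test_that("soft dice loss stays in [0, 1) for probability maps", {
  set.seed(7)
  for (k in 1:10) {
    p <- matrix(stats::runif(64), 8)
    t <- random_mask(8, 0.5)
    l <- dice_loss(p, t)
    expect_gte(l, 0)
    expect_lt(l, 1)
  }
})

test_that("all encoder families build and honour the shape contract", {
  x <- matrix(stats::rnorm(64 * 64), 64 * 64, 1)
  for (fam in c("tiny", "vgg11-like", "vgg16-like", "resnet34-like")) {
    m <- build_model(model_spec(fam), seed = 2)
    out <- myoinvade:::unet_forward(m, x, 64, 64)
    expect_identical(dim(out$logits), c(64L * 64L, 2L))
  }
  expect_lt(myoinvade:::n_parameters(build_model(model_spec("tiny"))), 5e5)
  expect_error(model_spec("alexnet"))
  expect_error(model_spec("tiny", pretrained = TRUE), "pretrained")
})

test_that("weight initialization is reproducible given the seed", {
  m1 <- build_model(model_spec("tiny"), seed = 9)
  m2 <- build_model(model_spec("tiny"), seed = 9)
  m3 <- build_model(model_spec("tiny"), seed = 10)
  expect_identical(m1$layers, m2$layers)
  expect_false(identical(m1$layers, m3$layers))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(5)
  m <- build_model(model_spec("tiny", base_channels = 4, depth = 2), seed = 3)
  x <- matrix(stats::rnorm(256), 256, 1)
  t <- cbind(as.vector(random_mask(16, 0.5)), as.vector(random_mask(16, 0.3)))
  fwd <- myoinvade:::unet_forward(m, x, 16, 16, keep_cache = TRUE)
  lg <- myoinvade:::dice_loss_grad(fwd$logits, t)
  g <- myoinvade:::unet_backward(m, fwd, lg$dlogits)
  eps <- 1e-6
  for (nm in sample(names(m$layers), 4)) {
    k <- sample(length(m$layers[[nm]]$W), 1)
    m2 <- m
    m2$layers[[nm]]$W[k] <- m2$layers[[nm]]$W[k] + eps
    f2 <- myoinvade:::unet_forward(m2, x, 16, 16)
    num <- (myoinvade:::dice_loss_grad(f2$logits, t)$loss - lg$loss) / eps
    expect_equal(g[[nm]]$W[k], num, tolerance = 1e-3)
  }
})

test_that("zero-epoch training returns the initialized model unchanged", {
  m <- build_model(model_spec("tiny", base_channels = 4, depth = 2), seed = 1)
  tr <- train_model(m, list(), list(), train_config(epochs = 0))
  expect_identical(tr$model$layers, m$layers)
  expect_identical(nrow(tr$history), 0L)
})

test_that("training reduces the Dice loss and checkpoints the best epoch", {
  set.seed(8)
  co <- generate_cohort(cohort_spec(n_cases = 10, canvas_size = 64,
                                    noise_sd = 0.03, seed = 77))
  samples <- prepare_cases(co)
  m <- build_model(model_spec("tiny"), seed = 5)
  tr <- train_model(m, samples[1:8], samples[9:10],
                    train_config(batch_size = 4, learning_rate = 0.05,
                                 epochs = 4, seed = 5))
  h <- tr$history
  expect_identical(nrow(h), 4L)
  expect_lt(h$train_loss[4], h$train_loss[1])
  expect_identical(tr$best_epoch, which.min(h$val_loss))
})

test_that("non-finite losses abort with a divergence diagnostic", {
  m <- build_model(model_spec("tiny", base_channels = 4, depth = 2), seed = 1)
  bad <- list(list(x = matrix(NaN, 256, 1),
                   t = cbind(rep(1, 256), rep(0, 256)), H = 16L, W = 16L))
  expect_error(
    train_model(m, bad, bad, train_config(epochs = 1, batch_size = 1)),
    class = "myoinvade_divergence_error"
  )
})

test_that("a model fitted to saturation segments its own phantom", {
  cs <- generate_phantom(phantom_params(
    canvas_size = 64, target_fraction = 0.4, lesion_center_angle = 1,
    noise_sd = 0.03, seed = 12
  ))
  samples <- prepare_cases(list(cs))
  m <- build_model(model_spec("tiny"), seed = 6)
  tr <- train_model(m, samples, samples,
                    train_config(batch_size = 1, learning_rate = 0.05,
                                 epochs = 100, seed = 6))
  out <- predict_masks(tr, standardize(cs$images$T1c), cs$case_id)
  expect_gt(iou(out$masks$uterus, cs$uterus_mask), 0.9)
  # containment enforced post hoc
  expect_true(all(out$masks$lesion <= out$masks$uterus))
})

test_that("empty probability maps yield flagged empty masks", {
  m <- build_model(model_spec("tiny", base_channels = 4, depth = 2), seed = 1)
  # force the head towards zero probability everywhere
  head_nm <- names(m$layers)[length(m$layers)]
  m$layers[[head_nm]]$W[] <- 0
  m$layers[[head_nm]]$b[] <- -50
  out <- predict_masks(m, matrix(stats::rnorm(32 * 32), 32), "c1")
  expect_identical(sum(out$masks$uterus), 0)
  expect_true("empty_uterus" %in% out$flags)
})
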