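test_that("standardization matches the hand-computed transform", {
  x <- matrix(c(0, 1, 2, 3), 2)
  s <- standardize(x)
  expect_equal(attr(s, "p_mean"), 1.5)
  expect_equal(attr(s, "p_std"), sqrt(1.25))
  expect_equal(sort(as.vector(s)),
               c(-1.3416408, -0.4472136, 0.4472136, 1.3416408),
               tolerance = 1e-6)
})

test_that("standardization yields mean 0 / sd 1 and is idempotent", {
  set.seed(1)
  img <- matrix(stats::runif(64 * 64, 10, 200), 64)
  s <- standardize(img)
  expect_lt(abs(mean(s)), 1e-6)
  expect_lt(abs(sqrt(mean((s - mean(s))^2)) - 1), 1e-6)
  s2 <- standardize(s)
  expect_lt(max(abs(s2 - s)), 1e-6)
})

test_that("constant images are rejected as degenerate", {
  expect_error(standardize(matrix(5, 10, 10)),
               class = "myoinvade_degenerate_error")
})

test_that("crop_resize takes the centered square window", {
  img <- matrix(stats::rnorm(1024 * 896), 1024, 896)
  out <- crop_resize(img, 896)
  expect_identical(dim(out), c(896L, 896L))
  expect_identical(out, img[64 + seq_len(896), ])

  sq <- matrix(stats::rnorm(64 * 64), 64)
  expect_identical(crop_resize(sq, 64), sq)
  expect_error(crop_resize(sq, 4))
})

test_that("mask resampling is nearest-neighbour and stays binary", {
  set.seed(2)
  m <- circle_mask(64, 30, 34, 18)
  out <- crop_resize(m, 48, kind = "mask")
  expect_true(all(out %in% c(0, 1)))
  up <- crop_resize(m, 128, kind = "mask")
  expect_true(all(up %in% c(0, 1)))
})

test_that("flip augmentation is an involution and preserves masks", {
  set.seed(3)
  img <- matrix(stats::rnorm(32 * 32), 32)
  m <- circle_mask(32, 15, 18, 8)
  a <- augment(img, m, plan = "flips", seed = 9)
  expect_identical(nrow(a), 3L)
  expect_identical(a$provenance, c("original", "augmented", "augmented"))
  h <- a$image[[which(a$transform == "hflip")]]
  expect_identical(h[, rev(seq_len(ncol(h)))], img)
  for (mm in a$mask) {
    expect_true(all(mm %in% c(0, 1)))
    expect_identical(myoinvade:::n_components(mm), 1L)
  }
})

test_that("affine augmentation is reproducible by seed", {
  img <- matrix(stats::rnorm(32 * 32), 32)
  m <- circle_mask(32, 15, 18, 8)
  a1 <- augment(img, m, seed = 5)
  a2 <- augment(img, m, seed = 5)
  a3 <- augment(img, m, seed = 6)
  p1 <- a1$params[[which(a1$transform == "affine_1")]]
  p2 <- a2$params[[which(a2$transform == "affine_1")]]
  p3 <- a3$params[[which(a3$transform == "affine_1")]]
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_identical(a1$image, a2$image)
  # the sampled affine parameters stay inside the advertised ranges
  expect_lte(abs(p1$angle), 15)
  expect_true(p1$scale >= 0.9 && p1$scale <= 1.1)
})

test_that("augmenting mismatched shapes fails", {
  expect_error(
    augment(matrix(0, 8, 8), matrix(0, 8, 9), seed = 1),
    class = "myoinvade_shape_error"
  )
})

test_that("cohort splitting reproduces the study design sizes", {
  truth <- tibble::tibble(
    case_id = sprintf("c%02d", 1:72),
    true_stage = rep(c("IA", "IB"), c(53, 19))
  )
  sp <- split_cohort(truth, seed = 5)
  expect_identical(sum(sp$split == "train"), 24L)
  expect_identical(sum(sp$split == "validation"), 6L)
  expect_identical(sum(sp$split == "test"), 42L)
  expect_identical(sum(sp$in_evaluation), 48L) # validation + test pool
  strict <- split_cohort(truth, seed = 5, evaluation = "strict")
  expect_identical(sum(strict$in_evaluation), 42L)

  small <- split_cohort(tibble::tibble(case_id = letters[1:9]),
                        train_fraction = 1 / 3, val_count = 1, seed = 1)
  expect_identical(
    as.integer(table(small$split)[c("train", "validation", "test")]),
    c(3L, 1L, 5L)
  )
})

test_that("stratified splits preserve stage proportions within one case", {
  truth <- tibble::tibble(
    case_id = sprintf("c%02d", 1:72),
    true_stage = rep(c("IA", "IB"), c(53, 19))
  )
  for (seed in 1:4) {
    sp <- split_cohort(truth, seed = seed)
    tab <- table(sp$split, truth$true_stage)
    for (grp in rownames(tab)) {
      n_grp <- sum(tab[grp, ])
      expect_lte(abs(tab[grp, "IB"] - n_grp * 19 / 72), 1)
    }
    expect_setequal(sp$case_id, truth$case_id)
  }
})

test_that("splits too small for the requested counts are rejected", {
  expect_error(
    split_cohort(tibble::tibble(case_id = letters[1:5]), val_count = 6),
    "too small"
  )
})
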