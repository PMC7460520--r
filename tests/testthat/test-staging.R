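test_that("ray profiles recover analytic circle geometry", {
  ut <- circle_mask(64, 32.5, 32.5, 30)
  le <- circle_mask(64, 32.5, 32.5, 10)
  pr <- ray_profile(ut, le, n_rays = 360)
  expect_true(all(pr$valid))
  expect_true(all(abs(pr$r_lesion - 10) <= 1))
  expect_true(all(abs(pr$r_serosa - 30) <= 1))

  # order-0 fit gives a constant junction near the cavity radius
  rj <- estimate_junction(pr, fit_order = 0)
  expect_lt(stats::sd(rj), 1e-9)
  expect_lt(abs(mean(rj) - 10), 1)

  est <- invasion_fraction(pr, rj)
  expect_lt(est$fraction, 0.05)
})

test_that("profile preconditions are enforced", {
  ut <- circle_mask(64, 32.5, 32.5, 20)
  outside <- circle_mask(64, 10, 55, 6)
  expect_error(ray_profile(ut, outside),
               class = "myoinvade_containment_error")
  expect_error(ray_profile(ut, matrix(0, 64, 64)),
               class = "myoinvade_empty_mask_error")
  expect_error(ray_profile(ut, circle_mask(32, 16, 16, 4)),
               class = "myoinvade_shape_error")
})

test_that("junction fit tracks the baseline and ignores the protrusion", {
  # no invasion: the fit should ride the lesion boundary everywhere
  cs0 <- generate_phantom(phantom_params(target_fraction = 0, seed = 13,
                                         lesion_center_angle = 0))
  pr0 <- ray_profile(cs0$uterus_mask, cs0$lesion_mask)
  rj0 <- estimate_junction(pr0)
  ok <- pr0$valid
  expect_lte(max(abs(rj0[ok] - pr0$r_lesion[ok])), 1.5)

  # 60-degree protrusion: outside the sector the lesion boundary IS the
  # baseline junction, and the fit must ride it despite the protrusion
  cs <- generate_phantom(phantom_params(
    target_fraction = 0.6, lesion_angular_extent = pi / 3,
    lesion_center_angle = 0.8, seed = 13
  ))
  pr <- ray_profile(cs$uterus_mask, cs$lesion_mask)
  rj <- estimate_junction(pr)
  outside <- abs(myoinvade:::wrap_angle(pr$theta - 0.8)) > pi / 3
  dev <- abs(rj - pr$r_lesion)[outside & pr$valid]
  expect_lte(max(dev), 2)
  # and inside the sector the fit stays well below the lesion boundary
  inside <- abs(myoinvade:::wrap_angle(pr$theta - 0.8)) < pi / 12
  expect_gt(max((pr$r_lesion - rj)[inside]), 3)
})

test_that("junction fit demands enough valid rays", {
  ut <- circle_mask(64, 32.5, 32.5, 25)
  le <- circle_mask(64, 32.5, 32.5, 8)
  pr <- ray_profile(ut, le, n_rays = 10)
  expect_error(estimate_junction(pr, fit_order = 3), "too few valid rays")
})

test_that("invasion fractions recover phantom ground truth", {
  cs <- generate_phantom(phantom_params(target_fraction = 0.75, seed = 19,
                                        lesion_center_angle = -1.2))
  est <- estimate_invasion(cs$uterus_mask, cs$lesion_mask)
  expect_lt(abs(est$fraction - cs$truth$true_fraction), 0.05)

  # full-thickness invasion reaches the serosa
  cs1 <- generate_phantom(phantom_params(target_fraction = 1, seed = 19,
                                         lesion_center_angle = -1.2))
  est1 <- estimate_invasion(cs1$uterus_mask, cs1$lesion_mask)
  expect_gte(est1$fraction, 0.95)
  expect_lte(est1$fraction, 1)
})

test_that("degenerate profiles are rejected", {
  ut <- circle_mask(64, 32.5, 32.5, 12)
  le <- circle_mask(64, 32.5, 32.5, 11)
  pr <- ray_profile(ut, le)
  # junction pinned at the serosa leaves no measurable thickness
  expect_error(invasion_fraction(pr, pr$r_serosa),
               class = "myoinvade_degenerate_error")
})

test_that("staging rule is max-over-slices with an inclusive 50% cutoff", {
  expect_identical(stage_case(c(0.1, 0.48))$stage, "IA")
  expect_identical(stage_case(c(0.1, 0.50))$stage, "IB")
  expect_identical(stage_case(0)$stage, "IA")
  expect_equal(stage_case(c(0.2, 0.7, 0.4))$fraction, 0.7)
  expect_error(stage_case(numeric(0)))
})

test_that("radially enlarging the lesion never decreases the fraction", {
  set.seed(23)
  for (s in 1:4) {
    cs <- generate_phantom(phantom_params(
      target_fraction = stats::runif(1, 0.2, 0.7), seed = s + 100,
      lesion_center_angle = stats::runif(1, -pi, pi)
    ))
    pr <- ray_profile(cs$uterus_mask, cs$lesion_mask)
    rj <- estimate_junction(pr)
    f0 <- invasion_fraction(pr, rj)$fraction
    grown <- myoinvade:::largest_component(
      EBImage::dilate(cs$lesion_mask, EBImage::makeBrush(3, "box")) *
        cs$uterus_mask
    )
    pr1 <- ray_profile(cs$uterus_mask, grown)
    # same junction baseline: monotone exactly
    f1 <- invasion_fraction(pr1, rj)$fraction
    expect_gte(f1, f0)
    # full re-estimation: monotone up to the fit's resolution
    f2 <- estimate_invasion(cs$uterus_mask, grown)$fraction
    expect_gte(f2, f0 - 0.01)
  }
})

test_that("estimates are equivariant under 90-degree rotation", {
  cs <- generate_phantom(phantom_params(target_fraction = 0.55, seed = 29,
                                        lesion_center_angle = 0.3))
  f0 <- estimate_invasion(cs$uterus_mask, cs$lesion_mask)$fraction
  f90 <- estimate_invasion(rotate90(cs$uterus_mask),
                           rotate90(cs$lesion_mask))$fraction
  expect_lte(abs(f90 - f0), 0.02)
})

test_that("stage_cohort flags unusable mask pairs instead of failing", {
  co <- generate_cohort(cohort_spec(n_cases = 2, seed = 3))
  preds <- list(
    case_001 = list(masks = list(uterus = co[[1]]$uterus_mask,
                                 lesion = co[[1]]$lesion_mask),
                    flags = character(0)),
    case_002 = list(masks = list(uterus = matrix(0, 128, 128),
                                 lesion = matrix(0, 128, 128)),
                    flags = "empty_uterus")
  )
  st <- stage_cohort(co, masks = preds)
  expect_false(is.na(st$fraction[1]))
  expect_true(is.na(st$fraction[2]))
  expect_match(st$flag[2], "empty_mask")
})
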