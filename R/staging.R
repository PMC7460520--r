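#' Radial profile of uterus and lesion masks
#'
#' Casts `n_rays` uniformly spaced rays from the lesion's central core (the
#' centroid of its erosion-stable interior) and records, per angle, the
#' outermost uterus crossing (`r_serosa`) and the outermost lesion crossing
#' (`r_lesion`). Rays that never cross the uterus are marked invalid. These
#' radial curves are the measurement geometry from which invasion depth is
#' defined.
#'
#' @param uterus_mask,lesion_mask Congruent binary matrices; the lesion must
#'   lie inside the uterus and both must be non-empty.
#' @param n_rays Number of uniformly spaced ray angles (default 720).
#' @param r_step Radial sampling step in pixels.
#' @return A `ray_profile` tibble with columns `theta`, `r_serosa`,
#'   `r_lesion`, `valid`, and attributes `origin` and `n_rays`.
#' @export
ray_profile <- function(uterus_mask, lesion_mask, n_rays = 720,
                        r_step = 0.25) {
  assert_same_shape(uterus_mask, lesion_mask, "uterus mask", "lesion mask")
  assert_binary_mask(uterus_mask, "uterus mask")
  assert_binary_mask(lesion_mask, "lesion mask")
  if (sum(uterus_mask) == 0 || sum(lesion_mask) == 0) {
    abort_myo("masks must be non-empty", class = "myoinvade_empty_mask_error")
  }
  if (any(lesion_mask > uterus_mask)) {
    abort_myo("lesion mask is not contained in the uterus mask",
              class = "myoinvade_containment_error")
  }

  origin <- lesion_core_centroid(lesion_mask)
  oi <- origin[1]
  oj <- origin[2]
  if (uterus_mask[round(oi), round(oj)] != 1) {
    abort_myo("ray origin falls outside the uterus mask",
              class = "myoinvade_containment_error")
  }

  h <- nrow(uterus_mask)
  w <- ncol(uterus_mask)
  theta <- seq(-pi, pi, length.out = n_rays + 1L)[-1L]
  rmax <- sqrt(h^2 + w^2)
  radii <- seq(0, rmax, by = r_step)

  # Sample both masks on the polar grid by nearest-neighbour lookup.
  ii <- round(outer(sin(theta), radii) + oi) # rows: y grows downward
  jj <- round(outer(cos(theta), radii) + oj)
  inside <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
  lin <- (pmax(pmin(jj, w), 1) - 1) * h + pmax(pmin(ii, h), 1)
  ut <- matrix(uterus_mask[lin], n_rays) * inside
  le <- matrix(lesion_mask[lin], n_rays) * inside

  outermost <- function(hits) {
    idx <- max.col(hits * rep(seq_along(radii), each = n_rays),
                   ties.method = "last")
    r <- radii[idx]
    r[rowSums(hits) == 0] <- 0
    r
  }
  r_serosa <- outermost(ut)
  r_lesion <- outermost(le)
  valid <- rowSums(ut) > 0

  out <- tibble::tibble(
    theta = theta, r_serosa = r_serosa, r_lesion = r_lesion, valid = valid
  )
  class(out) <- c("ray_profile", class(out))
  attr(out, "origin") <- origin
  attr(out, "n_rays") <- n_rays
  out
}

# Centroid (row, col) of the erosion-stable interior of a mask.
lesion_core_centroid <- function(mask) {
  core <- mask
  kern <- EBImage::makeBrush(3, shape = "box")
  repeat {
    nxt <- EBImage::erode(core, kern)
    if (sum(nxt) < 25) break
    core <- nxt
  }
  idx <- which(core == 1, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

#' Estimate the pre-invasion endomyometrial junction
#'
#' Fits a low-order trigonometric curve to the lesion's outer radius with
#' iterative down-weighting of positive residuals, so the fit tracks the
#' smooth non-invaded baseline while the lesion protrusion is treated as an
#' outlier. The estimate is clipped to `[0, r_serosa]`.
#'
#' @param profile A [ray_profile()].
#' @param fit_order Trigonometric order of the fit (0-3).
#' @param n_iter Reweighting iterations.
#' @return Numeric vector `r_junction_hat` aligned with `profile$theta`.
#' @export
estimate_junction <- function(profile, fit_order = 3, n_iter = 10) {
  stopifnot(inherits(profile, "ray_profile"))
  if (fit_order < 0 || fit_order > 3) abort_myo("fit_order must be 0-3")
  ok <- profile$valid & profile$r_lesion > 0
  need <- 2 * (2 * fit_order + 1)
  if (sum(ok) < need) {
    abort_myo(sprintf(
      "too few valid rays (%d) for a trigonometric fit of order %d (need %d)",
      sum(ok), fit_order, need
    ))
  }
  basis <- function(theta) {
    X <- matrix(1, length(theta), 1)
    for (k in seq_len(fit_order)) {
      X <- cbind(X, cos(k * theta), sin(k * theta))
    }
    X
  }
  X <- basis(profile$theta[ok])
  y <- profile$r_lesion[ok]
  w <- rep(1, length(y))
  beta <- NULL
  for (it in seq_len(n_iter)) {
    fit <- stats::lm.wfit(X, y, w)
    beta <- fit$coefficients
    res <- as.vector(y - X %*% beta)
    sigma <- max(stats::median(abs(res)) / 0.6745, 0.5)
    # protrusions (positive residuals) are the invading lesion: down-weight
    w <- ifelse(res > 0, exp(-(res / sigma)^2), 1)
  }
  r_hat <- as.vector(basis(profile$theta) %*% beta)
  clamp(r_hat, 0, profile$r_serosa)
}

#' Invasion-depth fraction from a radial profile
#'
#' For each valid ray computes
#' `f = max(0, r_lesion - r_junction_hat) / (r_serosa - r_junction_hat)`
#' (invasion depth over local myometrial thickness); rays whose residual
#' thickness is below `min_thickness` pixels are excluded as degenerate.
#' The case fraction is the maximum of a lightly smoothed `f` over angles,
#' clamped to `[0, 1]` - the deepest penetration governs.
#'
#' @param profile A [ray_profile()].
#' @param r_junction_hat Junction estimate from [estimate_junction()] (or
#'   known junction radii).
#' @param min_thickness Minimum admissible myometrial thickness in pixels.
#' @param smooth_window Circular moving-average window (rays) applied to the
#'   per-ray fractions before taking the maximum; 1 disables smoothing.
#' @return An `invasion_estimate` list: `fraction`, `per_ray` tibble,
#'   `n_valid_rays`, `method` metadata.
#' @export
invasion_fraction <- function(profile, r_junction_hat, min_thickness = 2,
                              smooth_window = 5) {
  stopifnot(inherits(profile, "ray_profile"))
  if (length(r_junction_hat) != nrow(profile)) {
    abort_myo("r_junction_hat must have one value per ray")
  }
  thick <- profile$r_serosa - r_junction_hat
  usable <- profile$valid & thick >= min_thickness
  if (!any(usable)) {
    abort_myo("all rays degenerate (no measurable myometrial thickness)",
              class = "myoinvade_degenerate_error")
  }
  f <- pmax(0, profile$r_lesion - r_junction_hat) / pmax(1e-6, thick)
  f[!usable] <- NA_real_
  fs <- circular_smooth(f, smooth_window)
  fraction <- clamp(max(fs, na.rm = TRUE), 0, 1)
  structure(
    list(
      fraction = fraction,
      per_ray = tibble::tibble(
        theta = profile$theta, fraction = f, usable = usable
      ),
      n_valid_rays = sum(usable),
      method = list(
        n_rays = attr(profile, "n_rays"), min_thickness = min_thickness,
        smooth_window = smooth_window
      )
    ),
    class = "invasion_estimate"
  )
}

# Circular moving average ignoring NAs.
circular_smooth <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  half <- floor(window / 2)
  idx <- outer(seq_len(n), (-half):half, function(i, k) ((i + k - 1) %% n) + 1)
  m <- matrix(x[idx], n)
  out <- rowMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' @export
print.invasion_estimate <- function(x, ...) {
  cat(sprintf(
    "<invasion_estimate> fraction %.3f (%d valid rays)\n",
    x$fraction, x$n_valid_rays
  ))
  invisible(x)
}

#' Stage a case from per-slice invasion fractions
#'
#' The case-level fraction is the maximum over slices (deepest invasion
#' governs staging); the FIGO call is IB when the fraction reaches the 50%
#' cutoff (inclusive: exactly 50% invasion is IB), IA otherwise.
#'
#' @param per_slice_fractions Numeric vector of per-slice fractions (>= 1).
#' @return A `stage_call` list: `stage` ("IA"/"IB"), `fraction`,
#'   `cutoff = 0.5`, `rule`.
#' @export
stage_case <- function(per_slice_fractions) {
  if (length(per_slice_fractions) == 0 || all(is.na(per_slice_fractions))) {
    abort_myo("at least one slice fraction is required")
  }
  fraction <- max(per_slice_fractions, na.rm = TRUE)
  structure(
    list(
      stage = if (fraction >= 0.5) "IB" else "IA",
      fraction = fraction,
      cutoff = 0.5,
      rule = "fraction >= 0.5 => IB"
    ),
    class = "stage_call"
  )
}

#' @export
print.stage_call <- function(x, ...) {
  cat(sprintf("<stage_call> %s (fraction %.3f, cutoff %.2f inclusive)\n",
              x$stage, x$fraction, x$cutoff))
  invisible(x)
}

#' Estimate the invasion fraction of one mask pair
#'
#' Convenience wrapper chaining [ray_profile()], [estimate_junction()] and
#' [invasion_fraction()].
#'
#' @inheritParams ray_profile
#' @inheritParams estimate_junction
#' @param ... Passed to [invasion_fraction()].
#' @return An `invasion_estimate`.
#' @export
estimate_invasion <- function(uterus_mask, lesion_mask, n_rays = 720,
                              fit_order = 3, ...) {
  prof <- ray_profile(uterus_mask, lesion_mask, n_rays = n_rays)
  rj <- estimate_junction(prof, fit_order = fit_order)
  invasion_fraction(prof, rj, ...)
}

#' Stage every case of a cohort from masks
#'
#' Runs the ray-based invasion estimator on each case's uterus/lesion mask
#' pair and applies the 50% staging rule. With `masks = "truth"` the
#' phantom ground-truth masks are used (estimator validation); with a list
#' of `segmentation_output`s the predicted masks are staged instead.
#'
#' @param cases A `phantom_cohort` (or list of `phantom_case`).
#' @param masks `"truth"` or a named list of `segmentation_output` objects
#'   keyed by `case_id`.
#' @param ... Passed to [estimate_invasion()].
#' @return A tibble: `case_id`, `fraction`, `stage`, `n_valid_rays`, `flag`.
#' @export
stage_cohort <- function(cases, masks = "truth", ...) {
  rows <- lapply(cases, function(cs) {
    um <- cs$uterus_mask
    lm <- cs$lesion_mask
    flag <- ""
    if (!identical(masks, "truth")) {
      so <- masks[[cs$case_id]]
      if (is.null(so)) abort_myo(sprintf("no prediction for %s", cs$case_id))
      um <- so$masks$uterus
      lm <- so$masks$lesion
      if (length(so$flags)) flag <- paste(so$flags, collapse = ";")
    }
    if (sum(lm) == 0 || sum(um) == 0) {
      return(tibble::tibble(
        case_id = cs$case_id, fraction = NA_real_, stage = NA_character_,
        n_valid_rays = 0L, flag = paste0(flag, ";empty_mask")
      ))
    }
    est <- tryCatch(
      estimate_invasion(um, lm, ...),
      myoinvade_error = function(e) NULL
    )
    if (is.null(est)) {
      return(tibble::tibble(
        case_id = cs$case_id, fraction = NA_real_, stage = NA_character_,
        n_valid_rays = 0L, flag = paste0(flag, ";estimation_failed")
      ))
    }
    call <- stage_case(est$fraction)
    tibble::tibble(
      case_id = cs$case_id, fraction = call$fraction, stage = call$stage,
      n_valid_rays = est$n_valid_rays, flag = flag
    )
  })
  dplyr::bind_rows(rows)
}
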