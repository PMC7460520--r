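#' Parameters for a single uterine phantom
#'
#' Defines the geometry, tissue intensities and noise level of one synthetic
#' sagittal uterine cross-section. The uterus is an ellipse (serosal
#' boundary), the endometrial cavity is bounded by a smooth low-order
#' trigonometric endomyometrial junction curve `r_junction(theta)`, and the
#' lesion extends radially beyond the junction over an angular sector to a
#' controllable depth fraction of the local myometrial thickness. An optional
#' leiomyoma is a disc in the myometrium that locally bulges the serosa
#' outward and dents the junction inward (mass effect), which is what makes
#' leiomyoma-bearing phantoms harder to stage.
#'
#' @param canvas_size Side of the square image in pixels (default 128;
#'   896 mirrors the full-resolution setting).
#' @param uterus_axes Semi-axes of the uterus ellipse in pixels; default
#'   `c(0.38, 0.30) * canvas_size`.
#' @param cavity_coefs Trigonometric coefficients of the baseline junction
#'   radius, a named list with `r0` (mean radius, pixels) and optional
#'   `a`, `b` (cosine/sine coefficient vectors, order <= 3, relative units).
#'   Default: `r0 = 0.45 * min(uterus_axes)` with mild order-2 modulation.
#' @param target_fraction Intended deepest invasion as a fraction of local
#'   myometrial thickness, in `[0, 1]`.
#' @param lesion_angular_extent Angular width of the invading sector,
#'   radians in `(0, 2*pi)`.
#' @param lesion_center_angle Centre angle of the invading sector; drawn
#'   uniformly if `NULL`.
#' @param leiomyoma `NULL`, or a list with `angle` (radians), `radius`
#'   (pixels), `compression` (dimensionless in `[0, 1]`, how strongly the
#'   disc displaces the junction/serosa).
#' @param intensity_table Mean intensity per tissue class per modality; a
#'   data frame with columns `tissue`, `T1c`, `T2` (see
#'   [default_intensity_table()]).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param seed Integer seed; generation is deterministic given the full
#'   parameter set.
#'
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(canvas_size = 128,
                           uterus_axes = NULL,
                           cavity_coefs = NULL,
                           target_fraction = 0.3,
                           lesion_angular_extent = pi / 3,
                           lesion_center_angle = NULL,
                           leiomyoma = NULL,
                           intensity_table = default_intensity_table(),
                           noise_sd = 0.05,
                           seed = 1L) {
  if (canvas_size < 32) abort_myo("canvas_size must be at least 32 pixels")
  uterus_axes <- uterus_axes %||% (c(0.38, 0.30) * canvas_size)
  if (length(uterus_axes) != 2 || any(uterus_axes <= 0)) {
    abort_myo("uterus_axes must be two positive semi-axes in pixels")
  }
  cavity_coefs <- cavity_coefs %||% list(
    r0 = 0.45 * min(uterus_axes),
    a = c(0.00, 0.08, 0.00),
    b = c(0.05, 0.00, 0.00)
  )
  cavity_coefs$a <- cavity_coefs$a %||% numeric(0)
  cavity_coefs$b <- cavity_coefs$b %||% numeric(0)
  if (length(cavity_coefs$a) > 3 || length(cavity_coefs$b) > 3) {
    abort_myo("cavity_coefs: trigonometric order must be <= 3")
  }
  if (!is.numeric(target_fraction) || target_fraction < 0 || target_fraction > 1) {
    abort_myo("target_fraction must lie in [0, 1]",
              class = "myoinvade_lesion_error")
  }
  if (lesion_angular_extent <= 0 || lesion_angular_extent >= 2 * pi) {
    abort_myo("lesion_angular_extent must lie in (0, 2*pi)")
  }
  if (!is.null(leiomyoma)) {
    stopifnot(is.list(leiomyoma))
    leiomyoma$angle <- leiomyoma$angle %||% 0
    leiomyoma$radius <- leiomyoma$radius %||% (0.08 * canvas_size)
    leiomyoma$compression <- leiomyoma$compression %||% 0.35
    if (leiomyoma$compression < 0 || leiomyoma$compression > 1) {
      abort_myo("leiomyoma$compression must lie in [0, 1]")
    }
  }
  p <- list(
    canvas_size = as.integer(canvas_size),
    uterus_axes = as.numeric(uterus_axes),
    cavity_coefs = cavity_coefs,
    target_fraction = as.numeric(target_fraction),
    lesion_angular_extent = as.numeric(lesion_angular_extent),
    lesion_center_angle = lesion_center_angle,
    leiomyoma = leiomyoma,
    intensity_table = intensity_table,
    noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  )
  class(p) <- "phantom_params"
  p
}

#' Default tissue intensity table
#'
#' Mean intensities (arbitrary units in roughly `[0, 1]`) per tissue class
#' for the two emulated contrasts: on the contrast-enhanced T1-weighted-like
#' channel the myometrium enhances and the lesion stays dark; on the
#' T2-weighted-like channel the endometrium/lesion is bright and the
#' leiomyoma is markedly dark.
#'
#' @return A tibble with columns `tissue`, `T1c`, `T2`.
#' @export
default_intensity_table <- function() {
  tibble::tibble(
    tissue = c("background", "myometrium", "lesion", "leiomyoma"),
    T1c = c(0.05, 0.75, 0.35, 0.55),
    T2 = c(0.05, 0.35, 0.80, 0.15)
  )
}

# Radius of an ellipse with semi-axes (a, b) along direction theta.
ellipse_radius <- function(theta, a, b) {
  a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
}

# Evaluate the low-order trigonometric junction curve.
trig_radius <- function(theta, coefs) {
  r <- rep(1, length(theta))
  for (k in seq_along(coefs$a)) r <- r + coefs$a[k] * cos(k * theta)
  for (k in seq_along(coefs$b)) r <- r + coefs$b[k] * sin(k * theta)
  coefs$r0 * r
}

# Gaussian angular bump used for leiomyoma mass effect.
angular_gauss <- function(theta, center, width) {
  exp(-(wrap_angle(theta - center) / width)^2)
}

# Raised-cosine lesion protrusion profile: 1 at the sector centre, 0 at the
# sector edges, identically 0 outside.
lesion_bump <- function(theta, center, extent) {
  d <- wrap_angle(theta - center)
  out <- numeric(length(theta))
  inside <- abs(d) < extent / 2
  out[inside] <- cos(d[inside] * pi / extent)^2
  out
}

# All radial curves of a phantom evaluated at angles theta.
phantom_curves <- function(params, theta, lesion_center) {
  a <- params$uterus_axes[1]
  b <- params$uterus_axes[2]
  r_ser <- ellipse_radius(theta, a, b)
  r_jun <- trig_radius(theta, params$cavity_coefs)
  if (!is.null(params$leiomyoma)) {
    lm <- params$leiomyoma
    r_mid <- (r_jun + r_ser) / 2
    width <- lm$radius / mean(r_mid) * 1.5
    g <- angular_gauss(theta, lm$angle, width)
    r_ser <- r_ser * (1 + 0.5 * lm$compression * g)
    r_jun <- r_jun * (1 - lm$compression * g)
  }
  bump <- lesion_bump(theta, lesion_center, params$lesion_angular_extent)
  r_les <- r_jun + params$target_fraction * bump * (r_ser - r_jun)
  list(r_serosa = r_ser, r_junction = r_jun, r_lesion = r_les)
}

#' Generate a single uterine phantom
#'
#' Rasterizes the uterus ellipse, the baseline endometrial cavity, the
#' invading lesion sector, and (optionally) a leiomyoma disc; paints per
#' tissue-class intensities for the two modality-like contrasts and adds
#' Gaussian noise. The true invasion fraction is the maximum over angles of
#' `(r_lesion - r_junction) / (r_serosa - r_junction)` realized by the
#' constructed geometry (evaluated on the angular grid including the sector
#' centre, where it equals `target_fraction` exactly). Generation is
#' deterministic given the parameters and seed.
#'
#' @param params A [phantom_params()] object.
#' @param case_id Case identifier string.
#' @param n_truth_angles Angular resolution of the recorded junction truth.
#' @return A `phantom_case` list: `case_id`, `images` (named list of
#'   matrices, one per modality), `uterus_mask`, `lesion_mask` (binary
#'   matrices; the lesion mask covers endometrium plus invading lesion),
#'   `junction_truth` (tibble `theta`, `r_junction`, `r_serosa`), `origin`
#'   (ray origin, c(row, col)), and `truth` (one-row tibble with
#'   `true_fraction`, `true_stage`, `leiomyoma_present`, `histology_type`).
#' @export
generate_phantom <- function(params, case_id = "case_001",
                             n_truth_angles = 720) {
  stopifnot(inherits(params, "phantom_params"))
  set.seed(child_seed(params$seed, "phantom"))
  n <- params$canvas_size
  cx <- (n + 1) / 2
  cy <- (n + 1) / 2

  lesion_center <- params$lesion_center_angle %||% stats::runif(1, -pi, pi)

  # Validate geometry on a fine angular grid before rasterizing.
  th_check <- seq(-pi, pi, length.out = 1441)[-1]
  cv <- phantom_curves(params, th_check, lesion_center)
  if (any(cv$r_junction >= cv$r_serosa - 1)) {
    abort_myo(
      "invalid geometry: cavity junction reaches the serosa (no myometrium left)",
      class = "myoinvade_lesion_error"
    )
  }
  if (any(cv$r_lesion > cv$r_serosa + 1e-9)) {
    abort_myo("lesion would exit the uterus", class = "myoinvade_lesion_error")
  }

  # Pixel-centre polar coordinates (row = y downward, col = x rightward).
  row <- matrix(seq_len(n), n, n)
  col <- matrix(seq_len(n), n, n, byrow = TRUE)
  dx <- col - cx
  dy <- row - cy
  r_px <- sqrt(dx^2 + dy^2)
  th_px <- atan2(dy, dx)

  pcv <- phantom_curves(params, as.vector(th_px), lesion_center)
  uterus_mask <- (r_px <= matrix(pcv$r_serosa, n, n)) * 1
  lesion_mask <- (r_px <= matrix(pcv$r_lesion, n, n)) * 1

  lm_mask <- matrix(0, n, n)
  if (!is.null(params$leiomyoma)) {
    lm <- params$leiomyoma
    thL <- lm$angle
    cvL <- phantom_curves(params, thL, lesion_center)
    r_mid <- (cvL$r_junction + cvL$r_serosa) / 2
    lx <- cx + r_mid * cos(thL)
    ly <- cy + r_mid * sin(thL)
    lm_mask <- ((col - lx)^2 + (row - ly)^2 <= lm$radius^2) * 1
    lm_mask <- lm_mask * uterus_mask * (1 - lesion_mask)
  }

  # Paint intensities per modality and add noise.
  it <- params$intensity_table
  get_mu <- function(tissue, mod) it[[mod]][match(tissue, it$tissue)]
  modalities <- setdiff(names(it), "tissue")
  images <- lapply(modalities, function(mod) {
    img <- matrix(get_mu("background", mod), n, n)
    img[uterus_mask == 1] <- get_mu("myometrium", mod)
    img[lesion_mask == 1] <- get_mu("lesion", mod)
    img[lm_mask == 1] <- get_mu("leiomyoma", mod)
    img + matrix(stats::rnorm(n * n, 0, params$noise_sd), n, n)
  })
  names(images) <- modalities

  # Recorded truth: angular grid including the sector centre, where the
  # realized maximum equals target_fraction exactly.
  th_truth <- sort(unique(c(
    seq(-pi, pi, length.out = n_truth_angles + 1)[-1], wrap_angle(lesion_center)
  )))
  tcv <- phantom_curves(params, th_truth, lesion_center)
  f_theta <- clamp(
    pmax(0, tcv$r_lesion - tcv$r_junction) /
      pmax(1e-6, tcv$r_serosa - tcv$r_junction),
    0, 1
  )
  true_fraction <- max(f_theta)
  junction_truth <- tibble::tibble(
    theta = th_truth,
    r_junction = tcv$r_junction,
    r_serosa = tcv$r_serosa
  )

  truth <- tibble::tibble(
    case_id = case_id,
    true_fraction = true_fraction,
    true_stage = ifelse(true_fraction >= 0.5, "IB", "IA"),
    leiomyoma_present = !is.null(params$leiomyoma),
    histology_type = "I"
  )

  structure(
    list(
      case_id = case_id,
      images = images,
      uterus_mask = uterus_mask,
      lesion_mask = lesion_mask,
      junction_truth = junction_truth,
      origin = c(row = cy, col = cx),
      lesion_center_angle = lesion_center,
      truth = truth,
      params = params
    ),
    class = "phantom_case"
  )
}

#' @export
print.phantom_case <- function(x, ...) {
  cat(sprintf(
    "<phantom_case %s> %dx%d, modalities: %s\n  true fraction %.3f, stage %s, leiomyoma: %s\n",
    x$case_id, nrow(x$uterus_mask), ncol(x$uterus_mask),
    paste(names(x$images), collapse = ", "),
    x$truth$true_fraction, x$truth$true_stage, x$truth$leiomyoma_present
  ))
  invisible(x)
}

#' Cohort specification for phantom generation
#'
#' Defaults emulate the study cohort composition: 26.4% stage IB (19/72),
#' 40.3% with leiomyoma (29/72), and per-stage invasion-fraction laws
#' bounded by the observed ranges (IA uniform on `[0, 0.48]`, IB uniform on
#' `[0.5, 0.87]`).
#'
#' @param n_cases Number of cases (>= 1).
#' @param stage_mix Proportion of stage-IB cases.
#' @param leiomyoma_prevalence Proportion of cases bearing a leiomyoma.
#' @param fraction_law Function `(stage, n)` returning `n` sampled target
#'   fractions for that stage; default uniform laws above.
#' @param type2_prevalence Proportion with type-II histology (covariate
#'   label only; default 13/72).
#' @param canvas_size Image side in pixels.
#' @param noise_sd Additive noise standard deviation.
#' @param seed Integer seed.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 72,
                        stage_mix = 19 / 72,
                        leiomyoma_prevalence = 29 / 72,
                        fraction_law = NULL,
                        type2_prevalence = 13 / 72,
                        canvas_size = 128,
                        noise_sd = 0.05,
                        seed = 1L) {
  if (n_cases < 1) abort_myo("n_cases must be >= 1")
  for (p in c(stage_mix, leiomyoma_prevalence, type2_prevalence)) {
    if (p < 0 || p > 1) abort_myo("proportions must lie in [0, 1]")
  }
  fraction_law <- fraction_law %||% function(stage, n) {
    if (stage == "IB") stats::runif(n, 0.5, 0.87) else stats::runif(n, 0, 0.48)
  }
  structure(
    list(
      n_cases = as.integer(n_cases), stage_mix = stage_mix,
      leiomyoma_prevalence = leiomyoma_prevalence,
      fraction_law = fraction_law, type2_prevalence = type2_prevalence,
      canvas_size = as.integer(canvas_size), noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a phantom cohort
#'
#' Draws per-case stage, leiomyoma status, histology label, target invasion
#' fraction and geometry jitter from the cohort specification, then
#' generates each phantom deterministically. Identical spec and seed yield
#' identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A `phantom_cohort`: a list of `phantom_case` objects with the
#'   per-case truth table available via [cohort_truth()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(child_seed(spec$seed, "cohort"))
  n <- spec$n_cases
  stages <- ifelse(stats::runif(n) < spec$stage_mix, "IB", "IA")
  leio <- stats::runif(n) < spec$leiomyoma_prevalence
  hist_type <- ifelse(stats::runif(n) < spec$type2_prevalence, "II", "I")
  fractions <- numeric(n)
  for (s in c("IA", "IB")) {
    idx <- which(stages == s)
    if (length(idx)) fractions[idx] <- spec$fraction_law(s, length(idx))
  }
  draws <- tibble::tibble(
    lesion_center = stats::runif(n, -pi, pi),
    extent = stats::runif(n, pi / 4, pi / 2),
    axis_jit1 = stats::runif(n, 0.92, 1.08),
    axis_jit2 = stats::runif(n, 0.92, 1.08),
    a2 = stats::runif(n, -0.08, 0.08),
    b1 = stats::runif(n, -0.06, 0.06),
    lm_angle = stats::runif(n, -pi, pi),
    lm_rad = stats::runif(n, 0.06, 0.10) * spec$canvas_size,
    lm_comp = stats::runif(n, 0.25, 0.45),
    case_seed = sample.int(2^30, n)
  )

  cases <- vector("list", n)
  for (i in seq_len(n)) {
    lm <- NULL
    if (leio[i]) {
      lm <- list(
        angle = draws$lm_angle[i], radius = draws$lm_rad[i],
        compression = draws$lm_comp[i]
      )
    }
    axes <- c(0.38 * draws$axis_jit1[i], 0.30 * draws$axis_jit2[i]) *
      spec$canvas_size
    params <- phantom_params(
      canvas_size = spec$canvas_size,
      uterus_axes = axes,
      cavity_coefs = list(
        r0 = 0.45 * min(axes),
        a = c(0, draws$a2[i], 0),
        b = c(draws$b1[i], 0, 0)
      ),
      target_fraction = fractions[i],
      lesion_angular_extent = draws$extent[i],
      lesion_center_angle = draws$lesion_center[i],
      leiomyoma = lm,
      noise_sd = spec$noise_sd,
      seed = draws$case_seed[i]
    )
    case <- generate_phantom(params, case_id = sprintf("case_%03d", i))
    case$truth$histology_type <- hist_type[i]
    cases[[i]] <- case
  }
  structure(cases, class = "phantom_cohort", spec = spec)
}

#' Per-case truth table of a cohort
#'
#' @param cohort A `phantom_cohort`.
#' @return A tibble with one row per case: `case_id`, `true_fraction`,
#'   `true_stage`, `leiomyoma_present`, `histology_type`.
#' @export
cohort_truth <- function(cohort) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  dplyr::bind_rows(lapply(cohort, function(cs) cs$truth))
}

#' @export
print.phantom_cohort <- function(x, ...) {
  tr <- cohort_truth(x)
  cat(sprintf(
    "<phantom_cohort> %d cases (%d IA / %d IB), %d with leiomyoma\n",
    nrow(tr), sum(tr$true_stage == "IA"), sum(tr$true_stage == "IB"),
    sum(tr$leiomyoma_present)
  ))
  invisible(x)
}
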