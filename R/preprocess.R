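#' Standardize an image to zero mean and unit variance
#'
#' Applies the pixel-wise transform `(P - Pmean) / Psd` over the whole
#' image, where `Pmean` and `Psd` are the mean and population (denominator
#' `n`) standard deviation of all pixels. The source statistics are kept as
#' attributes so the transform is invertible.
#'
#' @param img Numeric matrix of pixel intensities.
#' @return The standardized matrix with attributes `p_mean` and `p_std`.
#' @export
standardize <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (any(!is.finite(img))) abort_myo("image contains non-finite values")
  m <- mean(img)
  s <- sqrt(mean((img - m)^2))
  if (s == 0) {
    abort_myo("cannot standardize a constant image (zero pixel variance)",
              class = "myoinvade_degenerate_error")
  }
  out <- (img - m) / s
  attr(out, "p_mean") <- m
  attr(out, "p_std") <- s
  out
}

#' Center-crop to a square and resample to a target size
#'
#' Crops the largest centered square window, then resamples it to
#' `target x target` pixels: bilinear interpolation for images, nearest
#' neighbour for masks (which therefore stay binary).
#'
#' @param img Numeric matrix.
#' @param target Output side in pixels (>= 8).
#' @param kind `"image"` (bilinear) or `"mask"` (nearest neighbour).
#' @return A `target x target` matrix.
#' @export
crop_resize <- function(img, target, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(img))
  if (!is.numeric(target) || target < 8) {
    abort_myo("target size must be a positive number >= 8")
  }
  target <- as.integer(target)
  h <- nrow(img)
  w <- ncol(img)
  side <- min(h, w)
  r0 <- floor((h - side) / 2)
  c0 <- floor((w - side) / 2)
  cropped <- img[r0 + seq_len(side), c0 + seq_len(side), drop = FALSE]
  if (side == target) return(cropped)
  filt <- if (kind == "image") "bilinear" else "none"
  out <- EBImage::resize(cropped, w = target, h = target, filter = filt)
  out <- matrix(as.numeric(out), target, target)
  if (kind == "mask") out <- (out >= 0.5) * 1
  out
}

#' Augment an image/mask pair
#'
#' Emits the original pair plus, per the augmentation plan: the horizontal
#' flip, the vertical flip, a random small affine transform (rotation up to
#' 15 degrees, translation up to 5% of the side, isotropic scale in
#' 0.9-1.1), and an intensity-scaled copy (factor in 0.8-1.2; geometric
#' identity). Identical geometric transforms are applied to image and mask
#' (nearest neighbour for the mask, so it stays binary); random draws are
#' deterministic given the seed. Every emitted pair carries a provenance
#' tag so augmented derivatives can be barred from validation/test pools.
#'
#' @param img Numeric matrix.
#' @param mask Binary matrix, congruent with `img`.
#' @param plan Character subset of `c("flips", "affine", "intensity")`.
#' @param seed Integer seed for the random transform parameters.
#' @param n_affine Number of random affine copies.
#' @return A tibble with columns `transform`, `provenance` ("original" or
#'   "augmented"), `image` and `mask` (list-columns of matrices), and
#'   `params` (list-column with the sampled transform parameters).
#' @export
augment <- function(img, mask, plan = c("flips", "affine", "intensity"),
                    seed = 1L, n_affine = 1L) {
  assert_same_shape(img, mask, "image", "mask")
  assert_binary_mask(mask)
  plan <- match.arg(plan, several.ok = TRUE)
  set.seed(child_seed(seed, "augment"))

  rows <- list(tibble::tibble(
    transform = "identity", provenance = "original",
    image = list(img), mask = list(mask), params = list(NULL)
  ))

  if ("flips" %in% plan) {
    hflip <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    vflip <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
    rows <- c(rows, list(
      tibble::tibble(
        transform = "hflip", provenance = "augmented",
        image = list(hflip(img)), mask = list(hflip(mask)), params = list(NULL)
      ),
      tibble::tibble(
        transform = "vflip", provenance = "augmented",
        image = list(vflip(img)), mask = list(vflip(mask)), params = list(NULL)
      )
    ))
  }

  if ("affine" %in% plan) {
    for (k in seq_len(n_affine)) {
      pr <- list(
        angle = stats::runif(1, -15, 15),
        tx = stats::runif(1, -0.05, 0.05) * ncol(img),
        ty = stats::runif(1, -0.05, 0.05) * nrow(img),
        scale = stats::runif(1, 0.9, 1.1)
      )
      rows <- c(rows, list(tibble::tibble(
        transform = sprintf("affine_%d", k), provenance = "augmented",
        image = list(apply_affine(img, pr, kind = "image")),
        mask = list(apply_affine(mask, pr, kind = "mask")),
        params = list(pr)
      )))
    }
  }

  if ("intensity" %in% plan) {
    fac <- stats::runif(1, 0.8, 1.2)
    rows <- c(rows, list(tibble::tibble(
      transform = "intensity", provenance = "augmented",
      image = list(img * fac), mask = list(mask),
      params = list(list(factor = fac))
    )))
  }

  dplyr::bind_rows(rows)
}

# Apply a centre-anchored rotation/scale/translation to a matrix.
apply_affine <- function(m, pr, kind = c("image", "mask")) {
  kind <- match.arg(kind)
  h <- nrow(m)
  w <- ncol(m)
  th <- pr$angle * pi / 180
  s <- pr$scale
  # EBImage works in (x, y) = (row-as-x) order for plain matrices; build the
  # 3x2 matrix mapping input to output coordinates about the image centre.
  cx <- (h + 1) / 2
  cy <- (w + 1) / 2
  rot <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  off <- c(cx, cy) - rot %*% c(cx, cy) + c(pr$ty, pr$tx)
  m3 <- rbind(t(rot), as.numeric(off))
  filt <- if (kind == "image") "bilinear" else "none"
  out <- EBImage::affine(m, m3, filter = filt, bg.col = 0)
  out <- matrix(as.numeric(out), h, w)
  if (kind == "mask") out <- (out >= 0.5) * 1
  out
}

#' Split a cohort into training, validation and test groups
#'
#' Mirrors the study design: one third of cases train the model, a small
#' independent validation group drives checkpoint selection, and the
#' remainder form the test group. In the default (cohort-faithful) mode the
#' evaluation pool is validation plus test; `evaluation = "strict"` restricts
#' it to the test group only. Splitting can be stratified by stage so stage
#' proportions are preserved within one case per split.
#'
#' @param truth A data frame with columns `case_id` and (if stratifying)
#'   `true_stage`.
#' @param train_fraction Fraction of cases used for training (default 1/3).
#' @param val_count Number of validation cases (default 6).
#' @param seed Integer seed.
#' @param stratify_by_stage Preserve stage proportions across splits.
#' @param evaluation `"pooled"` (validation + test form the evaluation
#'   group) or `"strict"` (test only).
#' @return A tibble `case_id`, `split` in {train, validation, test},
#'   `in_evaluation` (logical); the evaluation mode is kept in attribute
#'   `evaluation`.
#' @export
split_cohort <- function(truth, train_fraction = 1 / 3, val_count = 6,
                         seed = 1L, stratify_by_stage = TRUE,
                         evaluation = c("pooled", "strict")) {
  evaluation <- match.arg(evaluation)
  stopifnot(is.data.frame(truth), "case_id" %in% names(truth))
  n <- nrow(truth)
  n_train <- round(n * train_fraction)
  if (n_train < 1 || val_count < 1 || n_train + val_count >= n) {
    abort_myo(sprintf(
      "cohort of %d cases is too small for %d training and %d validation cases",
      n, n_train, val_count
    ))
  }
  set.seed(child_seed(seed, "split"))

  assign_one <- function(ids, k_train, k_val) {
    ids <- sample(ids)
    tibble::tibble(
      case_id = ids,
      split = c(
        rep("train", k_train), rep("validation", k_val),
        rep("test", length(ids) - k_train - k_val)
      )
    )
  }

  if (stratify_by_stage && "true_stage" %in% names(truth) &&
      length(unique(truth$true_stage)) > 1) {
    strata <- split(truth$case_id, truth$true_stage)
    k_train <- largest_remainder(n_train, vapply(strata, length, 1L))
    k_val <- largest_remainder(val_count, vapply(strata, length, 1L) - k_train)
    out <- dplyr::bind_rows(lapply(seq_along(strata), function(i) {
      assign_one(strata[[i]], k_train[i], k_val[i])
    }))
  } else {
    out <- assign_one(truth$case_id, n_train, val_count)
  }
  out <- out[match(truth$case_id, out$case_id), ]
  out$in_evaluation <- if (evaluation == "pooled") {
    out$split %in% c("validation", "test")
  } else {
    out$split == "test"
  }
  attr(out, "evaluation") <- evaluation
  out
}

# Allocate `total` units across strata proportionally to sizes, assigning
# remainders to the largest fractional parts.
largest_remainder <- function(total, sizes) {
  share <- total * sizes / sum(sizes)
  k <- floor(share)
  rem <- total - sum(k)
  if (rem > 0) {
    ord <- order(share - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(pmin(k, sizes))
}
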