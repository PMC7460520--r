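#' Soft-Dice segmentation loss
#'
#' `1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)` with
#' smoothing term `smooth = 1`, averaged over structures when given
#' multi-channel inputs. Chosen over cross-entropy for its robustness to the
#' class imbalance between small uterine structures and background.
#'
#' @param prob Probability map (matrix or array), values in `[0, 1]`.
#' @param target Binary target mask, congruent with `prob`.
#' @param smooth Smoothing constant (default 1).
#' @return Scalar loss in `[0, 1)`.
#' @export
dice_loss <- function(prob, target, smooth = 1) {
  assert_same_shape(prob, target, "probability map", "target mask")
  assert_binary_mask(target, "target mask")
  p <- as.vector(prob)
  t <- as.vector(target)
  1 - (2 * sum(p * t) + smooth) / (sum(p) + sum(t) + smooth)
}

#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|`; when both masks are empty the two
#' raters agree on absence and the IoU is defined as 1.
#'
#' @param pred_mask,true_mask Congruent binary masks.
#' @return A fraction in `[0, 1]`.
#' @export
iou <- function(pred_mask, true_mask) {
  assert_same_shape(pred_mask, true_mask, "predicted mask", "reference mask")
  assert_binary_mask(pred_mask, "predicted mask")
  assert_binary_mask(true_mask, "reference mask")
  a <- as.vector(pred_mask) > 0
  b <- as.vector(true_mask) > 0
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Dice coefficient of two binary masks
#'
#' @inheritParams iou
#' @return `2|A n B| / (|A| + |B|)`, with the empty/empty case defined as 1.
#' @export
dice_coefficient <- function(pred_mask, true_mask) {
  assert_same_shape(pred_mask, true_mask, "predicted mask", "reference mask")
  a <- as.vector(pred_mask) > 0
  b <- as.vector(true_mask) > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Training configuration
#'
#' Defaults follow the study protocol: stochastic gradient descent with a
#' small batch (16 images), learning rate 0.001, 150 epochs, soft-Dice
#' loss. Momentum (0.9) is configurable.
#'
#' @param batch_size Images per gradient step (>= 1).
#' @param learning_rate Positive SGD step size.
#' @param epochs Number of passes over the training set.
#' @param momentum SGD momentum coefficient.
#' @param clip_norm Global gradient-norm ceiling per batch; guards the
#'   Dice loss against saturating every sigmoid in one overshoot (a dead
#'   network cannot recover since the gradient vanishes with `p(1-p)`).
#'   `Inf` disables clipping.
#' @param seed Integer seed controlling shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 16, learning_rate = 0.001,
                         epochs = 150, momentum = 0.9, clip_norm = 1,
                         seed = 1L) {
  if (batch_size < 1) abort_myo("batch_size must be >= 1")
  if (learning_rate <= 0) abort_myo("learning_rate must be > 0")
  if (clip_norm <= 0) abort_myo("clip_norm must be > 0")
  structure(
    list(
      batch_size = as.integer(batch_size), learning_rate = learning_rate,
      epochs = as.integer(epochs), momentum = momentum,
      clip_norm = clip_norm, seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# Convert an (image, masks) pair into the flat tensors the network consumes.
prepare_sample <- function(image, uterus_mask, lesion_mask) {
  h <- nrow(image)
  w <- ncol(image)
  list(
    x = matrix(as.vector(image), h * w, 1L),
    t = cbind(as.vector(uterus_mask), as.vector(lesion_mask)),
    H = h, W = w
  )
}

#' Prepare phantom cases for training
#'
#' Standardizes one modality of each case and stacks the uterus and lesion
#' masks as network targets.
#'
#' @param cases List of `phantom_case` objects (or a `phantom_cohort`).
#' @param modality Which image channel to use (default `"T1c"`).
#' @return A list of training samples.
#' @export
prepare_cases <- function(cases, modality = "T1c") {
  lapply(cases, function(cs) {
    img <- standardize(cs$images[[modality]])
    s <- prepare_sample(img, cs$uterus_mask, cs$lesion_mask)
    s$case_id <- cs$case_id
    s
  })
}

#' Train a segmentation model
#'
#' Mini-batch stochastic gradient descent with momentum on the soft-Dice
#' loss. Per-epoch training loss, validation loss and per-structure
#' validation IoU are logged; the returned model carries the weights of the
#' epoch with the smallest validation loss (checkpoint selection), not
#' necessarily the last. Deterministic given the seed (single-threaded).
#'
#' @param model A `myo_unet` from [build_model()].
#' @param train_samples,val_samples Lists from [prepare_cases()] (training
#'   samples may include augmented derivatives; validation samples must
#'   not).
#' @param config A [train_config()].
#' @return A `myo_training` list: `model` (best checkpoint), `history`
#'   (tibble `epoch`, `train_loss`, `val_loss`, `val_iou_uterus`,
#'   `val_iou_lesion`), `best_epoch`.
#' @export
train_model <- function(model, train_samples, val_samples, config) {
  stopifnot(inherits(model, "myo_unet"), inherits(config, "train_config"))
  if (config$epochs > 0 && length(train_samples) == 0) {
    abort_myo("no training samples")
  }
  set.seed(child_seed(config$seed, "train"))
  velocity <- lapply(model$layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  history <- vector("list", config$epochs)
  best <- list(val_loss = Inf, layers = model$layers, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(length(train_samples))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      acc <- NULL
      bloss <- 0
      for (i in bt) {
        sm <- train_samples[[i]]
        fwd <- unet_forward(model, sm$x, sm$H, sm$W, keep_cache = TRUE)
        lg <- dice_loss_grad(fwd$logits, sm$t)
        if (!is.finite(lg$loss)) {
          abort_myo(sprintf(
            "training diverged (non-finite loss at epoch %d)", epoch
          ), class = "myoinvade_divergence_error")
        }
        bloss <- bloss + lg$loss
        g <- unet_backward(model, fwd, lg$dlogits)
        acc <- if (is.null(acc)) g else accumulate_grads(acc, g)
      }
      ep_loss <- ep_loss + bloss
      nb <- length(bt)
      gnorm <- sqrt(sum(vapply(acc, function(g) {
        sum(g$W^2) + sum(g$b^2)
      }, numeric(1)))) / nb
      scl <- if (is.finite(config$clip_norm) && gnorm > config$clip_norm) {
        config$clip_norm / gnorm
      } else {
        1
      }
      for (nm in names(model$layers)) {
        velocity[[nm]]$W <- config$momentum * velocity[[nm]]$W -
          config$learning_rate * scl * acc[[nm]]$W / nb
        velocity[[nm]]$b <- config$momentum * velocity[[nm]]$b -
          config$learning_rate * scl * acc[[nm]]$b / nb
        model$layers[[nm]]$W <- model$layers[[nm]]$W + velocity[[nm]]$W
        model$layers[[nm]]$b <- model$layers[[nm]]$b + velocity[[nm]]$b
      }
    }
    val <- evaluate_model(model, val_samples)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      train_loss = ep_loss / length(train_samples),
      val_loss = val$loss,
      val_iou_uterus = val$iou[1],
      val_iou_lesion = val$iou[2]
    )
    if (is.finite(val$loss) && val$loss < best$val_loss) {
      best <- list(val_loss = val$loss, layers = model$layers, epoch = epoch)
    }
  }

  model$layers <- best$layers
  structure(
    list(
      model = model,
      history = if (config$epochs > 0) dplyr::bind_rows(history) else
        tibble::tibble(
          epoch = integer(), train_loss = numeric(), val_loss = numeric(),
          val_iou_uterus = numeric(), val_iou_lesion = numeric()
        ),
      best_epoch = best$epoch
    ),
    class = "myo_training"
  )
}

accumulate_grads <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

# Mean loss and per-structure IoU (threshold 0.5) over samples.
evaluate_model <- function(model, samples) {
  if (length(samples) == 0) {
    return(list(loss = NA_real_, iou = c(NA_real_, NA_real_)))
  }
  n_str <- length(model$spec$structures)
  losses <- numeric(length(samples))
  ious <- matrix(0, length(samples), n_str)
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    fwd <- unet_forward(model, sm$x, sm$H, sm$W, keep_cache = FALSE)
    lg <- dice_loss_grad(fwd$logits, sm$t)
    losses[i] <- lg$loss
    for (s in seq_len(n_str)) {
      ious[i, s] <- iou((lg$prob[, s] >= 0.5) * 1, sm$t[, s])
    }
  }
  list(loss = mean(losses), iou = colMeans(ious))
}

#' @export
print.myo_training <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<myo_training> %d epochs, best checkpoint at epoch %d\n",
    nrow(h), x$best_epoch
  ))
  if (nrow(h)) {
    last <- h[nrow(h), ]
    cat(sprintf(
      "  final: train loss %.4f, val loss %.4f, val IoU uterus %.3f lesion %.3f\n",
      last$train_loss, last$val_loss, last$val_iou_uterus, last$val_iou_lesion
    ))
  }
  invisible(x)
}

#' Predict uterus and lesion masks for one image
#'
#' Runs the network, thresholds the per-structure sigmoid probability maps
#' at 0.5, keeps the largest connected component of each structure, and
#' enforces lesion containment by intersecting the lesion mask with the
#' uterus mask.
#'
#' @param model A `myo_unet` (or `myo_training`, whose checkpoint is used).
#' @param image Standardized image matrix at the model's resolution.
#' @param case_id Optional identifier carried into the output.
#' @return A `segmentation_output` list: `case_id`, `prob` (named list of
#'   probability matrices), `masks` (named list of binary matrices), and
#'   `flags` (character vector noting empty structures).
#' @export
predict_masks <- function(model, image, case_id = NA_character_) {
  if (inherits(model, "myo_training")) model <- model$model
  stopifnot(inherits(model, "myo_unet"))
  h <- nrow(image)
  w <- ncol(image)
  fwd <- unet_forward(model, matrix(as.vector(image), h * w, 1L), h, w)
  p <- sigmoid(fwd$logits)
  sn <- model$spec$structures
  prob <- lapply(seq_along(sn), function(s) matrix(p[, s], h, w))
  names(prob) <- sn
  masks <- lapply(prob, function(pm) largest_component((pm >= 0.5) * 1))
  if (all(c("uterus", "lesion") %in% sn)) {
    masks$lesion <- masks$lesion * masks$uterus
  }
  flags <- names(masks)[vapply(masks, sum, 1) == 0]
  structure(
    list(
      case_id = case_id, prob = prob, masks = masks,
      flags = if (length(flags)) paste0("empty_", flags) else character(0)
    ),
    class = "segmentation_output"
  )
}

#' @export
print.segmentation_output <- function(x, ...) {
  areas <- vapply(x$masks, sum, 1)
  cat(sprintf(
    "<segmentation_output %s> %s\n", x$case_id,
    paste(sprintf("%s: %d px", names(areas), as.integer(areas)),
          collapse = ", ")
  ))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
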