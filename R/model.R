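# Encoder-decoder (U-Net style) network: construction, forward, backward.
#
# The architecture is compiled into a linear program of ops
# (conv3/conv1/relu/pool/up/skip save/concat/residual add) executed by a
# generic interpreter, so one code path serves all encoder families.

encoder_family_presets <- function(family) {
  switch(family,
    "tiny" = list(depth = 3L, base_channels = 8L, convs_per_stage = 2L,
                  decoder_convs = 1L, residual = FALSE),
    "vgg11-like" = list(depth = 4L, base_channels = 16L,
                        convs_per_stage = c(1L, 1L, 2L, 2L, 2L),
                        residual = FALSE),
    "vgg16-like" = list(depth = 4L, base_channels = 16L,
                        convs_per_stage = c(2L, 2L, 3L, 3L, 3L),
                        residual = FALSE),
    "resnet34-like" = list(depth = 4L, base_channels = 16L,
                           convs_per_stage = c(1L, 1L, 2L, 2L, 2L),
                           residual = TRUE),
    abort_myo(sprintf("unsupported encoder family '%s'", family))
  )
}

#' Segmentation model specification
#'
#' @param encoder_family One of `"tiny"`, `"vgg11-like"`, `"vgg16-like"`,
#'   `"resnet34-like"`. The `tiny` variant (depth 3, < 0.5M parameters) is
#'   meant for CPU desk-scale work; the named families mirror the encoder
#'   depths/widths of their namesakes at reduced channel counts.
#' @param base_channels Channels of the first encoder stage; overrides the
#'   family preset when supplied.
#' @param depth Number of down/up-sampling stages; overrides the preset.
#' @param structures Ordered output structures, default uterus then lesion;
#'   one sigmoid probability map is emitted per structure (they may overlap,
#'   lesion containment is enforced downstream).
#' @param pretrained Must be `FALSE`: no pretrained encoder weights are
#'   bundled, all models are randomly initialized.
#' @return A `model_spec` list.
#' @export
model_spec <- function(encoder_family = "tiny", base_channels = NULL,
                       depth = NULL, structures = c("uterus", "lesion"),
                       pretrained = FALSE) {
  preset <- encoder_family_presets(encoder_family)
  if (isTRUE(pretrained)) {
    abort_myo(paste0(
      "pretrained encoder weights are not bundled; ",
      "use pretrained = FALSE (random initialization)"
    ))
  }
  depth <- as.integer(depth %||% preset$depth)
  cps <- preset$convs_per_stage
  if (length(cps) == 1L) cps <- rep(cps, depth + 1L)
  if (length(cps) != depth + 1L) cps <- rep_len(cps, depth + 1L)
  structure(
    list(
      encoder_family = encoder_family,
      base_channels = as.integer(base_channels %||% preset$base_channels),
      depth = depth,
      convs_per_stage = as.integer(cps),
      decoder_convs = as.integer(preset$decoder_convs %||% 2L),
      residual = preset$residual,
      structures = structures,
      pretrained = FALSE
    ),
    class = "model_spec"
  )
}

new_conv_layer <- function(type, c_in, c_out) {
  k <- if (type == "conv3") 9L else 1L
  sd <- sqrt(2 / (k * c_in))
  list(
    type = type, c_in = c_in, c_out = c_out,
    W = matrix(stats::rnorm(k * c_in * c_out, 0, sd), k * c_in, c_out),
    b = numeric(c_out)
  )
}

# Compile the U-Net program. Returns list(program, layers).
compile_unet <- function(spec, in_channels = 1L) {
  ch <- spec$base_channels * 2L^(0:spec$depth)
  layers <- list()
  program <- list()
  lid <- 0L
  add_layer <- function(type, ci, co) {
    lid <<- lid + 1L
    nm <- sprintf("L%02d", lid)
    layers[[nm]] <<- new_conv_layer(type, ci, co)
    nm
  }
  emit <- function(...) program[[length(program) + 1L]] <<- list(...)

  conv_stack <- function(c_in, c_out, n_convs, residual) {
    if (!residual) {
      ci <- c_in
      for (k in seq_len(n_convs)) {
        emit(op = "conv", layer = add_layer("conv3", ci, c_out))
        emit(op = "relu")
        ci <- c_out
      }
    } else {
      # residual blocks of two 3x3 convs with identity/1x1 shortcut
      ci <- c_in
      for (k in seq_len(max(1L, n_convs))) {
        proj <- if (ci != c_out) add_layer("conv1", ci, c_out) else NA_character_
        emit(op = "res_save")
        emit(op = "conv", layer = add_layer("conv3", ci, c_out))
        emit(op = "relu")
        emit(op = "conv", layer = add_layer("conv3", c_out, c_out))
        emit(op = "res_add", proj = proj)
        emit(op = "relu")
        ci <- c_out
      }
    }
  }

  ci <- in_channels
  for (i in seq_len(spec$depth)) {
    conv_stack(ci, ch[i], spec$convs_per_stage[i], spec$residual)
    emit(op = "skip_save", name = sprintf("s%d", i))
    emit(op = "pool")
    ci <- ch[i]
  }
  conv_stack(ci, ch[spec$depth + 1L], spec$convs_per_stage[spec$depth + 1L],
             spec$residual)
  for (i in rev(seq_len(spec$depth))) {
    emit(op = "up")
    emit(op = "concat", name = sprintf("s%d", i))
    c_in_dec <- ch[i + 1L] + ch[i]
    emit(op = "conv", layer = add_layer("conv3", c_in_dec, ch[i]))
    emit(op = "relu")
    if (spec$decoder_convs > 1L) {
      for (k in seq_len(spec$decoder_convs - 1L)) {
        emit(op = "conv", layer = add_layer("conv3", ch[i], ch[i]))
        emit(op = "relu")
      }
    }
  }
  emit(op = "conv", layer = add_layer("conv1", ch[1L], length(spec$structures)))
  list(program = program, layers = layers)
}

#' Build a segmentation model
#'
#' Constructs a randomly initialized encoder-decoder network with equal
#' numbers of down- and up-sampling stages and skip connections between
#' opposing stages, emitting one sigmoid probability map per structure.
#' Initialization is deterministic given the seed.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A `myo_unet` model object.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(child_seed(seed, "init"))
  net <- compile_unet(spec)
  structure(
    list(spec = spec, program = net$program, layers = net$layers, seed = seed),
    class = "myo_unet"
  )
}

#' @export
print.myo_unet <- function(x, ...) {
  np <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 1))
  cat(sprintf(
    "<myo_unet %s> depth %d, base %d channels, %d conv layers, %s parameters\n  structures: %s\n",
    x$spec$encoder_family, x$spec$depth, x$spec$base_channels,
    length(x$layers), format(np, big.mark = ","),
    paste(x$spec$structures, collapse = ", ")
  ))
  invisible(x)
}

n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) length(l$W) + length(l$b), 1))
}

# Forward pass. x: (H*W) x Cin matrix. Returns logits and (optionally) the
# cache needed for backprop.
unet_forward <- function(model, x, H, W, keep_cache = FALSE) {
  if (H %% 2L^model$spec$depth != 0 || W %% 2L^model$spec$depth != 0) {
    abort_myo(sprintf(
      "input %dx%d is not divisible by 2^depth = %d",
      H, W, 2L^model$spec$depth
    ), class = "myoinvade_shape_error")
  }
  skips <- list()
  res_stack <- list()
  cache <- if (keep_cache) vector("list", length(model$program)) else NULL
  h <- H; w <- W
  for (s in seq_along(model$program)) {
    step <- model$program[[s]]
    switch(step$op,
      conv = {
        ly <- model$layers[[step$layer]]
        if (ly$type == "conv3") {
          g <- conv_geom(h, w)
          r <- conv3_forward(x, ly$W, ly$b, g)
          if (keep_cache) cache[[s]] <- list(cols = r$cols, h = h, w = w)
        } else {
          r <- conv1_forward(x, ly$W, ly$b)
          if (keep_cache) cache[[s]] <- list(x = r$x)
        }
        x <- r$out
      },
      relu = {
        r <- relu_forward(x)
        x <- r$out
        if (keep_cache) cache[[s]] <- list(keep = r$keep)
      },
      pool = {
        g <- conv_geom(h, w)
        r <- maxpool_forward(x, g)
        if (keep_cache) cache[[s]] <- list(argmax = r$argmax, h = h, w = w)
        x <- r$out
        h <- h %/% 2L; w <- w %/% 2L
      },
      up = {
        g <- conv_geom(h, w)
        x <- upsample_forward(x, g)
        if (keep_cache) cache[[s]] <- list(h = h, w = w)
        h <- h * 2L; w <- w * 2L
      },
      skip_save = {
        skips[[step$name]] <- x
      },
      concat = {
        sk <- skips[[step$name]]
        if (keep_cache) cache[[s]] <- list(c_main = ncol(x), c_skip = ncol(sk))
        x <- cbind(x, sk)
      },
      res_save = {
        res_stack[[length(res_stack) + 1L]] <- x
      },
      res_add = {
        saved <- res_stack[[length(res_stack)]]
        res_stack[[length(res_stack)]] <- NULL
        if (!is.na(step$proj)) {
          ly <- model$layers[[step$proj]]
          r <- conv1_forward(saved, ly$W, ly$b)
          if (keep_cache) cache[[s]] <- list(saved = saved)
          x <- x + r$out
        } else {
          if (keep_cache) cache[[s]] <- list(saved = NULL)
          x <- x + saved
        }
      }
    )
  }
  list(logits = x, cache = cache, H = H, W = W)
}

# Backward pass from dlogits; returns gradients named by layer.
unet_backward <- function(model, fwd, dlogits) {
  grads <- lapply(model$layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  dskips <- list()
  dres_stack <- list()
  dx <- dlogits
  for (s in rev(seq_along(model$program))) {
    step <- model$program[[s]]
    ca <- fwd$cache[[s]]
    switch(step$op,
      conv = {
        ly <- model$layers[[step$layer]]
        if (ly$type == "conv3") {
          g <- conv_geom(ca$h, ca$w)
          r <- conv3_backward(dx, ca$cols, ly$W, ly$c_in, g)
        } else {
          r <- conv1_backward(dx, ca$x, ly$W)
        }
        grads[[step$layer]]$W <- grads[[step$layer]]$W + r$dW
        grads[[step$layer]]$b <- grads[[step$layer]]$b + r$db
        dx <- r$dx
      },
      relu = {
        dx <- relu_backward(dx, ca$keep)
      },
      pool = {
        g <- conv_geom(ca$h, ca$w)
        dx <- maxpool_backward(dx, ca$argmax, g, ca$h * ca$w)
      },
      up = {
        g <- conv_geom(ca$h, ca$w)
        dx <- upsample_backward(dx, g)
      },
      skip_save = {
        d_extra <- dskips[[step$name]]
        if (!is.null(d_extra)) dx <- dx + d_extra
      },
      concat = {
        dskips[[step$name]] <- dx[, ca$c_main + seq_len(ca$c_skip), drop = FALSE]
        dx <- dx[, seq_len(ca$c_main), drop = FALSE]
      },
      res_save = {
        d_extra <- dres_stack[[length(dres_stack)]]
        dres_stack[[length(dres_stack)]] <- NULL
        dx <- dx + d_extra
      },
      res_add = {
        if (!is.na(step$proj)) {
          ly <- model$layers[[step$proj]]
          r <- conv1_backward(dx, ca$saved, ly$W)
          grads[[step$proj]]$W <- grads[[step$proj]]$W + r$dW
          grads[[step$proj]]$b <- grads[[step$proj]]$b + r$db
          dres_stack[[length(dres_stack) + 1L]] <- r$dx
        } else {
          dres_stack[[length(dres_stack) + 1L]] <- dx
        }
      }
    )
  }
  grads
}

# Soft-Dice loss over all structures and its gradient wrt the logits.
dice_loss_grad <- function(logits, target, smooth = 1) {
  p <- sigmoid(logits)
  S <- ncol(p)
  A <- 2 * colSums(p * target) + smooth
  B <- colSums(p) + colSums(target) + smooth
  loss <- mean(1 - A / B)
  # d(1 - A/B)/dp = -(2*t*B - A)/B^2, averaged over structures
  dp <- -(2 * target * rep(B, each = nrow(p)) - rep(A, each = nrow(p))) /
    rep(B^2, each = nrow(p)) / S
  dlogits <- dp * p * (1 - p)
  list(loss = loss, dlogits = dlogits, prob = p)
}
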