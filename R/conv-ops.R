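# Low-level tensor ops for the encoder-decoder network.
#
# Feature maps are stored as (H*W) x C matrices with column-major spatial
# indexing (idx = (j-1)*H + i), so 3x3 convolutions become one im2col gather
# plus a BLAS matrix product. Spatial index tables are cached per (H, W).

.geom_cache <- new.env(parent = emptyenv())

conv_geom <- function(H, W) {
  key <- paste0(H, "x", W)
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  Hp <- H + 2L
  i <- rep(seq_len(H), W)
  j <- rep(seq_len(W), each = H)
  # padded linear index of interior pixel (i+1, j+1)
  interior <- j * Hp + (i + 1L)
  # One gather index over all 9 kernel offsets: block o = (dj)*3 + di + 1.
  # With weight rows ordered (channel-major, offset-minor: row = (c-1)*9 + o)
  # the gathered (9*H*W) x C matrix reshapes to the (H*W) x (9*C) im2col
  # matrix without any permutation.
  samp_all <- integer(9L * H * W)
  o <- 0L
  for (dj in 0:2) {
    for (di in 0:2) {
      o <- o + 1L
      samp_all[((o - 1L) * H * W + 1L):(o * H * W)] <-
        (j + dj - 1L) * Hp + (i + di)
    }
  }
  used <- sort(unique(samp_all))
  pool <- NULL
  if (H %% 2 == 0 && W %% 2 == 0) {
    h2 <- H %/% 2L
    w2 <- W %/% 2L
    oi <- rep(seq_len(h2), w2)
    oj <- rep(seq_len(w2), each = h2)
    pool <- cbind(
      (2L * oj - 2L) * H + (2L * oi - 1L),
      (2L * oj - 2L) * H + (2L * oi),
      (2L * oj - 1L) * H + (2L * oi - 1L),
      (2L * oj - 1L) * H + (2L * oi)
    )
  }
  # Nearest upsample x2: source row for each output pixel of the 2H x 2W map.
  ui <- rep(seq_len(2L * H), 2L * W)
  uj <- rep(seq_len(2L * W), each = 2L * H)
  up_src <- (ceiling(uj / 2) - 1L) * H + ceiling(ui / 2)
  g <- list(H = H, W = W, interior = interior, samp_all = samp_all,
            used = used, pool = pool, up_src = up_src)
  .geom_cache[[key]] <- g
  g
}

conv3_forward <- function(x, Wm, b, geom) {
  C <- ncol(x)
  n <- geom$H * geom$W
  xp <- matrix(0, (geom$H + 2L) * (geom$W + 2L), C)
  xp[geom$interior, ] <- x
  cols <- xp[geom$samp_all, , drop = FALSE]
  dim(cols) <- c(n, 9L * C)
  out <- cols %*% Wm
  out <- out + rep(b, each = n)
  list(out = out, cols = cols)
}

conv3_backward <- function(dout, cols, Wm, C, geom) {
  dW <- crossprod(cols, dout)
  db <- colSums(dout)
  dcols <- dout %*% t(Wm)
  dim(dcols) <- c(9L * geom$H * geom$W, C)
  acc <- rowsum(dcols, group = geom$samp_all)
  dxp <- matrix(0, (geom$H + 2L) * (geom$W + 2L), C)
  dxp[geom$used, ] <- acc
  list(dx = dxp[geom$interior, , drop = FALSE], dW = dW, db = db)
}

conv1_forward <- function(x, Wm, b) {
  out <- x %*% Wm
  out <- out + rep(b, each = nrow(out))
  list(out = out, x = x)
}

conv1_backward <- function(dout, x, Wm) {
  list(dx = dout %*% t(Wm), dW = crossprod(x, dout), db = colSums(dout))
}

relu_forward <- function(x) {
  keep <- x > 0
  x[!keep] <- 0
  list(out = x, keep = keep)
}

relu_backward <- function(dout, keep) {
  dout[!keep] <- 0
  dout
}

maxpool_forward <- function(x, geom) {
  idx <- geom$pool
  out <- x[idx[, 1], , drop = FALSE]
  am <- matrix(1L, nrow(out), ncol(out))
  for (k in 2:4) {
    cand <- x[idx[, k], , drop = FALSE]
    # which() drops NA comparisons so non-finite activations propagate to
    # the loss (where divergence is diagnosed) instead of crashing here
    upd <- which(cand > out)
    out[upd] <- cand[upd]
    am[upd] <- k
  }
  list(out = out, argmax = am)
}

maxpool_backward <- function(dout, argmax, geom, n_in) {
  dx <- matrix(0, n_in, ncol(dout))
  idx <- geom$pool
  for (k in 1:4) {
    sel <- argmax == k
    g <- dout
    g[!sel] <- 0
    tgt <- idx[, k]
    dx[tgt, ] <- dx[tgt, ] + g
  }
  dx
}

upsample_forward <- function(x, geom) {
  x[geom$up_src, , drop = FALSE]
}

upsample_backward <- function(dout, geom) {
  out <- rowsum(dout, group = geom$up_src)
  # rowsum orders by sorted group labels 1..H*W, matching source rows
  out
}

sigmoid <- function(z) 1 / (1 + exp(-z))
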