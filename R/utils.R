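# Internal helpers shared across modules.

abort_myo <- function(message, class = "myoinvade_error", ...) {
  rlang::abort(message, class = c(class, "myoinvade_error"), ...)
}

assert_same_shape <- function(a, b, what_a = "first input", what_b = "second input") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    abort_myo(sprintf(
      "shape mismatch: %s is %s but %s is %s",
      what_a, paste(da, collapse = "x"), what_b, paste(db, collapse = "x")
    ), class = "myoinvade_shape_error")
  }
  invisible(TRUE)
}

assert_binary_mask <- function(m, what = "mask") {
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1))) {
    abort_myo(sprintf("%s must be binary (0/1); found other values", what))
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Deterministic per-stage child seeds below 2^31, so independent pipeline
# stages do not share RNG streams.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    phantom = 101L, cohort = 211L, split = 307L, augment = 401L,
    init = 503L, train = 601L, staging = 701L, stats = 809L
  )
  off <- offsets[[stage]] %||% 907L
  as.integer((abs(as.numeric(seed)) * 2654435 + off * 97) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Wrap angular difference into (-pi, pi].
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

# Largest connected component of a binary mask (4/8-connectivity via EBImage).
largest_component <- function(mask) {
  if (sum(mask) == 0) return(mask)
  lab <- EBImage::bwlabel(mask)
  tab <- tabulate(lab[lab > 0])
  keep <- which.max(tab)
  out <- (lab == keep) * 1
  storage.mode(out) <- "double"
  out
}

n_components <- function(mask) {
  if (sum(mask) == 0) return(0L)
  as.integer(max(EBImage::bwlabel(mask)))
}
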