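# Internal neural-network primitives shared by the generator, discriminator,
# and the feature embedders. All image tensors are (H, W, C, N) arrays.

as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

conv2d <- function(x, w) cpp_conv2d(as_batch(x), w)

conv2d_bw <- function(x, w, dy, want_dx = TRUE, want_dw = TRUE) {
  cpp_conv2d_bw(as_batch(x), w, as_batch(dy), want_dx, want_dw)
}

down2 <- function(x) cpp_down2(as_batch(x))
down2_bw <- function(dy) cpp_down2_bw(as_batch(dy))
up2 <- function(x) cpp_up2(as_batch(x))
up2_bw <- function(dy) cpp_up2_bw(as_batch(dy))

# Leaky ReLU with slope 0.2 and the usual sqrt(2) variance-preserving gain.
lrelu <- function(x, gain = sqrt(2)) {
  neg <- x < 0
  y <- x
  y[neg] <- 0.2 * y[neg]
  list(y = y * gain, neg = neg)
}

lrelu_bw <- function(dy, neg, gain = sqrt(2)) {
  dx <- dy * gain
  dx[neg] <- 0.2 * dx[neg]
  dx
}

# Horizontal mirroring (left-right flip); its own adjoint.
mirror_lr <- function(x, idx = NULL) {
  x <- as_batch(x)
  W <- dim(x)[2]
  if (is.null(idx)) return(x[, W:1, , , drop = FALSE])
  if (length(idx) > 0) {
    flipped <- x[, W:1, , , drop = FALSE][, , , idx, drop = FALSE]
    x[, , , idx] <- flipped
  }
  x
}

# Equalized-learning-rate dense layer helpers. Raw weights are stored with
# init sd 1/lrmul; the effective weight is raw * lrmul / sqrt(fan_in).
dense_scale <- function(fan_in, lrmul = 1) lrmul / sqrt(fan_in)

dense_fw <- function(x, w_raw, b_raw, lrmul = 1) {
  # x: (fan_in, N); w_raw: (fan_in, fan_out)
  sc <- dense_scale(nrow(w_raw), lrmul)
  y <- crossprod(w_raw, x) * sc
  y + b_raw * lrmul
}

dense_bw <- function(x, w_raw, dy, lrmul = 1) {
  sc <- dense_scale(nrow(w_raw), lrmul)
  list(
    dx = (w_raw %*% dy) * sc,
    dw = (x %*% t(dy)) * sc,
    db = rowSums(dy) * lrmul
  )
}

conv_scale <- function(k, cin) 1 / sqrt(k * k * cin)

init_dense <- function(fan_in, fan_out, lrmul = 1, bias_init = 0) {
  list(
    w = matrix(stats::rnorm(fan_in * fan_out, sd = 1 / lrmul), fan_in, fan_out),
    b = rep(bias_init / lrmul, fan_out)
  )
}

init_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout), dim = c(k, k, cin, cout))
}

# Minibatch standard-deviation channel (single group over the whole batch):
# appends one channel holding the mean over (h, w, c) of the per-location
# batch standard deviation.
mbstd_fw <- function(x, eps = 1e-8) {
  d <- dim(x)
  N <- d[4]
  mu <- apply(x, c(1, 2, 3), mean)
  varm <- apply(x, c(1, 2, 3), function(v) mean((v - mean(v))^2))
  stdm <- sqrt(varm + eps)
  s <- mean(stdm)
  out <- array(0, dim = c(d[1], d[2], d[3] + 1L, N))
  out[, , seq_len(d[3]), ] <- x
  out[, , d[3] + 1L, ] <- s
  list(y = out, mu = mu, stdm = stdm, x = x)
}

mbstd_bw <- function(dy, cache) {
  d <- dim(cache$x)
  N <- d[4]
  C <- d[3]
  dx <- dy[, , seq_len(C), , drop = FALSE]
  ds <- sum(dy[, , C + 1L, , drop = FALSE])
  # s = mean_{hwc} sqrt(var_{hwc} + eps); d s/d x_i(hwc) = (x_i - mu)/(N*std*HWC)
  HWC <- prod(d[1:3])
  coef <- ds / (N * HWC)
  centered <- sweep(cache$x, c(1, 2, 3), cache$mu, "-")
  dx + coef * sweep(centered, c(1, 2, 3), cache$stdm, "/")
}

# Adam with decoupled state kept in an environment keyed by parameter name.
adam_state <- function() new.env(parent = emptyenv())

adam_step <- function(params, grads, state, lr, beta1 = 0, beta2 = 0.99, eps = 1e-8) {
  state$t <- (if (is.null(state$t)) 0 else state$t) + 1
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    key_m <- paste0(nm, ".m")
    key_v <- paste0(nm, ".v")
    m <- if (is.null(state[[key_m]])) g * 0 else state[[key_m]]
    v <- if (is.null(state[[key_v]])) g * 0 else state[[key_v]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state[[key_m]] <- m
    state[[key_v]] <- v
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  params
}

# Accumulate a gradient into a named list.
acc_grad <- function(grads, nm, g) {
  if (is.null(grads[[nm]])) grads[[nm]] <- g else grads[[nm]] <- grads[[nm]] + g
  grads
}

# Run a closure with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
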