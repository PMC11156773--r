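# GAN inversion: optimize an extended latent code w+ and all per-layer noise
# injection maps so the synthesized image reconstructs a target. The
# initializer ranks random latent samples by SSIM against the target; the
# loss is a perceptual feature distance plus a heavily weighted noise
# autocorrelation regularizer; learning-rate and latent-noise schedules
# stabilize the Adam loop.

#' Projection configuration
#'
#' @param iterations Total Adam iterations (default 3000).
#' @param lr_max Peak learning rate (0.1).
#' @param lr_rampup_iters Cosine ramp 0 -> lr_max over the first iterations
#'   (50).
#' @param lr_rampdown_iters Cosine ramp lr_max -> 0 over the final iterations
#'   (250).
#' @param noise_ramp_iters Latent-noise ramp length (750): the noise factor
#'   t falls linearly from 1 to 0 over this many iterations.
#' @param noise_factor Scale of the additive latent noise (0.05); the
#'   standard deviation added to w is `noise_factor * sigma_w * t^2`.
#' @param reg_weight Weight c of the noise-map regularizer (1e5).
#' @param init_samples Number N of random latent samples used by the
#'   initializer (10000).
#' @param init_top_k Number of top-SSIM samples averaged into the initial w
#'   (100; 1 recovers single-best, `init_samples` recovers plain averaging).
#' @param adam_betas,adam_eps Adam moment parameters for the projection loop.
#' @param seed RNG seed covering initialization and the optimization loop.
#' @return A list of class `projection_config`.
#' @export
projection_config <- function(iterations = 3000L, lr_max = 0.1,
                              lr_rampup_iters = 50L, lr_rampdown_iters = 250L,
                              noise_ramp_iters = 750L, noise_factor = 0.05,
                              reg_weight = 1e5, init_samples = 10000L,
                              init_top_k = 100L, adam_betas = c(0, 0.99),
                              adam_eps = 1e-8, seed = 1L) {
  stopifnot(
    iterations >= 1, lr_rampup_iters + lr_rampdown_iters <= iterations,
    noise_ramp_iters <= iterations, lr_rampup_iters >= 0,
    lr_rampdown_iters >= 0, noise_ramp_iters >= 0,
    init_samples >= init_top_k, init_top_k >= 1
  )
  structure(list(
    iterations = as.integer(iterations), lr_max = lr_max,
    lr_rampup_iters = as.integer(lr_rampup_iters),
    lr_rampdown_iters = as.integer(lr_rampdown_iters),
    noise_ramp_iters = as.integer(noise_ramp_iters),
    noise_factor = noise_factor, reg_weight = reg_weight,
    init_samples = as.integer(init_samples),
    init_top_k = as.integer(init_top_k),
    adam_betas = adam_betas, adam_eps = adam_eps, seed = as.integer(seed)
  ), class = "projection_config")
}

gaussian_kernel <- function(size = 11L, sigma = 1.5) {
  ax <- seq_len(size) - (size + 1) / 2
  g <- exp(-ax^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Filter every plane of a (H, W, P) stack with a single-channel kernel.
blur_planes <- function(x, kern) {
  d <- dim(x)
  k4 <- array(kern, dim = c(dim(kern), 1L, 1L))
  y <- conv2d(array(x, dim = c(d[1], d[2], 1L, prod(d) / (d[1] * d[2]))), k4)
  array(y, dim = d)
}

#' Structural similarity index
#'
#' Standard single-scale SSIM with K1 = 0.01, K2 = 0.03 and an 11x11
#' Gaussian window (sigma 1.5), averaged over pixels and channels.
#'
#' @param a,b Images of identical shape ((H, W) or (H, W, C)).
#' @param data_range Declared dynamic range of the intensities (1 for
#'   \[0, 1\] images).
#' @return Scalar in \[-1, 1\].
#' @export
ssim <- function(a, b, data_range = 1) {
  if (!identical(dim(a), dim(b))) stop("ssim: shape mismatch")
  k <- gaussian_kernel()
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  if (length(dim(a)) == 2) { dim(a) <- c(dim(a), 1L); dim(b) <- dim(a) }
  mu_a <- blur_planes(a, k); mu_b <- blur_planes(b, k)
  s_aa <- blur_planes(a * a, k) - mu_a^2
  s_bb <- blur_planes(b * b, k) - mu_b^2
  s_ab <- blur_planes(a * b, k) - mu_a * mu_b
  num <- (2 * mu_a * mu_b + c1) * (2 * s_ab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (s_aa + s_bb + c2)
  mean(num / den)
}

# Batched SSIM of one target against N candidate images (shared windows).
ssim_batch <- function(target, imgs) {
  d <- dim(imgs)   # (H, W, C, N)
  n <- d[4]
  k <- gaussian_kernel()
  c1 <- 0.01^2; c2 <- 0.03^2
  tg <- array(target, dim = c(d[1:3], 1L))
  mu_t <- blur_planes(tg, k)
  s_tt <- blur_planes(tg * tg, k) - mu_t^2
  mu_i <- blur_planes(imgs, k)
  s_ii <- blur_planes(imgs * imgs, k) - mu_i^2
  ti <- imgs * as.vector(tg)
  mu_ti <- blur_planes(ti, k)
  tgv <- as.vector(mu_t)
  s_ti <- mu_ti - mu_i * tgv
  num <- (2 * mu_i * tgv + c1) * (2 * s_ti + c2)
  den <- (mu_i^2 + as.vector(mu_t^2) + c1) * (s_ii + as.vector(s_tt) + c2)
  colMeans(matrix(num / den, ncol = n))
}

#' SSIM-ranked latent initialization
#'
#' Draws N latent codes z ~ N(0, I), maps them through the mapping network,
#' synthesizes each with zero injection noise, and ranks the images by SSIM
#' against the target. The initial latent is the mean of the top-k w codes;
#' `sigma_w` is the scalar spread (root mean per-component variance) of all
#' N sampled w, used to scale the stabilizing latent noise.
#'
#' @param model A `generator_model`.
#' @param target (H, W, C) intensity image in \[0, 1\] matching the model
#'   resolution.
#' @param config A [projection_config()].
#' @return List with `init_w` (length-d vector) and `sigma_w` (scalar).
#' @export
init_latent <- function(model, target, config = projection_config()) {
  if (config$init_samples < config$init_top_k) stop("init_samples < init_top_k")
  if (!all(dim(target)[1:2] == model$res)) {
    stop("target resolution does not match model")
  }
  with_seed(config$seed, {
    N <- config$init_samples
    z <- matrix(stats::rnorm(model$d * N), model$d, N)
    w <- map_forward(model, z)$w
    scores <- numeric(N)
    chunk <- 256L
    for (start in seq(1L, N, by = chunk)) {
      idx <- start:min(start + chunk - 1L, N)
      wp <- array(0, dim = c(model$L, model$d, length(idx)))
      for (s in seq_len(model$L)) wp[s, , ] <- w[, idx]
      imgs <- synth_to_intensity(synth_forward(model, wp, "zero")$img)
      scores[idx] <- ssim_batch(target, imgs)
    }
    top <- order(scores, decreasing = TRUE)[seq_len(config$init_top_k)]
    init_w <- rowMeans(w[, top, drop = FALSE])
    sigma_w <- sqrt(mean(apply(w, 1, stats::var)))
    list(init_w = init_w, sigma_w = sigma_w, scores = scores)
  })
}

#' Random multi-scale convolutional embedder for the perceptual loss
#'
#' The feature stack at each dyadic scale (full, half, quarter resolution)
#' consists of the image plane itself — the Gaussian-style image pyramid —
#' plus fixed-seed random 3x3 convolution features with a leaky-ReLU
#' nonlinearity. The pyramid levels anchor the distance at every pixel and
#' scale (including image borders, which windowed features under-weight);
#' the random projections add phase/structure sensitivity. A pretrained
#' backbone can be substituted through the same interface.
#'
#' @param img_channels Image channels.
#' @param width Random feature channels per scale.
#' @param n_scales Number of dyadic scales.
#' @param seed Seed fixing the random weights.
#' @return A list with `forward(x, keep)` and `backward(cache, dfeats)`
#'   functions.
#' @export
perceptual_embedder <- function(img_channels = 3L, width = 24L,
                                n_scales = 3L, seed = 11L) {
  ws <- with_seed(seed, lapply(seq_len(n_scales), function(i) {
    init_conv(3L, img_channels, width)
  }))
  sc <- conv_scale(3, img_channels)
  forward <- function(x, keep = FALSE) {
    x <- as_batch(x)
    feats <- vector("list", 2L * n_scales)
    cache <- if (keep) list(xs = vector("list", n_scales),
                            negs = vector("list", n_scales)) else NULL
    for (i in seq_len(n_scales)) {
      if (i > 1) x <- down2(x)
      feats[[2L * i - 1L]] <- x            # pyramid level
      h <- conv2d(x, ws[[i]] * sc)
      lr <- lrelu(h)
      feats[[2L * i]] <- lr$y              # random conv features
      if (keep) { cache$xs[[i]] <- x; cache$negs[[i]] <- lr$neg }
    }
    list(feats = feats, cache = cache)
  }
  backward <- function(cache, dfeats) {
    dx_total <- NULL
    for (i in rev(seq_len(n_scales))) {
      dh <- lrelu_bw(dfeats[[2L * i]], cache$negs[[i]])
      dx <- conv2d_bw(cache$xs[[i]], ws[[i]] * sc, dh, want_dw = FALSE)$dx
      dx <- dx + dfeats[[2L * i - 1L]]
      if (!is.null(dx_total)) dx <- dx + dx_total
      dx_total <- if (i > 1) down2_bw(dx) else dx
    }
    dx_total
  }
  list(forward = forward, backward = backward, width = width,
       n_scales = n_scales, seed = seed)
}

#' Perceptual feature distance
#'
#' Sum over all embedder feature maps of the squared feature differences
#' between two images — the image-quality term of the projection loss.
#'
#' @param a,b Images of identical shape.
#' @param embedder A [perceptual_embedder()] (or compatible backbone).
#' @return Non-negative scalar.
#' @export
perceptual_distance <- function(a, b, embedder = perceptual_embedder()) {
  if (!identical(dim(a), dim(b))) stop("perceptual_distance: shape mismatch")
  fa <- embedder$forward(a)$feats
  fb <- embedder$forward(b)$feats
  sum(vapply(seq_along(fa), function(i) sum((fa[[i]] - fb[[i]])^2),
             numeric(1)))
}

# Perceptual distance plus gradient with respect to b.
perceptual_with_grad <- function(a_feats, b, embedder) {
  fwd <- embedder$forward(b, keep = TRUE)
  dfeats <- vector("list", length(a_feats))
  val <- 0
  for (i in seq_along(a_feats)) {
    diff <- fwd$feats[[i]] - a_feats[[i]]
    val <- val + sum(diff^2)
    dfeats[[i]] <- 2 * diff
  }
  list(value = val, grad = embedder$backward(fwd$cache, dfeats))
}

shift_circ <- function(p, dr, dc) {
  n <- nrow(p); m <- ncol(p)
  ri <- ((seq_len(n) - 1 - dr) %% n) + 1
  ci <- ((seq_len(m) - 1 - dc) %% m) + 1
  p[ri, ci, drop = FALSE]
}

#' Noise-map autocorrelation regularizer
#'
#' For each noise map, builds a pyramid by repeated 2x average pooling (with
#' 2x amplitude compensation so unit-variance noise stays unit-variance)
#' down to 8x8, and at every level accumulates the squared
#' resolution-normalized lag-1 autocorrelations with circular horizontal and
#' vertical shifts:
#' \eqn{(1/r^2)(\sum p \cdot p_{x-1})^2 + (1/r^2)(\sum p \cdot p_{y-1})^2}.
#' White noise gives a value near zero; structured maps are penalized.
#'
#' @param stack List of square noise matrices, each at least 8x8.
#' @return Non-negative scalar total over all maps and pyramid levels.
#' @export
noise_reg <- function(stack) {
  if (!is.list(stack)) stack <- list(stack)
  total <- 0
  for (p in stack) {
    p <- as.matrix(p)
    if (nrow(p) < 8 || ncol(p) < 8) stop("noise map smaller than 8x8")
    repeat {
      r2 <- length(p)
      ax <- sum(p * shift_circ(p, 0, 1))
      ay <- sum(p * shift_circ(p, 1, 0))
      total <- total + (ax^2 + ay^2) / r2
      if (nrow(p) <= 8) break
      p <- down2(array(p, dim = c(dim(p), 1L, 1L)))[, , 1, 1] * 2
    }
  }
  total
}

# Gradients of noise_reg with respect to each map in the stack.
noise_reg_grad <- function(stack) {
  lapply(stack, function(p0) {
    p0 <- as.matrix(p0)
    levels <- list(p0)
    while (nrow(levels[[length(levels)]]) > 8) {
      pl <- levels[[length(levels)]]
      levels[[length(levels) + 1]] <-
        down2(array(pl, dim = c(dim(pl), 1L, 1L)))[, , 1, 1] * 2
    }
    dlev <- vector("list", length(levels))
    for (j in seq_along(levels)) {
      p <- levels[[j]]
      r2 <- length(p)
      ax <- sum(p * shift_circ(p, 0, 1))
      ay <- sum(p * shift_circ(p, 1, 0))
      dlev[[j]] <- (2 * ax / r2) * (shift_circ(p, 0, 1) + shift_circ(p, 0, -1)) +
                   (2 * ay / r2) * (shift_circ(p, 1, 0) + shift_circ(p, -1, 0))
    }
    g <- dlev[[length(dlev)]]
    for (j in rev(seq_len(length(levels) - 1))) {
      gb <- down2_bw(array(g, dim = c(dim(g), 1L, 1L)))[, , 1, 1] * 2
      g <- dlev[[j]] + gb
    }
    g
  })
}

#' Projection learning-rate schedule
#'
#' Cosine half-wave ramp from 0 to `lr_max` over the first
#' `lr_rampup_iters` iterations, a constant plateau, and a cosine ramp back
#' to 0 over the final `lr_rampdown_iters` iterations.
#'
#' @param iter Zero-based iteration index in `[0, iterations)`.
#' @param config A [projection_config()].
#' @return Learning rate.
#' @export
lr_schedule <- function(iter, config) {
  it <- config$iterations
  if (any(iter < 0 | iter >= it)) stop("iter out of range")
  lr <- rep(config$lr_max, length(iter))
  up <- iter < config$lr_rampup_iters
  lr[up] <- config$lr_max * 0.5 *
    (1 - cos(pi * iter[up] / config$lr_rampup_iters))
  dn_start <- it - config$lr_rampdown_iters
  dn <- iter >= dn_start
  tdn <- (iter[dn] - dn_start) / max(config$lr_rampdown_iters - 1, 1)
  lr[dn] <- pmin(lr[dn], config$lr_max * 0.5 * (1 + cos(pi * tdn)))
  lr
}

#' Adaptive latent-noise standard deviation
#'
#' The stabilizing Gaussian noise added to w has standard deviation
#' `noise_factor * sigma_w * t^2` with t falling linearly from 1 to 0 over
#' the first `noise_ramp_iters` iterations.
#'
#' @param iter Zero-based iteration index (>= 0).
#' @param sigma_w Scalar latent spread from [init_latent()].
#' @param config A [projection_config()].
#' @return Standard deviation (0 from `noise_ramp_iters` onward).
#' @export
latent_noise_std <- function(iter, sigma_w, config) {
  if (any(iter < 0)) stop("iter must be >= 0")
  if (config$noise_ramp_iters == 0) return(rep(0, length(iter)))
  t <- pmax(0, 1 - iter / config$noise_ramp_iters)
  config$noise_factor * sigma_w * t^2
}

#' Project an image into extended latent space
#'
#' Joint Adam optimization of the extended latent code w+ (initialized by
#' broadcasting the SSIM-ranked initial w to all style layers) and all noise
#' injection maps, minimizing perceptual distance plus the weighted noise
#' regularizer. Per iteration: scheduled Gaussian noise is added to w+, the
#' learning rate follows [lr_schedule()], and after the update every noise
#' map is renormalized to zero mean and unit variance. Noise maps smaller
#' than 8x8 are optimized but excluded from the regularizer.
#'
#' @param model A `generator_model`.
#' @param target (H, W, C) intensity image in \[0, 1\] (or a `phantom`).
#' @param config A [projection_config()].
#' @param embedder Perceptual embedder (default [perceptual_embedder()]).
#' @return Object of class `projection_result`: `wplus` (L x d), `noise_maps`
#'   (list of matrices), `loss_trace` (data frame with total, perceptual and
#'   regularization columns per iteration), `init_w`, `sigma_w`.
#' @export
project_image <- function(model, target, config = projection_config(),
                          embedder = perceptual_embedder(model$img_channels)) {
  if (inherits(target, "phantom")) target <- target$channels
  if (!all(dim(target) == c(model$res, model$res, model$img_channels))) {
    stop("target shape does not match model resolution/channels")
  }
  ini <- init_latent(model, target, config)
  target_s <- intensity_to_synth(target)
  a_feats <- embedder$forward(target_s)$feats
  reg_idx <- which(model$noise_res >= 8)
  with_seed(config$seed + 1L, {
    L <- model$L; d <- model$d
    wplus <- matrix(ini$init_w, L, d, byrow = TRUE)
    maps <- lapply(model$noise_res, function(r) matrix(stats::rnorm(r * r), r, r))
    maps <- lapply(maps, function(m) (m - mean(m)) / stats::sd(m))
    opt <- adam_state()
    b1 <- config$adam_betas[1]; b2 <- config$adam_betas[2]
    trace <- matrix(NA_real_, config$iterations, 3,
                    dimnames = list(NULL, c("total", "perceptual", "regularization")))
    for (it in seq_len(config$iterations)) {
      std <- latent_noise_std(it - 1, ini$sigma_w, config)
      w_in <- wplus + matrix(stats::rnorm(L * d, sd = max(std, 0)), L, d)
      fwd <- synth_forward(model, w_in,
                           lapply(maps, function(m) array(m, dim = c(dim(m), 1L))),
                           keep = TRUE)
      img <- fwd$img
      pg <- perceptual_with_grad(a_feats, img, embedder)
      reg <- noise_reg(maps[reg_idx])
      total <- pg$value + config$reg_weight * reg
      if (!is.finite(total)) {
        stop(sprintf("non-finite projection loss at iteration %d (perceptual %.3g, reg %.3g)",
                     it, pg$value, reg))
      }
      trace[it, ] <- c(total, pg$value, config$reg_weight * reg)
      sbw <- synth_backward(model, fwd, pg$grad,
                            want_params = FALSE, want_noise = TRUE)
      grads <- list(wplus = matrix(sbw$dwplus, L, d))
      for (i in seq_along(maps)) {
        grads[[paste0("n", i)]] <- matrix(sbw$dnoise[[i]], nrow(maps[[i]]), ncol(maps[[i]]))
      }
      rg <- noise_reg_grad(maps[reg_idx])
      for (j in seq_along(reg_idx)) {
        i <- reg_idx[j]
        grads[[paste0("n", i)]] <- grads[[paste0("n", i)]] + config$reg_weight * rg[[j]]
      }
      params <- c(list(wplus = wplus),
                  stats::setNames(maps, paste0("n", seq_along(maps))))
      params <- adam_step(params, grads, opt, lr_schedule(it - 1, config),
                          b1, b2, config$adam_eps)
      wplus <- params$wplus
      maps <- lapply(seq_along(maps), function(i) {
        m <- params[[paste0("n", i)]]
        m <- m - mean(m)
        m / sqrt(mean(m^2))
      })
    }
    structure(list(
      wplus = wplus, noise_maps = maps,
      loss_trace = as.data.frame(trace),
      init_w = ini$init_w, sigma_w = ini$sigma_w, config = config
    ), class = "projection_result")
  })
}

#' @export
print.projection_result <- function(x, ...) {
  n <- nrow(x$loss_trace)
  cat(sprintf(
    "projection_result: %d iterations, loss %.4g -> %.4g (perceptual %.4g -> %.4g)\n",
    n, x$loss_trace$total[1], x$loss_trace$total[n],
    x$loss_trace$perceptual[1], x$loss_trace$perceptual[n]
  ))
  invisible(x)
}
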