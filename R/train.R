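# Adversarial training: non-saturating logistic losses, lazy R1 gradient
# penalty, adaptive discriminator augmentation restricted to horizontal
# mirroring, Adam for both networks.

#' Training configuration
#'
#' Hyperparameters for [gan_train()]. Defaults follow the training recipe the
#' package targets: learning rate 0.0025 for generator and discriminator,
#' Adam with beta = (0, 0.99) and eps = 1e-8, non-saturating logistic loss
#' with R1 regularization, and adaptive discriminator augmentation (ADA)
#' using horizontal mirroring as the only augmentation.
#'
#' @param learning_rate Adam learning rate for both networks.
#' @param adam_betas Length-2 numeric, Adam (beta1, beta2).
#' @param adam_eps Adam epsilon.
#' @param r1_gamma R1 gradient-penalty weight.
#' @param r1_interval Apply the (lazily weighted) R1 term every this many
#'   discriminator steps.
#' @param ada_target Target value for the discriminator-overfitting statistic
#'   rt = E\[sign D(real)\].
#' @param ada_step Probability adjustment applied per controller update. If
#'   `NULL`, sized so p can traverse \[0, 1\] in `ada_kimg` thousand images.
#' @param ada_kimg Traversal scale used when `ada_step` is `NULL`.
#' @param mirror_augment Enable ADA mirroring.
#' @param kimg_budget Training length in thousands of (real) images shown.
#' @param batch_size Minibatch size.
#' @param fid_interval Evaluate the Fréchet feature distance every this many
#'   steps (0 disables evaluation during training).
#' @param fid_samples Number of real/generated samples per evaluation.
#' @param seed Integer RNG seed for the whole run.
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.0025, adam_betas = c(0, 0.99),
                         adam_eps = 1e-8, r1_gamma = 1, r1_interval = 16L,
                         ada_target = 0.6, ada_step = NULL, ada_kimg = 500,
                         mirror_augment = TRUE, kimg_budget = 10,
                         batch_size = 16L, fid_interval = 0L,
                         fid_samples = 128L, seed = 1L) {
  if (is.null(ada_step)) ada_step <- batch_size / (ada_kimg * 1000)
  structure(list(
    learning_rate = learning_rate, adam_betas = adam_betas,
    adam_eps = adam_eps, r1_gamma = r1_gamma,
    r1_interval = as.integer(r1_interval), ada_target = ada_target,
    ada_step = ada_step, mirror_augment = isTRUE(mirror_augment),
    kimg_budget = kimg_budget, batch_size = as.integer(batch_size),
    fid_interval = as.integer(fid_interval),
    fid_samples = as.integer(fid_samples), seed = as.integer(seed)
  ), class = "train_config")
}

#' ADA probability controller step
#'
#' Adjusts the augmentation probability: increase by `ada_step` when the
#' overfitting statistic exceeds its target, decrease otherwise; the result
#' is clamped to \[0, 1\].
#'
#' @param p Current augmentation probability in \[0, 1\].
#' @param rt Signed overfitting statistic (mean sign of the discriminator
#'   output on real minibatches).
#' @param config A [train_config()].
#' @return Updated probability in \[0, 1\].
#' @export
ada_controller_step <- function(p, rt, config) {
  stopifnot(p >= 0, p <= 1)
  p <- p + if (rt > config$ada_target) config$ada_step else -config$ada_step
  min(max(p, 0), 1)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
sigmoid <- function(x) 1 / (1 + exp(-x))

disc_input_grad <- function(d, x) {
  if (inherits(d, "discriminator_model")) {
    fwd <- disc_forward(d, x, keep = TRUE)
    disc_backward(d, fwd, rep(1, fwd$n), want_dx = TRUE,
                  want_params = FALSE)$dx
  } else if (is.list(d) && is.function(d$grad)) {
    d$grad(x)
  } else {
    stop("d must be a discriminator_model or a list with a grad() function")
  }
}

#' R1 gradient penalty
#'
#' Computes \eqn{(\gamma/2)\, E[\lVert \nabla_x D(x) \rVert^2]} over a batch
#' of real images — the R1 regularizer attached to the logistic GAN loss.
#'
#' @param d A `discriminator_model`, or a list with functions `score(x)` and
#'   `grad(x)` (gradient of the summed score with respect to the input) for
#'   analytically known discriminators.
#' @param real_images (H, W, C, N) array.
#' @param gamma Penalty weight.
#' @return Scalar penalty value.
#' @export
r1_penalty <- function(d, real_images, gamma = 1) {
  x <- as_batch(real_images)
  g <- disc_input_grad(d, x)
  n <- dim(x)[4]
  per_sample <- colSums(matrix(g^2, ncol = n))
  gamma / 2 * mean(per_sample)
}

# Parameter gradient of the lazily weighted R1 term via a central-difference
# Hessian-vector product (two first-order backward passes; exact up to finite
# difference error for the piecewise-linear discriminator).
r1_param_grads <- function(D, x, gamma, interval) {
  n <- dim(x)[4]
  fwd <- disc_forward(D, x, keep = TRUE)
  g <- disc_backward(D, fwd, rep(1, n), want_dx = TRUE, want_params = FALSE)$dx
  rms <- sqrt(mean(g^2))
  if (rms < 1e-12) return(NULL)
  eps <- 1e-3 / rms
  fp <- disc_forward(D, x + eps * g, keep = TRUE)
  gp <- disc_backward(D, fp, rep(1, n), want_params = TRUE)$grads
  fm <- disc_forward(D, x - eps * g, keep = TRUE)
  gm <- disc_backward(D, fm, rep(1, n), want_params = TRUE)$grads
  scale <- gamma * interval / (2 * eps * n)
  out <- list()
  for (nm in names(gp)) out[[nm]] <- (gp[[nm]] - gm[[nm]]) * scale
  attr(out, "penalty") <- gamma / 2 * mean(colSums(matrix(g^2, ncol = n)))
  out
}

coerce_image_stack <- function(images) {
  if (is.list(images)) {
    if (length(images) == 0) stop("empty dataset")
    dims <- unique(lapply(images, function(x) dim(as_batch(x))[1:3]))
    if (length(dims) != 1) stop("mixed resolutions in dataset")
    arr <- array(0, dim = c(dims[[1]], length(images)))
    for (i in seq_along(images)) arr[, , , i] <- images[[i]]
    arr
  } else {
    as_batch(images)
  }
}

#' Train the style-based GAN
#'
#' Alternating generator/discriminator Adam steps with non-saturating
#' logistic losses, lazy R1 regularization, and ADA-controlled horizontal
#' mirroring. Input images are intensity rasters in \[0, 1\] and are mapped
#' internally to the generator's signed output range.
#'
#' @param images List of (H, W, C) arrays or an (H, W, C, N) array; all the
#'   same power-of-two resolution.
#' @param config A [train_config()].
#' @param d Latent dimensionality.
#' @param channels Optional channel-width map (see [generator_model()]).
#' @param embedder Feature embedder for the Fréchet metric (defaults to
#'   [fid_embedder()]) when `fid_interval > 0`.
#' @param verbose Print progress lines.
#' @return List with elements `model` (the generator), `discriminator`, and
#'   `history` (a data frame of per-step losses, ADA probability, and
#'   periodic Fréchet distances).
#' @export
gan_train <- function(images, config = train_config(), d = 64L,
                      channels = NULL, embedder = NULL, verbose = FALSE) {
  x_all <- coerce_image_stack(images)
  dims <- dim(x_all)
  res <- dims[1]
  if (dims[1] != dims[2]) stop("images must be square")
  if (res < 8 || log2(res) != round(log2(res))) {
    stop("resolution must be a power of two >= 8")
  }
  n_data <- dims[4]
  if (n_data < 1) stop("empty dataset")
  x_all <- intensity_to_synth(x_all)

  set.seed(config$seed)
  G <- generator_model(res = res, d = d, img_channels = dims[3],
                       channels = channels, seed = config$seed + 1L)
  D <- discriminator_model(res = res, img_channels = dims[3],
                           channels = channels, seed = config$seed + 2L)
  opt_g <- adam_state()
  opt_d <- adam_state()
  b1 <- config$adam_betas[1]; b2 <- config$adam_betas[2]
  B <- min(config$batch_size, n_data)
  steps <- max(1L, ceiling(config$kimg_budget * 1000 / B))
  ada_p <- 0
  if (config$fid_interval > 0 && is.null(embedder)) embedder <- fid_embedder()

  hist <- list()
  fid_log <- list()
  sample_fakes <- function(n) {
    z <- matrix(stats::rnorm(G$d * n), G$d, n)
    w <- map_forward(G, z)$w
    wp <- array(0, dim = c(G$L, G$d, n))
    for (s in seq_len(G$L)) wp[s, , ] <- w
    synth_forward(G, wp, "random")$img
  }
  eval_fid <- function() {
    nfid <- min(config$fid_samples, n_data)
    xr <- x_all[, , , sample.int(n_data, nfid), drop = FALSE]
    xf <- sample_fakes(nfid)
    fid_score(synth_to_intensity(xr), synth_to_intensity(xf), embedder)
  }
  if (config$fid_interval > 0) {
    fid_log[[length(fid_log) + 1]] <- c(step = 0, fid = eval_fid())
  }

  for (step in seq_len(steps)) {
    idx <- sample.int(n_data, B, replace = n_data < B)
    xr <- x_all[, , , idx, drop = FALSE]

    # --- discriminator step ---
    z <- matrix(stats::rnorm(G$d * B), G$d, B)
    w <- map_forward(G, z)$w
    wp <- array(0, dim = c(G$L, G$d, B))
    for (s in seq_len(G$L)) wp[s, , ] <- w
    xf <- synth_forward(G, wp, "random")$img
    if (config$mirror_augment && ada_p > 0) {
      xr_in <- mirror_lr(xr, which(stats::runif(B) < ada_p))
      xf_in <- mirror_lr(xf, which(stats::runif(B) < ada_p))
    } else {
      xr_in <- xr; xf_in <- xf
    }
    fr <- disc_forward(D, xr_in, keep = TRUE)
    ff <- disc_forward(D, xf_in, keep = TRUE)
    d_loss <- mean(softplus(-fr$score)) + mean(softplus(ff$score))
    gr_r <- disc_backward(D, fr, -sigmoid(-fr$score) / B)$grads
    gr_f <- disc_backward(D, ff, sigmoid(ff$score) / B)$grads
    grads_d <- gr_r
    for (nm in names(gr_f)) grads_d[[nm]] <- grads_d[[nm]] + gr_f[[nm]]
    r1_val <- NA_real_
    if (config$r1_gamma > 0 && step %% config$r1_interval == 0) {
      r1g <- r1_param_grads(D, xr_in, config$r1_gamma, config$r1_interval)
      if (!is.null(r1g)) {
        r1_val <- attr(r1g, "penalty")
        for (nm in names(r1g)) grads_d[[nm]] <- grads_d[[nm]] + r1g[[nm]]
      }
    }
    D$params <- adam_step(D$params, grads_d, opt_d, config$learning_rate,
                          b1, b2, config$adam_eps)

    # ADA controller
    rt <- mean(sign(fr$score))
    if (config$mirror_augment) {
      ada_p <- ada_controller_step(ada_p, rt, config)
    }

    # --- generator step ---
    z <- matrix(stats::rnorm(G$d * B), G$d, B)
    mp <- map_forward(G, z, keep = TRUE)
    wp <- array(0, dim = c(G$L, G$d, B))
    for (s in seq_len(G$L)) wp[s, , ] <- mp$w
    sf <- synth_forward(G, wp, "random", keep = TRUE)
    flip_idx <- if (config$mirror_augment && ada_p > 0) {
      which(stats::runif(B) < ada_p)
    } else integer(0)
    xg <- mirror_lr(sf$img, flip_idx)
    fg <- disc_forward(D, xg, keep = TRUE)
    g_loss <- mean(softplus(-fg$score))
    dimg <- disc_backward(D, fg, -sigmoid(-fg$score) / B, want_dx = TRUE,
                          want_params = FALSE)$dx
    dimg <- mirror_lr(dimg, flip_idx)
    sbw <- synth_backward(G, sf, dimg, want_params = TRUE)
    dw <- apply(sbw$dwplus, c(2, 3), sum)
    grads_g <- c(sbw$grads, map_backward(G, mp$cache, dw))
    G$params <- adam_step(G$params, grads_g, opt_g, config$learning_rate,
                          b1, b2, config$adam_eps)

    if (!all(is.finite(c(d_loss, g_loss)))) {
      stop(sprintf("non-finite loss at step %d", step))
    }
    hist[[step]] <- c(step = step, d_loss = d_loss, g_loss = g_loss,
                      r1 = r1_val, ada_p = ada_p, rt = rt)
    if (config$fid_interval > 0 && step %% config$fid_interval == 0) {
      fid_log[[length(fid_log) + 1]] <- c(step = step, fid = eval_fid())
    }
    if (verbose && step %% 25 == 0) {
      message(sprintf("step %d/%d  d=%.3f g=%.3f p=%.3f",
                      step, steps, d_loss, g_loss, ada_p))
    }
  }
  if (config$fid_interval > 0 &&
      fid_log[[length(fid_log)]]["step"] < steps) {
    fid_log[[length(fid_log) + 1]] <- c(step = steps, fid = eval_fid())
  }
  list(
    model = G, discriminator = D,
    history = as.data.frame(do.call(rbind, hist)),
    fid_history = if (length(fid_log)) {
      as.data.frame(do.call(rbind, fid_log))
    } else NULL,
    config = config
  )
}
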