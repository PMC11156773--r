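# Residual discriminator mirroring the synthesis network: fromRGB, residual
# downsampling blocks to 4x4, a minibatch standard-deviation channel, and two
# dense layers producing a single logit per image.

build_disc_layers <- function(res, channels) {
  ch <- function(r) channels[[as.character(r)]]
  blocks <- list()
  r <- res
  while (r > 4) {
    blocks[[length(blocks) + 1]] <- list(
      name = sprintf("d%d", r), res = as.integer(r),
      cin = ch(r), cout = ch(r / 2)
    )
    r <- r / 2
  }
  blocks
}

#' Create a discriminator model
#'
#' Residual convolutional discriminator for the adversarial training loop:
#' 1x1 fromRGB, residual blocks that halve resolution down to 4x4 (skip path:
#' average-pool + 1x1 convolution), a minibatch standard-deviation channel,
#' and dense layers to a scalar logit.
#'
#' @inheritParams generator_model
#' @return An object of class `discriminator_model`.
#' @export
discriminator_model <- function(res = 32L, img_channels = 3L,
                                channels = NULL, seed = 2L) {
  if (res < 8 || log2(res) != round(log2(res))) {
    stop("res must be a power of two >= 8")
  }
  if (is.null(channels)) channels <- default_channels(res)
  blocks <- build_disc_layers(res, channels)
  ch4 <- channels[["4"]]
  params <- list()
  with_seed(seed, {
    params[["fromrgb.w"]] <- init_conv(1L, img_channels, channels[[as.character(res)]])
    params[["fromrgb.b"]] <- rep(0, channels[[as.character(res)]])
    for (b in blocks) {
      params[[paste0(b$name, ".conv0.w")]] <- init_conv(3L, b$cin, b$cin)
      params[[paste0(b$name, ".conv0.b")]] <- rep(0, b$cin)
      params[[paste0(b$name, ".conv1.w")]] <- init_conv(3L, b$cin, b$cout)
      params[[paste0(b$name, ".conv1.b")]] <- rep(0, b$cout)
      params[[paste0(b$name, ".skip.w")]] <- init_conv(1L, b$cin, b$cout)
    }
    params[["final.conv.w"]] <- init_conv(3L, ch4 + 1L, ch4)
    params[["final.conv.b"]] <- rep(0, ch4)
    fc1 <- init_dense(16L * ch4, ch4)
    params[["final.fc1.w"]] <- fc1$w
    params[["final.fc1.b"]] <- fc1$b
    fc2 <- init_dense(ch4, 1L)
    params[["final.fc2.w"]] <- fc2$w
    params[["final.fc2.b"]] <- fc2$b
  })
  structure(list(
    res = as.integer(res), img_channels = as.integer(img_channels),
    channels = channels, blocks = blocks, params = params, version = "1"
  ), class = "discriminator_model")
}

#' @export
print.discriminator_model <- function(x, ...) {
  cat(sprintf("discriminator_model: %dx%d input, %d residual blocks\n",
              x$res, x$res, length(x$blocks)))
  invisible(x)
}

disc_forward <- function(D, x, keep = FALSE) {
  p <- D$params
  x <- as_batch(x)
  n <- dim(x)[4]
  cache <- if (keep) list(x_in = x) else NULL
  y <- conv2d(x, p[["fromrgb.w"]] * conv_scale(1, D$img_channels))
  y <- badd(y, p[["fromrgb.b"]])
  lr <- lrelu(y)
  if (keep) cache$fromrgb_neg <- lr$neg
  x <- lr$y
  if (keep) cache$blocks <- vector("list", length(D$blocks))
  for (bi in seq_along(D$blocks)) {
    b <- D$blocks[[bi]]
    bc <- list(x_in = x)
    y0 <- conv2d(x, p[[paste0(b$name, ".conv0.w")]] * conv_scale(3, b$cin))
    y0 <- badd(y0, p[[paste0(b$name, ".conv0.b")]])
    lr0 <- lrelu(y0)
    bc$neg0 <- lr0$neg
    bc$a0 <- lr0$y
    y1 <- conv2d(lr0$y, p[[paste0(b$name, ".conv1.w")]] * conv_scale(3, b$cin))
    y1 <- badd(y1, p[[paste0(b$name, ".conv1.b")]])
    lr1 <- lrelu(y1)
    bc$neg1 <- lr1$neg
    main <- down2(lr1$y)
    xd <- down2(x)
    bc$xd <- xd
    skip <- conv2d(xd, p[[paste0(b$name, ".skip.w")]] * conv_scale(1, b$cin))
    x <- (main + skip) / sqrt(2)
    if (keep) cache$blocks[[bi]] <- bc
  }
  mb <- mbstd_fw(x)
  if (keep) cache$mbstd <- mb
  y <- conv2d(mb$y, p[["final.conv.w"]] * conv_scale(3, dim(mb$y)[3]))
  y <- badd(y, p[["final.conv.b"]])
  lrf <- lrelu(y)
  if (keep) { cache$final_neg <- lrf$neg }
  flat <- matrix(lrf$y, ncol = n)
  if (keep) cache$flat <- flat
  h <- dense_fw(flat, p[["final.fc1.w"]], p[["final.fc1.b"]])
  lh <- lrelu(h)
  if (keep) { cache$fc1_neg <- lh$neg; cache$h <- lh$y }
  score <- dense_fw(lh$y, p[["final.fc2.w"]], p[["final.fc2.b"]])
  list(score = drop(score), cache = cache, n = n)
}

disc_backward <- function(D, fwd, dscore, want_dx = FALSE, want_params = TRUE) {
  p <- D$params
  cache <- fwd$cache
  n <- fwd$n
  grads <- list()
  dsc <- matrix(dscore, nrow = 1)
  bw2 <- dense_bw(cache$h, p[["final.fc2.w"]], dsc)
  if (want_params) {
    grads[["final.fc2.w"]] <- bw2$dw; grads[["final.fc2.b"]] <- bw2$db
  }
  dh <- lrelu_bw(bw2$dx, cache$fc1_neg)
  bw1 <- dense_bw(cache$flat, p[["final.fc1.w"]], dh)
  if (want_params) {
    grads[["final.fc1.w"]] <- bw1$dw; grads[["final.fc1.b"]] <- bw1$db
  }
  ch4 <- D$channels[["4"]]
  dconv_out <- array(bw1$dx, dim = c(4L, 4L, ch4, n))
  dconv_out <- lrelu_bw(dconv_out, cache$final_neg)
  if (want_params) {
    grads[["final.conv.b"]] <- rowSums(colSums(dconv_out, dims = 2))
  }
  cin_f <- dim(cache$mbstd$y)[3]
  bwf <- conv2d_bw(cache$mbstd$y, p[["final.conv.w"]] * conv_scale(3, cin_f),
                   dconv_out, want_dx = TRUE, want_dw = want_params)
  if (want_params) grads[["final.conv.w"]] <- bwf$dw * conv_scale(3, cin_f)
  dx <- mbstd_bw(bwf$dx, cache$mbstd)
  for (bi in rev(seq_along(D$blocks))) {
    b <- D$blocks[[bi]]
    bc <- cache$blocks[[bi]]
    dx <- dx / sqrt(2)
    # skip path
    bws <- conv2d_bw(bc$xd, p[[paste0(b$name, ".skip.w")]] * conv_scale(1, b$cin),
                     dx, want_dx = TRUE, want_dw = want_params)
    if (want_params) {
      grads[[paste0(b$name, ".skip.w")]] <- bws$dw * conv_scale(1, b$cin)
    }
    dx_skip <- down2_bw(bws$dx)
    # main path
    dmain <- down2_bw(dx)
    dmain <- lrelu_bw(dmain, bc$neg1)
    if (want_params) {
      grads[[paste0(b$name, ".conv1.b")]] <- rowSums(colSums(dmain, dims = 2))
    }
    bw1c <- conv2d_bw(bc$a0, p[[paste0(b$name, ".conv1.w")]] * conv_scale(3, b$cin),
                      dmain, want_dx = TRUE, want_dw = want_params)
    if (want_params) {
      grads[[paste0(b$name, ".conv1.w")]] <- bw1c$dw * conv_scale(3, b$cin)
    }
    da0 <- lrelu_bw(bw1c$dx, bc$neg0)
    if (want_params) {
      grads[[paste0(b$name, ".conv0.b")]] <- rowSums(colSums(da0, dims = 2))
    }
    bw0c <- conv2d_bw(bc$x_in, p[[paste0(b$name, ".conv0.w")]] * conv_scale(3, b$cin),
                      da0, want_dx = TRUE, want_dw = want_params)
    if (want_params) {
      grads[[paste0(b$name, ".conv0.w")]] <- bw0c$dw * conv_scale(3, b$cin)
    }
    dx <- bw0c$dx + dx_skip
  }
  dx <- lrelu_bw(dx, cache$fromrgb_neg)
  if (want_params) {
    grads[["fromrgb.b"]] <- rowSums(colSums(dx, dims = 2))
  }
  bwr <- conv2d_bw(cache$x_in, p[["fromrgb.w"]] * conv_scale(1, D$img_channels),
                   dx, want_dx = want_dx, want_dw = want_params)
  if (want_params) grads[["fromrgb.w"]] <- bwr$dw * conv_scale(1, D$img_channels)
  list(grads = grads, dx = if (want_dx) bwr$dx else NULL)
}
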