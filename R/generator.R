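# Style-based generator: a 4-layer fully-connected mapping network Z -> W and a
# style-modulated synthesis network W+ -> image with per-layer noise injection.
# Weight demodulation replaces instance normalization; equalized learning rate
# is used throughout; all backward passes are hand-written.

default_channels <- function(res, max_ch = 64) {
  rs <- 4 * 2^(0:(log2(res) - 2))
  ch <- pmin(max_ch, 512 / rs)
  stats::setNames(as.integer(ch), as.character(rs))
}

num_style_layers <- function(res) as.integer(2 * log2(res) - 2)

build_synthesis_layers <- function(res, channels, img_channels = 3L) {
  layers <- list()
  slot <- 1L
  noise_id <- 1L
  ch <- function(r) channels[[as.character(r)]]
  layers[[1]] <- list(
    name = "b4.conv", kind = "conv", res = 4L, k = 3L,
    cin = ch(4), cout = ch(4), up = FALSE, slot = slot, noise = noise_id
  )
  rs <- 4 * 2^(seq_len(log2(res) - 2))
  for (r in rs) {
    slot <- slot + 1L; noise_id <- noise_id + 1L
    layers[[length(layers) + 1]] <- list(
      name = sprintf("b%d.conv0", r), kind = "conv", res = as.integer(r), k = 3L,
      cin = ch(r / 2), cout = ch(r), up = TRUE, slot = slot, noise = noise_id
    )
    slot <- slot + 1L; noise_id <- noise_id + 1L
    layers[[length(layers) + 1]] <- list(
      name = sprintf("b%d.conv1", r), kind = "conv", res = as.integer(r), k = 3L,
      cin = ch(r), cout = ch(r), up = FALSE, slot = slot, noise = noise_id
    )
  }
  layers[[length(layers) + 1]] <- list(
    name = "torgb", kind = "torgb", res = as.integer(res), k = 1L,
    cin = ch(res), cout = img_channels, up = FALSE, slot = slot + 1L, noise = NA
  )
  layers
}

#' Create a style-based generator model
#'
#' Builds an untrained generator with a 4-layer mapping network
#' \eqn{G_{map}: Z \to W} and a style-modulated synthesis network
#' \eqn{G_{syn}: W^+ \to X} that starts from a learned 4x4 constant and
#' doubles resolution per block up to `res`. Each synthesis convolution takes
#' its own style row (so the model has `2*log2(res) - 2` style inputs) and an
#' additive noise map whose gain is learned (initialized at zero).
#'
#' @param res Output resolution, a power of two >= 8.
#' @param d Latent dimensionality of both Z and W (toy default 64).
#' @param img_channels Number of image channels (3; ADC-like inputs are
#'   duplicated to 3 channels upstream).
#' @param channels Optional named integer vector mapping resolution
#'   (`"4"`, `"8"`, ...) to channel width; defaults to `min(64, 512/res)`.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `generator_model`.
#' @export
generator_model <- function(res = 32L, d = 64L, img_channels = 3L,
                            channels = NULL, seed = 1L) {
  if (res < 8 || log2(res) != round(log2(res))) {
    stop("res must be a power of two >= 8")
  }
  if (is.null(channels)) channels <- default_channels(res)
  layers <- build_synthesis_layers(res, channels, img_channels)
  L <- num_style_layers(res)
  stopifnot(layers[[length(layers)]]$slot == L)
  params <- list()
  with_seed(seed, {
    params[["const"]] <- array(stats::rnorm(16 * channels[["4"]]),
                               dim = c(4L, 4L, channels[["4"]]))
    for (i in 1:4) {
      fc <- init_dense(d, d, lrmul = 0.01)
      params[[sprintf("map.fc%d.w", i)]] <- fc$w
      params[[sprintf("map.fc%d.b", i)]] <- fc$b
    }
    for (ly in layers) {
      nm <- ly$name
      params[[paste0(nm, ".w")]] <- init_conv(ly$k, ly$cin, ly$cout)
      params[[paste0(nm, ".b")]] <- rep(0, ly$cout)
      aff <- init_dense(d, ly$cin, lrmul = 1, bias_init = 1)
      params[[paste0(nm, ".aff.w")]] <- aff$w
      params[[paste0(nm, ".aff.b")]] <- aff$b
      if (ly$kind == "conv") params[[paste0(nm, ".ngain")]] <- 0
    }
  })
  noise_res <- vapply(Filter(function(l) l$kind == "conv", layers),
                      function(l) l$res, integer(1))
  structure(list(
    res = as.integer(res), d = as.integer(d), L = L,
    img_channels = as.integer(img_channels), channels = channels,
    layers = layers, noise_res = noise_res, params = params,
    map_lrmul = 0.01, version = "1"
  ), class = "generator_model")
}

#' @export
print.generator_model <- function(x, ...) {
  cat(sprintf(
    "generator_model: %dx%d, %d channels, d=%d, %d style layers, %d noise maps\n",
    x$res, x$res, x$img_channels, x$d, x$L, length(x$noise_res)
  ))
  invisible(x)
}

# Multiply each channel-plane by a per-(channel, sample) scalar m (C x N).
cmul <- function(x, m) {
  d <- dim(x)
  x * rep(as.vector(m), each = d[1] * d[2])
}

# Add a per-channel bias (recycled over samples).
badd <- function(x, b) {
  d <- dim(x)
  x + rep(b, each = d[1] * d[2])
}

# ---- mapping network ----

map_forward <- function(model, z, keep = FALSE) {
  # z: (d, N)
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  nrm <- 1 / sqrt(colMeans(z^2) + 1e-8)
  x <- sweep(z, 2, nrm, "*")
  cache <- if (keep) list(inputs = list(), negs = list()) else NULL
  for (i in 1:4) {
    if (keep) cache$inputs[[i]] <- x
    y <- dense_fw(x, model$params[[sprintf("map.fc%d.w", i)]],
                  model$params[[sprintf("map.fc%d.b", i)]], model$map_lrmul)
    lr <- lrelu(y)
    if (keep) cache$negs[[i]] <- lr$neg
    x <- lr$y
  }
  list(w = x, cache = cache)
}

map_backward <- function(model, cache, dw) {
  grads <- list()
  dx <- dw
  for (i in 4:1) {
    dx <- lrelu_bw(dx, cache$negs[[i]])
    bw <- dense_bw(cache$inputs[[i]], model$params[[sprintf("map.fc%d.w", i)]],
                   dx, model$map_lrmul)
    grads[[sprintf("map.fc%d.w", i)]] <- bw$dw
    grads[[sprintf("map.fc%d.b", i)]] <- bw$db
    dx <- bw$dx
  }
  grads
}

#' Map a latent code z into the intermediate latent space W
#'
#' Applies the 4-layer nonlinear mapping network (with input normalization of
#' z). Deterministic given the model; broadcasting the result to all style
#' layers yields a valid extended latent code.
#'
#' @param model A `generator_model`.
#' @param z Numeric vector of length `model$d` (or a d x N matrix).
#' @return A vector (or matrix) of the same shape in W.
#' @export
map_latent <- function(model, z) {
  vec <- is.null(dim(z))
  if (vec) z <- matrix(z, ncol = 1)
  if (nrow(z) != model$d) stop(sprintf("z must have dimension %d", model$d))
  if (!all(is.finite(z))) stop("z must be finite")
  w <- map_forward(model, z)$w
  if (vec) drop(w) else w
}

# ---- synthesis network ----

make_noise <- function(model, n, kind = "random") {
  lapply(model$noise_res, function(r) {
    if (identical(kind, "zero")) {
      array(0, dim = c(r, r, n))
    } else {
      array(stats::rnorm(r * r * n), dim = c(r, r, n))
    }
  })
}

# Coerce user noise input to the internal batched list form.
normalize_noise <- function(model, noise, n) {
  if (is.character(noise)) return(make_noise(model, n, noise))
  stopifnot(is.list(noise), length(noise) == length(model$noise_res))
  lapply(seq_along(noise), function(i) {
    ni <- noise[[i]]
    r <- model$noise_res[i]
    if (length(dim(ni)) == 2) {
      stopifnot(all(dim(ni) == c(r, r)))
      array(rep(as.vector(ni), n), dim = c(r, r, n))
    } else {
      stopifnot(all(dim(ni) == c(r, r, n)))
      ni
    }
  })
}

synth_forward <- function(model, wplus, noise = "zero", keep = FALSE) {
  # wplus: (L, d) or (L, d, N)
  if (length(dim(wplus)) == 2) dim(wplus) <- c(dim(wplus), 1L)
  L <- model$L
  if (dim(wplus)[1] != L) stop(sprintf("wplus must have %d style rows", L))
  n <- dim(wplus)[3]
  noise <- normalize_noise(model, noise, n)
  p <- model$params
  x <- array(rep(as.vector(p[["const"]]), n),
             dim = c(4L, 4L, dim(p[["const"]])[3], n))
  caches <- if (keep) vector("list", length(model$layers)) else NULL
  for (li in seq_along(model$layers)) {
    ly <- model$layers[[li]]
    nm <- ly$name
    if (ly$up) x <- up2(x)
    wrow <- matrix(wplus[ly$slot, , ], nrow = model$d)
    s <- dense_fw(wrow, p[[paste0(nm, ".aff.w")]], p[[paste0(nm, ".aff.b")]])
    xm <- cmul(x, s)
    weff <- p[[paste0(nm, ".w")]] * conv_scale(ly$k, ly$cin)
    y0 <- conv2d(xm, weff)
    cache <- list(x = x, s = s, wrow = wrow)
    if (ly$kind == "conv") {
      wsq <- matrix(colSums(matrix(weff^2, ncol = ly$cin * ly$cout)),
                    ly$cin, ly$cout)
      q <- crossprod(wsq, s^2) + 1e-8
      dcoef <- 1 / sqrt(q)
      y <- cmul(y0, dcoef)
      if (keep) { cache$y0 <- y0; cache$dcoef <- dcoef; cache$wsq <- wsq }
      g <- p[[paste0(nm, ".ngain")]]
      nz <- noise[[ly$noise]]
      if (g != 0) {
        nzv <- g * as.vector(nz)
        for (cc in seq_len(ly$cout)) y[, , cc, ] <- y[, , cc, ] + nzv
      }
      y <- badd(y, p[[paste0(nm, ".b")]])
      lr <- lrelu(y)
      if (keep) cache$neg <- lr$neg
      x <- lr$y
    } else {
      x <- badd(y0, p[[paste0(nm, ".b")]])
    }
    if (keep) caches[[li]] <- cache
  }
  list(img = x, caches = caches, noise = noise, n = n)
}

synth_backward <- function(model, fwd, dimg,
                           want_params = TRUE, want_noise = FALSE) {
  p <- model$params
  L <- model$L
  n <- fwd$n
  grads <- list()
  dwplus <- array(0, dim = c(L, model$d, n))
  dnoise <- if (want_noise) lapply(fwd$noise, function(x) x * 0) else NULL
  dy <- dimg
  for (li in rev(seq_along(model$layers))) {
    ly <- model$layers[[li]]
    nm <- ly$name
    cache <- fwd$caches[[li]]
    weff <- p[[paste0(nm, ".w")]] * conv_scale(ly$k, ly$cin)
    dweff_extra <- NULL
    ds_extra <- NULL
    if (ly$kind == "conv") {
      dy <- lrelu_bw(dy, cache$neg)
      if (want_params) {
        grads[[paste0(nm, ".b")]] <- rowSums(colSums(dy, dims = 2))
      }
      g <- p[[paste0(nm, ".ngain")]]
      nz <- fwd$noise[[ly$noise]]
      if (want_params || want_noise) {
        dn <- colSums(aperm(dy, c(3, 1, 2, 4)), dims = 1) # (H, W, N)
        if (want_params) grads[[paste0(nm, ".ngain")]] <- sum(dn * nz)
        if (want_noise) dnoise[[ly$noise]] <- dnoise[[ly$noise]] + g * dn
      }
      # demodulation backward
      dy0 <- cmul(dy, cache$dcoef)
      dd <- colSums(dy * cache$y0, dims = 2)            # (cout, N)
      dq <- -0.5 * cache$dcoef^3 * dd
      ds_extra <- 2 * cache$s * (cache$wsq %*% dq)      # (cin, N)
      dwsq <- (cache$s^2) %*% t(dq)                     # (cin, cout)
      dweff_extra <- 2 * weff *
        array(rep(as.vector(dwsq), each = ly$k * ly$k),
              dim = dim(weff))
    } else {
      if (want_params) {
        grads[[paste0(nm, ".b")]] <- rowSums(colSums(dy, dims = 2))
      }
      dy0 <- dy
    }
    xm <- cmul(cache$x, cache$s)
    bw <- conv2d_bw(xm, weff, dy0, want_dx = TRUE, want_dw = want_params)
    if (want_params) {
      dweff <- bw$dw
      if (!is.null(dweff_extra)) dweff <- dweff + dweff_extra
      grads[[paste0(nm, ".w")]] <- dweff * conv_scale(ly$k, ly$cin)
    }
    dxm <- bw$dx
    ds <- colSums(dxm * cache$x, dims = 2)
    if (!is.null(ds_extra)) ds <- ds + ds_extra
    abw <- dense_bw(cache$wrow, p[[paste0(nm, ".aff.w")]], ds)
    if (want_params) {
      grads[[paste0(nm, ".aff.w")]] <- abw$dw
      grads[[paste0(nm, ".aff.b")]] <- abw$db
    }
    dwplus[ly$slot, , ] <- dwplus[ly$slot, , ] + abw$dx
    dx <- cmul(dxm, cache$s)
    if (ly$up) dx <- up2_bw(dx)
    dy <- dx
  }
  if (want_params) {
    grads[["const"]] <- rowSums(dy, dims = 3)
  }
  list(grads = grads, dwplus = dwplus, dnoise = dnoise)
}

#' Synthesize an image from an extended latent code
#'
#' Runs the synthesis network on a W+ code. With `noise = "zero"` the output
#' is a pure function of `(model, wplus)`; `noise = "random"` draws fresh
#' standard-normal injection maps; a list of per-layer maps gives full control
#' (as needed to reproduce a projection result exactly).
#'
#' @param model A `generator_model`.
#' @param wplus Either a length-d vector (broadcast to all style layers) or an
#'   L x d matrix with one style row per layer.
#' @param noise `"zero"`, `"random"`, or a list of per-layer noise matrices
#'   matching `model$noise_res`.
#' @return An (H, W, C) numeric array in the generator's output range
#'   (approximately \[-1, 1\] for trained models; see [synth_to_intensity()]).
#' @export
synthesize <- function(model, wplus, noise = "zero") {
  if (is.null(dim(wplus))) {
    if (length(wplus) != model$d) stop("wplus vector must have length d")
    wplus <- matrix(wplus, nrow = model$L, ncol = model$d, byrow = TRUE)
  }
  if (nrow(wplus) != model$L) {
    stop(sprintf("wplus must have %d rows (one per style layer)", model$L))
  }
  out <- synth_forward(model, wplus, noise)
  array(out$img, dim = dim(out$img)[1:3])
}

#' Convert generator output to intensity scale
#'
#' Maps the generator's signed output range linearly to \[0, 1\] and clips.
#' @param img Array produced by [synthesize()].
#' @return Array of the same shape with values in \[0, 1\].
#' @export
synth_to_intensity <- function(img) {
  pmin(pmax((img + 1) / 2, 0), 1)
}

# Intensity [0,1] image -> generator range [-1,1].
intensity_to_synth <- function(img) img * 2 - 1
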