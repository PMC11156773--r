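# Fréchet distance between Gaussian fits of feature embeddings, with a
# pluggable embedder. The default embedder is a fixed-seed random two-stage
# convolutional feature map, reproducible without any external downloads;
# a pretrained backbone can be plugged in through the same interface.
# Numbers from different embedders are never comparable.

#' Fixed-seed random convolutional feature embedder
#'
#' Two random 3x3 convolution stages (leaky ReLU, 2x average pooling) whose
#' weights are drawn once from a seeded RNG; features are per-channel spatial
#' means and standard deviations. Used as the default embedder for the
#' Fréchet quality metric.
#'
#' @param img_channels Number of image channels.
#' @param widths Channel widths of the two stages.
#' @param seed Seed fixing the random weights.
#' @return A list with a `$embed(images)` function mapping an (H, W, C, N)
#'   array to an N x D feature matrix, and a `$dim` field.
#' @export
fid_embedder <- function(img_channels = 3L, widths = c(12L, 24L), seed = 7L) {
  ws <- with_seed(seed, list(
    w1 = init_conv(3L, img_channels, widths[1]),
    w2 = init_conv(3L, widths[1], widths[2])
  ))
  embed <- function(images) {
    x <- as_batch(images)
    n <- dim(x)[4]
    h1 <- lrelu(conv2d(x, ws$w1 * conv_scale(3, img_channels)))$y
    h1 <- down2(h1)
    h2 <- lrelu(conv2d(h1, ws$w2 * conv_scale(3, widths[1])))$y
    h2 <- down2(h2)
    d2 <- dim(h2)
    m <- matrix(h2, nrow = d2[1] * d2[2])  # (HW) x (C*N)
    mu <- colMeans(m)
    sd_ <- sqrt(colMeans(m^2) - mu^2 + 1e-12)
    feats <- rbind(matrix(mu, d2[3], n), matrix(sd_, d2[3], n))
    t(feats)
  }
  list(embed = embed, dim = 2L * widths[2], kind = "random_conv", seed = seed)
}

# Symmetric PSD matrix square root via eigendecomposition.
sqrtm_psd <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Fréchet distance between two Gaussians
#'
#' \eqn{\lVert\mu_1-\mu_2\rVert^2 + tr(\Sigma_1+\Sigma_2
#' - 2(\Sigma_1\Sigma_2)^{1/2})}, the distance underlying the FID quality
#' metric for generative models.
#'
#' @param mean1,mean2 Mean vectors.
#' @param cov1,cov2 Symmetric positive semidefinite covariance matrices.
#' @param tol Tolerance for the symmetry / PSD validation.
#' @return Non-negative scalar.
#' @export
frechet_distance <- function(mean1, cov1, mean2, cov2, tol = 1e-6) {
  cov1 <- as.matrix(cov1); cov2 <- as.matrix(cov2)
  for (S in list(cov1, cov2)) {
    if (max(abs(S - t(S))) > tol * (1 + max(abs(S)))) {
      stop("covariance matrix is not symmetric")
    }
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -tol * (1 + max(abs(ev)))) {
      stop("covariance matrix is not positive semidefinite")
    }
  }
  a <- sqrtm_psd(cov1)
  mid <- sqrtm_psd(a %*% cov2 %*% a)
  d2 <- sum((mean1 - mean2)^2) +
    sum(diag(cov1)) + sum(diag(cov2)) - 2 * sum(diag(mid))
  max(d2, 0)
}

gaussian_stats <- function(feats) {
  list(mean = colMeans(feats), cov = stats::cov(feats))
}

#' Fréchet feature distance between two image sets
#'
#' Embeds both sets with the given embedder, fits a Gaussian to each feature
#' cloud, and returns their Fréchet distance.
#'
#' @param real_images,generated_images (H, W, C, N) arrays (or lists of
#'   (H, W, C) arrays), intensities in \[0, 1\].
#' @param embedder An embedder from [fid_embedder()] (or a compatible
#'   pretrained backbone wrapper).
#' @return Non-negative scalar.
#' @export
fid_score <- function(real_images, generated_images, embedder = fid_embedder()) {
  fr <- embedder$embed(coerce_image_stack(real_images))
  fg <- embedder$embed(coerce_image_stack(generated_images))
  sr <- gaussian_stats(fr)
  sg <- gaussian_stats(fg)
  frechet_distance(sr$mean, sr$cov, sg$mean, sg$cov)
}
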