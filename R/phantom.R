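# Synthetic 2D brain-like phantoms with known tissue masks and controllable
# disease attributes. The geometry (elliptical head, cortical ribbon,
# paraventricular lesion blobs) is deliberately schematic: it preserves the
# analysis-relevant statistics — brain parenchymal fraction, ventricle area,
# lesion load, multi-echo decay — with exact ground truth, which real
# anatomy cannot provide.

T1W_TISSUES <- list(
  s0 = c(background = 0.02, csf = 0.34, gm = 0.65, wm = 0.85),
  t2star = c(background = 1e6, csf = 200, gm = 70, wm = 55)
)
ADC_TISSUES <- c(background = 0.02, csf = 0.90, gm = 0.55, wm = 0.40,
                 lesion = 0.88)
DEFAULT_TE <- c(8.12, 13.19, 19.26)

#' Phantom attribute record
#'
#' Generating attributes of one synthetic brain slice.
#'
#' @param cohort_label `"HC"` or `"MS"`.
#' @param ventricle_scale Dimensionless >= 0; 1.0 is the reference ventricle
#'   area (CSF area scales linearly with this value).
#' @param cortical_thinning Fraction in \[0, 1\]; shrinks the cortical
#'   gray-matter ribbon thickness.
#' @param lesion_count Non-negative integer number of periventricular lesions.
#' @param slice_position Integer axial slice index (0..5; larger = smaller
#'   head cross-section).
#' @param age_proxy Years; continuous covariate weakly scaling head size.
#' @param contrast `"t1w_multiecho"` (3-channel echo decay) or `"adc"`
#'   (single map duplicated to 3 identical channels).
#' @param seed Integer seed making the phantom deterministic.
#' @return A list of class `attribute_record`.
#' @export
attribute_record <- function(cohort_label = "HC", ventricle_scale = 1.0,
                             cortical_thinning = 0.15, lesion_count = 0L,
                             slice_position = 0L, age_proxy = 38,
                             contrast = c("t1w_multiecho", "adc"),
                             seed = 1L) {
  contrast <- match.arg(contrast)
  cohort_label <- match.arg(cohort_label, c("HC", "MS"))
  if (ventricle_scale < 0) stop("ventricle_scale must be >= 0")
  if (cortical_thinning < 0 || cortical_thinning > 1) {
    stop("cortical_thinning must be in [0, 1]")
  }
  if (lesion_count < 0) stop("lesion_count must be >= 0")
  structure(list(
    cohort_label = cohort_label, ventricle_scale = ventricle_scale,
    cortical_thinning = cortical_thinning,
    lesion_count = as.integer(lesion_count),
    slice_position = as.integer(slice_position),
    age_proxy = age_proxy, contrast = contrast, seed = as.integer(seed)
  ), class = "attribute_record")
}

#' Generate a synthetic brain slice phantom
#'
#' Rasterizes a schematic axial brain slice: an elliptical head whose axes
#' scale with `age_proxy` and `slice_position`, central ventricular CSF
#' ellipses scaled by `ventricle_scale`, a cortical gray-matter ribbon whose
#' thickness shrinks with `cortical_thinning`, white matter filling the
#' interior, and small lesion blobs adjacent to the ventricles. For the
#' multi-echo contrast, channel c of tissue tau follows
#' \eqn{S_0(\tau)\exp(-TE_c / T2^*(\tau))} at TE = 8.12, 13.19, 19.26 ms;
#' ADC phantoms carry identical bright-CSF/bright-lesion channels.
#' Deterministic given `(attrs, size, noise_sd)`.
#'
#' @param attrs An [attribute_record()].
#' @param size Image side in pixels; power of two >= 32.
#' @param noise_sd Additive Gaussian acquisition-noise standard deviation in
#'   intensity units (0 gives a clean 4-level phantom).
#' @param te Echo times in milliseconds (length 3).
#' @return An object of class `phantom`: `channels` (H, W, 3 array in
#'   \[0, 1\]), `tissue_masks` (background/csf/gm/wm logical rasters, mutually
#'   exclusive and jointly exhaustive), `lesion_mask`, `attrs`, `te_values`.
#' @export
make_phantom <- function(attrs, size = 64L, noise_sd = 0.02,
                         te = DEFAULT_TE) {
  stopifnot(inherits(attrs, "attribute_record"))
  if (size < 32 || log2(size) != round(log2(size))) {
    stop("size must be a power of two >= 32")
  }
  S <- as.integer(size)
  ax <- seq(-1, 1, length.out = S)
  X <- matrix(ax, S, S, byrow = TRUE)  # column coordinate
  Y <- matrix(ax, S, S)                # row coordinate

  age_scale <- 1 + 0.0015 * (attrs$age_proxy - 38)
  slice_factor <- 1 - 0.03 * attrs$slice_position
  a <- 0.66 * age_scale * slice_factor
  b <- 0.82 * age_scale * slice_factor
  rho <- sqrt((X / a)^2 + (Y / b)^2)
  head <- rho <= 1
  theta <- 0.16 * (1 - 0.6 * attrs$cortical_thinning)
  gm <- head & rho > (1 - theta)
  interior <- rho <= (1 - theta)

  vs <- attrs$ventricle_scale
  va <- 0.085 * sqrt(vs)
  vb <- 0.30 * sqrt(vs)
  cx <- 0.12; cy <- 0.02
  vent <- (((X - cx) / va)^2 + ((Y - cy) / vb)^2 <= 1) |
          (((X + cx) / va)^2 + ((Y - cy) / vb)^2 <= 1)
  if (vs > 0 && any(vent & !interior)) {
    stop("ventricle_scale too large: ventricles exceed the head interior")
  }
  csf <- vent & interior
  wm <- interior & !csf
  background <- !head

  lesion <- matrix(FALSE, S, S)
  with_seed(attrs$seed, {
    if (attrs$lesion_count > 0) {
      for (k in seq_len(attrs$lesion_count)) {
        side <- if (stats::runif(1) < 0.5) 1 else -1
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 1.25, 1.7)
        lx <- side * cx + rad * va * cos(ang)
        ly <- cy + rad * vb * sin(ang) * 0.8
        lr <- stats::runif(1, 0.028, 0.045)
        lesion <- lesion | (((X - lx)^2 + (Y - ly)^2) <= lr^2)
      }
      lesion <- lesion & (wm | gm)
    }
    img <- array(0, dim = c(S, S, 3L))
    if (attrs$contrast == "t1w_multiecho") {
      for (ch in 1:3) {
        plane <- matrix(0, S, S)
        for (t in c("background", "csf", "gm", "wm")) {
          m <- switch(t, background = background, csf = csf, gm = gm, wm = wm)
          plane[m] <- T1W_TISSUES$s0[[t]] * exp(-te[ch] / T1W_TISSUES$t2star[[t]])
        }
        plane[lesion] <- 0.75 * exp(-te[ch] / 65)
        if (noise_sd > 0) plane <- plane + stats::rnorm(S * S, sd = noise_sd)
        img[, , ch] <- plane
      }
    } else {
      plane <- matrix(0, S, S)
      for (t in c("background", "csf", "gm", "wm")) {
        m <- switch(t, background = background, csf = csf, gm = gm, wm = wm)
        plane[m] <- ADC_TISSUES[[t]]
      }
      plane[lesion] <- ADC_TISSUES[["lesion"]]
      if (noise_sd > 0) plane <- plane + stats::rnorm(S * S, sd = noise_sd)
      for (ch in 1:3) img[, , ch] <- plane
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(
      channels = img,
      tissue_masks = list(background = background, csf = csf, gm = gm, wm = wm),
      lesion_mask = lesion,
      attrs = attrs,
      te_values = te
    ), class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "phantom: %dx%d %s, cohort %s, ventricle_scale %.2f, %d lesion(s), BPF %.3f\n",
    dim(x$channels)[1], dim(x$channels)[2], x$attrs$contrast,
    x$attrs$cohort_label, x$attrs$ventricle_scale, x$attrs$lesion_count,
    analytic_bpf(x)
  ))
  invisible(x)
}

#' Ground-truth brain parenchymal fraction of a phantom
#'
#' Exact pixel-count BPF, \eqn{(|GM|+|WM|) / (|GM|+|WM|+|CSF|)}, from the
#' phantom's tissue masks; the oracle against which segmentation-based BPF is
#' validated.
#'
#' @param p A `phantom`.
#' @return Fraction in \[0, 1\].
#' @export
analytic_bpf <- function(p) {
  stopifnot(inherits(p, "phantom"))
  gm <- sum(p$tissue_masks$gm)
  wm <- sum(p$tissue_masks$wm)
  csf <- sum(p$tissue_masks$csf)
  if (gm + wm + csf == 0) stop("empty intracranial region")
  (gm + wm) / (gm + wm + csf)
}

#' Default cohort-conditional attribute distributions
#'
#' @return Named list of distribution parameters used by [sample_cohort()]:
#'   ventricle log-scale shift and spread, lesion Poisson means, cortical
#'   thinning Beta parameters, and age means/SDs per cohort.
#' @export
cohort_defaults <- function() {
  list(
    ventricle_meanlog = c(HC = 0, MS = 0.25),
    ventricle_sdlog = 0.18,
    lesion_mean = c(HC = 0.3, MS = 4),
    thinning_shape1 = c(HC = 2, MS = 4),
    thinning_shape2 = c(HC = 8, MS = 6),
    age_mean = c(HC = 36.94, MS = 38.75),
    age_sd = c(HC = 12.55, MS = 10.08),
    slice_positions = 0:5
  )
}

#' Sample a phantom cohort
#'
#' Draws `n` attribute records from cohort-conditional distributions —
#' ventricle scale is log-normal with the MS log-mean shifted +0.25, lesion
#' count is Poisson (mean 0.3 for HC, 4 for MS), cortical thinning is Beta,
#' age is Gaussian with cohort-specific mean/SD — and rasterizes a phantom
#' for each. Reproducible under `seed`.
#'
#' @param n Number of subjects (>= 1).
#' @param label Cohort label, `"HC"` or `"MS"`.
#' @param contrast `"t1w_multiecho"` or `"adc"`.
#' @param seed Integer seed.
#' @param size Image side in pixels.
#' @param noise_sd Acquisition-noise SD passed to [make_phantom()].
#' @param params Distribution parameters, see [cohort_defaults()].
#' @param slice_position Optional fixed slice position (otherwise sampled).
#' @return List of `phantom` objects; the drawn attribute table is attached
#'   as `attr(, "attrs")` (a data frame).
#' @export
sample_cohort <- function(n, label = c("HC", "MS"),
                          contrast = c("t1w_multiecho", "adc"),
                          seed = 1L, size = 64L, noise_sd = 0.02,
                          params = cohort_defaults(),
                          slice_position = NULL) {
  label <- match.arg(label)
  contrast <- match.arg(contrast)
  if (n < 1) stop("n must be >= 1")
  tab <- with_seed(seed, {
    data.frame(
      subject_id = sprintf("%s%04d", label, seq_len(n)),
      cohort = label,
      ventricle_scale = stats::rlnorm(n, params$ventricle_meanlog[[label]],
                                      params$ventricle_sdlog),
      cortical_thinning = stats::rbeta(n, params$thinning_shape1[[label]],
                                       params$thinning_shape2[[label]]),
      lesion_count = stats::rpois(n, params$lesion_mean[[label]]),
      slice_position = if (is.null(slice_position)) {
        sample(params$slice_positions, n, replace = TRUE)
      } else rep(as.integer(slice_position), n),
      age_proxy = pmin(pmax(stats::rnorm(n, params$age_mean[[label]],
                                         params$age_sd[[label]]), 18), 75),
      seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  phantoms <- lapply(seq_len(n), function(i) {
    at <- attribute_record(
      cohort_label = label, ventricle_scale = tab$ventricle_scale[i],
      cortical_thinning = tab$cortical_thinning[i],
      lesion_count = tab$lesion_count[i],
      slice_position = tab$slice_position[i],
      age_proxy = tab$age_proxy[i], contrast = contrast, seed = tab$seed[i]
    )
    make_phantom(at, size = size, noise_sd = noise_sd)
  })
  attr(phantoms, "attrs") <- tab
  phantoms
}

#' Stack phantom images into an array
#'
#' @param phantoms List of `phantom` objects.
#' @return (H, W, 3, N) intensity array.
#' @export
phantom_stack <- function(phantoms) {
  coerce_image_stack(lapply(phantoms, function(p) p$channels))
}

#' Export a phantom cohort to disk
#'
#' Writes each phantom either as a 16-bit PNG per channel or as a single
#' NIfTI file (H x W x 1 x C), plus a CSV metadata table
#' (subject_id, cohort, age_proxy, slice_position, seed).
#'
#' @param phantoms List of phantoms from [sample_cohort()].
#' @param dir Output directory (created if missing).
#' @param format `"png"` or `"nifti"`.
#' @return Invisibly, the metadata data frame (with file paths).
#' @export
export_cohort <- function(phantoms, dir, format = c("png", "nifti")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- attr(phantoms, "attrs")
  if (is.null(tab)) {
    tab <- do.call(rbind, lapply(seq_along(phantoms), function(i) {
      a <- phantoms[[i]]$attrs
      data.frame(subject_id = sprintf("S%04d", i), cohort = a$cohort_label,
                 ventricle_scale = a$ventricle_scale,
                 cortical_thinning = a$cortical_thinning,
                 lesion_count = a$lesion_count,
                 slice_position = a$slice_position,
                 age_proxy = a$age_proxy, seed = a$seed)
    }))
  }
  paths <- character(length(phantoms))
  for (i in seq_along(phantoms)) {
    img <- phantoms[[i]]$channels
    if (format == "png") {
      base <- file.path(dir, tab$subject_id[i])
      for (ch in seq_len(dim(img)[3])) {
        write_image(img[, , ch], sprintf("%s_ch%d.png", base, ch))
      }
      paths[i] <- sprintf("%s_ch*.png", base)
    } else {
      path <- file.path(dir, paste0(tab$subject_id[i], ".nii.gz"))
      write_image(img, path)
      paths[i] <- path
    }
  }
  tab$path <- paths
  utils::write.csv(tab, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(tab)
}
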