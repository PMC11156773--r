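# Morphometry of (simulated) disease progression: k-means tissue
# segmentation with k = 4 (background, CSF, GM, WM), single-slice brain
# parenchymal fraction, BPF-vs-alpha curves with paired t-tests, intensity
# profiles, and signed difference maps.

# k-means++ seeding on a 1-D intensity sample.
kmeanspp_centers <- function(v, k) {
  centers <- numeric(k)
  centers[1] <- v[sample.int(length(v), 1)]
  d2 <- (v - centers[1])^2
  for (j in 2:k) {
    p <- d2 / sum(d2)
    centers[j] <- v[sample.int(length(v), 1, prob = p)]
    d2 <- pmin(d2, (v - centers[j])^2)
  }
  centers
}

#' Segment a slice into background, CSF, GM, and WM by k-means
#'
#' Clusters pixel intensities with k-means (k = 4, seeded k-means++
#' initialization, 10 restarts) and maps clusters to tissues: the cluster
#' dominating the image border becomes background; the remaining three are
#' ordered by centroid intensity and assigned per contrast
#' (T1-weighted: CSF < GM < WM; ADC: WM < GM < CSF).
#'
#' @param image Single-channel matrix (if a 3-channel array is given, the
#'   first channel is used). Any affine intensity scale is acceptable.
#' @param contrast `"t1w"` (alias `"t1w_multiecho"`) or `"adc"`.
#' @param seed Integer seed for the restarts.
#' @param restarts Number of k-means restarts (>= 10 recommended).
#' @return Object of class `tissue_segmentation`: `labels` (character matrix
#'   with values background/csf/gm/wm), `centroids` (named, sorted by
#'   intensity), `assignment_rule`.
#' @export
segment_tissues <- function(image, contrast = c("t1w", "adc", "t1w_multiecho"),
                            seed = 1L, restarts = 10L) {
  contrast <- match.arg(contrast)
  if (contrast == "t1w_multiecho") contrast <- "t1w"
  if (length(dim(image)) == 3) image <- image[, , 1]
  image <- as.matrix(image)
  v <- as.vector(image)
  if (max(v) - min(v) < 1e-12) stop("constant image cannot be segmented")
  k <- 4L
  uq <- unique(v)
  if (length(uq) < k) {
    stop(sprintf("image has only %d distinct intensities; need >= 4", length(uq)))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      cen <- sort(kmeanspp_centers(v, k))
      if (length(unique(cen)) < k) next
      km <- tryCatch(stats::kmeans(v, centers = cen, iter.max = 100),
                     error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) stop("k-means failed on this image")
  lab <- matrix(best$cluster, nrow(image), ncol(image))
  border <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  bg_cluster <- as.integer(names(which.max(table(border))))
  rest <- setdiff(seq_len(k), bg_cluster)
  rest <- rest[order(best$centers[rest])]
  tissue_order <- if (contrast == "t1w") {
    c("csf", "gm", "wm")            # increasing intensity
  } else {
    c("wm", "gm", "csf")            # ADC: CSF brightest
  }
  map <- character(k)
  map[bg_cluster] <- "background"
  map[rest] <- tissue_order
  labels <- matrix(map[lab], nrow(image), ncol(image))
  centroids <- stats::setNames(drop(best$centers), map)
  structure(list(
    labels = labels,
    centroids = centroids,
    assignment_rule = list(
      background = "border-dominant cluster",
      ordering = paste(tissue_order, collapse = " < "),
      contrast = contrast
    )
  ), class = "tissue_segmentation")
}

#' @export
print.tissue_segmentation <- function(x, ...) {
  tb <- table(x$labels)
  cat("tissue_segmentation:", paste(names(tb), tb, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Brain parenchymal fraction from a segmentation
#'
#' \eqn{BPF = (V_{GM}+V_{WM}) / (V_{GM}+V_{WM}+V_{CSF})} with pixel-count
#' volumes from the label map of a single 2D slice.
#'
#' @param seg A `tissue_segmentation`.
#' @return Fraction in \[0, 1\].
#' @export
bpf_from_labels <- function(seg) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  gm <- sum(seg$labels == "gm")
  wm <- sum(seg$labels == "wm")
  csf <- sum(seg$labels == "csf")
  if (gm + wm + csf == 0) stop("empty intracranial region")
  (gm + wm) / (gm + wm + csf)
}

#' Paired t-test with an explicit degenerate-case contract
#'
#' Two-sided paired Student t-test on the differences x - y; when the
#' differences have zero variance the p-value is undefined and the result is
#' flagged instead of returning an infinite statistic.
#'
#' @param x,y Equal-length numeric vectors, n >= 2.
#' @return List with `t`, `p`, `df`, and `flag` (`"ok"` or
#'   `"zero_variance"`).
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) < .Machine$double.eps^0.5 * (1 + max(abs(d)))) {
    return(list(t = NA_real_, p = NA_real_, df = length(x) - 1L,
                flag = "zero_variance"))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), flag = "ok")
}

#' BPF trajectories over a manipulation grid
#'
#' Segments channel 1 of every image in a set of per-subject manipulation
#' series sharing one alpha grid, computes per-subject, per-alpha BPF and
#' tissue volumes, and runs a paired t-test of each alpha column against the
#' alpha = 0 baseline (significance threshold 0.001).
#'
#' @param series_list List of `manipulation_series`, one per subject.
#' @param contrast `"t1w"` or `"adc"` (drives the cluster-to-tissue rule).
#' @param seed Segmentation seed.
#' @param significance_threshold Paired-test threshold (0.001).
#' @return Object of class `bpf_curve`: `alpha_grid`, `bpf` (subjects x
#'   alphas), `volumes` (subjects x alphas x 3 pixel counts, GM/WM/CSF),
#'   `p_values`, `t_values`, `flags`, `significant`, `baseline_index`.
#' @export
bpf_curve <- function(series_list, contrast = c("t1w", "adc", "t1w_multiecho"),
                      seed = 1L, significance_threshold = 0.001) {
  contrast <- match.arg(contrast)
  grids <- unique(lapply(series_list, function(s) s$alpha_grid))
  if (length(grids) != 1) stop("subjects have differing alpha grids")
  grid <- grids[[1]]
  ns <- length(series_list)
  na <- length(grid)
  bpf <- matrix(NA_real_, ns, na)
  vols <- array(NA_real_, dim = c(ns, na, 3),
                dimnames = list(NULL, NULL, c("gm", "wm", "csf")))
  for (i in seq_len(ns)) {
    for (j in seq_len(na)) {
      seg <- segment_tissues(series_list[[i]]$images[[j]], contrast,
                             seed = seed)
      bpf[i, j] <- bpf_from_labels(seg)
      vols[i, j, ] <- c(sum(seg$labels == "gm"), sum(seg$labels == "wm"),
                        sum(seg$labels == "csf"))
    }
  }
  baseline <- series_list[[1]]$baseline_index
  pv <- rep(NA_real_, na)
  tv <- rep(NA_real_, na)
  flags <- rep("baseline", na)
  for (j in seq_len(na)) {
    if (j == baseline) next
    if (ns < 2) { flags[j] <- "insufficient_subjects"; next }
    tt <- paired_ttest(bpf[, j], bpf[, baseline])
    pv[j] <- tt$p; tv[j] <- tt$t; flags[j] <- tt$flag
  }
  structure(list(
    alpha_grid = grid, bpf = bpf, volumes = vols,
    p_values = pv, t_values = tv, flags = flags,
    significant = !is.na(pv) & pv < significance_threshold,
    significance_threshold = significance_threshold,
    baseline_index = baseline
  ), class = "bpf_curve")
}

#' @export
print.bpf_curve <- function(x, ...) {
  cat("bpf_curve: mean BPF by alpha\n")
  print(data.frame(alpha = x$alpha_grid,
                   mean_bpf = colMeans(x$bpf),
                   p = x$p_values,
                   significant = x$significant))
  invisible(x)
}

#' Row and column intensity profiles
#'
#' Raw intensity sequences of one row and one column (channel 1 for
#' multi-channel images), as used to visualize ventricular enlargement.
#'
#' @param image Matrix or (H, W, C) array.
#' @param row_index,col_index 1-based indices within bounds.
#' @return List with `row` (length W) and `column` (length H) profiles.
#' @export
intensity_profile <- function(image, row_index, col_index) {
  if (length(dim(image)) == 3) image <- image[, , 1]
  if (row_index < 1 || row_index > nrow(image) ||
      col_index < 1 || col_index > ncol(image)) {
    stop("profile index out of bounds")
  }
  list(row = image[row_index, ], column = image[, col_index])
}

#' Signed difference map between an image and a baseline
#'
#' Pixelwise `image - baseline`; positive values mark intensity increases
#' from baseline (rendered red downstream), negative values decreases
#' (blue).
#'
#' @param image,baseline Arrays of identical shape.
#' @return Signed array of the same shape.
#' @export
difference_map <- function(image, baseline) {
  if (!identical(dim(image), dim(baseline))) stop("shape mismatch")
  image - baseline
}
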