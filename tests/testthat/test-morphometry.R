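test_that("k-means segmentation recovers clean phantom tissue maps exactly", {
  p <- clean_phantom(seed = 26)
  seg <- segment_tissues(p$channels, "t1w", seed = 1)
  expect_identical(seg$labels, true_label_map(p))

  # label-permutation invariance: tissue assignment identical across seeds
  seg2 <- segment_tissues(p$channels, "t1w", seed = 999)
  expect_identical(seg$labels, seg2$labels)

  # ADC contrast flips the intensity-to-tissue ordering
  pa <- make_phantom(attribute_record(contrast = "adc", seed = 26), 64,
                     noise_sd = 0)
  sega <- segment_tissues(pa$channels, "adc", seed = 1)
  expect_identical(sega$labels, true_label_map(pa))

  expect_error(segment_tissues(matrix(0.5, 32, 32)), "constant")
})

test_that("segmentation tolerates acquisition noise at the default level", {
  p <- make_phantom(attribute_record(seed = 27), 64, noise_sd = 0.02)
  seg <- segment_tissues(p$channels, "t1w", seed = 1)
  expect_gte(mean(seg$labels == true_label_map(p)), 0.98)
})

test_that("BPF from labels follows the volume ratio and matches the oracle", {
  fake_seg <- function(gm, wm, csf, bg = 5) {
    structure(list(labels = matrix(rep(c("background", "gm", "wm", "csf"),
                                       c(bg, gm, wm, csf)))),
              class = "tissue_segmentation")
  }
  expect_equal(bpf_from_labels(fake_seg(100, 200, 100)), 0.75)
  expect_equal(bpf_from_labels(fake_seg(100, 200, 0)), 1.0)
  expect_error(bpf_from_labels(fake_seg(0, 0, 0)), "empty")

  for (s in 1:5) {
    p <- clean_phantom(seed = 30 + s, ventricle_scale = 0.7 + 0.3 * s)
    seg <- segment_tissues(p$channels, "t1w", seed = 1)
    expect_lt(abs(bpf_from_labels(seg) - analytic_bpf(p)), 0.02)
  }
})

test_that("segmented BPF decreases monotonically with ventricle scale", {
  scales <- c(0.6, 0.9, 1.2, 1.5, 1.8)
  bpfs <- vapply(scales, function(vs) {
    p <- clean_phantom(seed = 3, ventricle_scale = vs)
    bpf_from_labels(segment_tissues(p$channels, "t1w", seed = 1))
  }, numeric(1))
  expect_equal(cor(scales, bpfs, method = "spearman"), -1)
})

test_that("paired t-test matches the closed-form Student oracle", {
  # oracle: t = mean(d) / (sd(d)/sqrt(n)); p = 2 * pt(-|t|, n - 1)
  y <- c(5, 5, 5)
  x <- y + c(1, 2, 3)
  res <- paired_ttest(x, y)
  t_oracle <- 2 / (1 / sqrt(3))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-t_oracle, 2), tolerance = 1e-12)
  expect_equal(res$p, 0.0742, tolerance = 1e-3)
  expect_equal(res$df, 2)

  swapped <- paired_ttest(y, x)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)

  same <- paired_ttest(x, x)
  expect_equal(same$flag, "zero_variance")
  expect_true(is.na(same$p))

  expect_error(paired_ttest(1:3, 1:4), "equal length")
  expect_error(paired_ttest(1, 2), "n >= 2")
})

test_that("BPF curves handle degenerate and mismatched series", {
  p <- clean_phantom(seed = 33)
  const_series <- function() {
    structure(list(alpha_grid = c(0, 1, 2),
                   images = list(p$channels, p$channels, p$channels),
                   wplus_series = NULL, baseline_index = 1L),
              class = "manipulation_series")
  }
  cv <- bpf_curve(list(const_series(), const_series()), "t1w")
  expect_true(all(cv$flags[-1] == "zero_variance"))
  expect_false(any(cv$significant))
  expect_equal(dim(cv$bpf), c(2, 3))

  single <- bpf_curve(list(const_series()), "t1w")
  expect_true(all(is.na(single$p_values)))
  expect_true(all(single$flags[-1] == "insufficient_subjects"))
  expect_equal(dim(single$bpf), c(1, 3))

  other <- const_series(); other$alpha_grid <- c(0, 1, 3)
  expect_error(bpf_curve(list(const_series(), other), "t1w"), "differing")
})

test_that("intensity profiles cross the ventricle dip", {
  im <- matrix(0.7, 16, 16)
  expect_equal(intensity_profile(im, 4, 9)$row, rep(0.7, 16))
  expect_length(intensity_profile(im, 4, 9)$column, 16)
  expect_error(intensity_profile(im, 0, 1), "bounds")
  expect_error(intensity_profile(im, 1, 17), "bounds")

  p <- clean_phantom(seed = 34, ventricle_scale = 1.4)
  ridx <- round(nrow(p$channels) * 0.51)  # row through the ventricles
  prof <- intensity_profile(p$channels, ridx, round(ncol(p$channels) / 2))
  jmin <- which.min(prof$row)
  expect_true(p$tissue_masks$csf[ridx, jmin] ||
                p$tissue_masks$background[ridx, jmin])
})

test_that("difference maps are signed and localize ventricular change", {
  p1 <- clean_phantom(seed = 35, ventricle_scale = 1.0)
  p2 <- clean_phantom(seed = 35, ventricle_scale = 1.8)
  a <- p1$channels; b <- p2$channels
  expect_true(all(difference_map(a, a) == 0))
  expect_equal(difference_map(a, b), -difference_map(b, a))
  expect_error(difference_map(a, a[1:32, 1:32, ]), "shape")

  # enlarging the ventricle lowers T1w intensity inside the enlarged region
  d <- difference_map(b, a)[, , 1]
  grew <- p2$tissue_masks$csf & !p1$tissue_masks$csf
  expect_lt(sum(d[grew]), 0)
  expect_lt(mean(d[grew]), -0.1)
})
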