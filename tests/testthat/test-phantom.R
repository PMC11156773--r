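test_that("phantom generation is deterministic and masks partition the image", {
  at <- attribute_record("MS", ventricle_scale = 1.3, lesion_count = 3,
                         contrast = "adc", seed = 11)
  p1 <- make_phantom(at, 64)
  p2 <- make_phantom(at, 64)
  expect_identical(p1, p2)

  for (p in list(p1, clean_phantom(seed = 4))) {
    s <- p$tissue_masks$background + p$tissue_masks$csf +
      p$tissue_masks$gm + p$tissue_masks$wm
    expect_true(all(s == 1))
    expect_true(all(p$channels >= 0 & p$channels <= 1))
  }
})

test_that("lesions are periventricular, optional, and confined to parenchyma", {
  p0 <- make_phantom(attribute_record(lesion_count = 0, seed = 1), 64)
  expect_equal(sum(p0$lesion_mask), 0)

  p <- make_phantom(attribute_record("MS", lesion_count = 5, seed = 7,
                                     contrast = "adc"), 64)
  expect_gt(sum(p$lesion_mask), 0)
  inside <- p$tissue_masks$wm | p$tissue_masks$gm
  expect_true(all(inside[p$lesion_mask]))
})

test_that("CSF area scales with ventricle_scale and BPF decreases with it", {
  area <- function(vs) {
    p <- make_phantom(attribute_record(ventricle_scale = vs, seed = 1), 64,
                      noise_sd = 0)
    sum(p$tissue_masks$csf)
  }
  expect_gt(area(1.5), area(0.8))

  scales <- c(0.6, 0.9, 1.2, 1.5, 1.8)
  bpfs <- vapply(scales, function(vs) {
    analytic_bpf(make_phantom(attribute_record(ventricle_scale = vs, seed = 1),
                              64, noise_sd = 0))
  }, numeric(1))
  expect_true(all(diff(bpfs) < 0))
})

test_that("multi-echo channels decay with TE; ADC channels are identical", {
  p <- make_phantom(attribute_record(seed = 3), 64, noise_sd = 0)
  for (tissue in c("csf", "gm", "wm")) {
    m <- p$tissue_masks[[tissue]]
    means <- vapply(1:3, function(ch) mean(p$channels[, , ch][m]), numeric(1))
    expect_true(all(diff(means) <= 0),
                info = sprintf("%s intensity must not increase with TE", tissue))
  }
  # T1w ordering within each channel: WM > GM > CSF > background
  for (ch in 1:3) {
    pl <- p$channels[, , ch]
    expect_gt(mean(pl[p$tissue_masks$wm]), mean(pl[p$tissue_masks$gm]))
    expect_gt(mean(pl[p$tissue_masks$gm]), mean(pl[p$tissue_masks$csf]))
    expect_gt(mean(pl[p$tissue_masks$csf]), mean(pl[p$tissue_masks$background]))
  }

  pa <- make_phantom(attribute_record(contrast = "adc", seed = 3), 64)
  expect_identical(pa$channels[, , 1], pa$channels[, , 2])
  expect_identical(pa$channels[, , 1], pa$channels[, , 3])
})

test_that("invalid phantom requests are rejected", {
  expect_error(make_phantom(attribute_record(), 48), "power of two")
  expect_error(make_phantom(attribute_record(), 16), "power of two")
  expect_error(make_phantom(attribute_record(ventricle_scale = 40), 64),
               "ventricle")
  expect_error(attribute_record(ventricle_scale = -1), "ventricle_scale")
  expect_error(attribute_record(cortical_thinning = 1.5), "cortical_thinning")
})

test_that("cohort sampling is reproducible with MS shifted toward larger ventricles", {
  hc <- sample_cohort(50, "HC", seed = 21, size = 32)
  ms <- sample_cohort(50, "MS", seed = 21, size = 32)
  expect_length(ms, 50)
  expect_gt(mean(attr(ms, "attrs")$ventricle_scale),
            mean(attr(hc, "attrs")$ventricle_scale))
  expect_gt(mean(attr(ms, "attrs")$lesion_count),
            mean(attr(hc, "attrs")$lesion_count))

  hc2 <- sample_cohort(50, "HC", seed = 21, size = 32)
  expect_identical(attr(hc, "attrs"), attr(hc2, "attrs"))

  expect_error(sample_cohort(0, "HC"), "n must be")
  expect_error(sample_cohort(5, "XX"), "arg")
})

test_that("analytic BPF follows the volume-ratio definition", {
  fake <- function(gm, wm, csf, bg = 10) {
    masks <- list(
      background = matrix(rep(c(TRUE, FALSE), c(bg, gm + wm + csf))),
      gm = matrix(rep(c(FALSE, TRUE, FALSE), c(bg, gm, wm + csf))),
      wm = matrix(rep(c(FALSE, TRUE, FALSE), c(bg + gm, wm, csf))),
      csf = matrix(rep(c(FALSE, TRUE), c(bg + gm + wm, csf)))
    )
    structure(list(tissue_masks = masks), class = "phantom")
  }
  expect_equal(analytic_bpf(fake(100, 200, 100)), 0.75)
  expect_equal(analytic_bpf(fake(100, 200, 0)), 1.0)
  expect_equal(analytic_bpf(fake(0, 0, 50)), 0.0)
  expect_error(analytic_bpf(fake(0, 0, 0)), "empty intracranial")
})
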