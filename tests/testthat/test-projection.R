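test_that("SSIM has the expected fixed points and symmetry", {
  p <- clean_phantom(seed = 5)
  x <- p$channels
  expect_equal(ssim(x, x), 1.0)
  expect_equal(ssim(x, 1 - x), ssim(1 - x, x))
  bin <- matrix(as.numeric(outer(1:32, 1:32, "+") %% 2 == 0), 32, 32)
  expect_lt(ssim(bin, 1 - bin), 1)
  expect_error(ssim(x, x[1:32, 1:32, ]), "shape")
})

test_that("SSIM-ranked initialization is deterministic and reduces to plain averaging", {
  lm <- asNamespace("latentmorph")
  G <- tiny_generator(seed = 12)
  cfg <- projection_config(iterations = 10, lr_rampup_iters = 2,
                           lr_rampdown_iters = 2, noise_ramp_iters = 5,
                           init_samples = 64, init_top_k = 8, seed = 17)
  # target synthesized from one of the codes the initializer will draw
  zs <- lm$with_seed(cfg$seed, matrix(rnorm(G$d * 64), G$d, 64))
  w0 <- map_latent(G, zs[, 7])
  target <- synth_to_intensity(synthesize(G, w0))
  ini <- init_latent(G, target, cfg)
  expect_equal(which.max(ini$scores), 7)

  ini2 <- init_latent(G, target, cfg)
  expect_identical(ini, ini2)

  cfg_all <- projection_config(iterations = 10, lr_rampup_iters = 2,
                               lr_rampdown_iters = 2, noise_ramp_iters = 5,
                               init_samples = 64, init_top_k = 64, seed = 17)
  ini_all <- init_latent(G, target, cfg_all)
  W <- lm$map_forward(G, zs)$w
  expect_equal(ini_all$init_w, rowMeans(W), tolerance = 1e-12)

  expect_error(projection_config(init_samples = 10, init_top_k = 100))
})

test_that("perceptual distance is a symmetric premetric increasing with noise", {
  emb <- perceptual_embedder(3, seed = 2)
  p <- clean_phantom(seed = 6)
  x <- p$channels
  expect_equal(perceptual_distance(x, x, emb), 0)
  set.seed(13)
  y <- pmin(pmax(x + rnorm(length(x), sd = 0.1), 0), 1)
  expect_equal(perceptual_distance(x, y, emb), perceptual_distance(y, x, emb))
  expect_error(perceptual_distance(x, x[, , 1:2], emb), "shape")

  # monotone on average across noise levels
  set.seed(14)
  lvls <- seq(0.01, 0.4, length.out = 20)
  d <- vapply(lvls, function(s) {
    mean(replicate(3, perceptual_distance(
      x, x + array(rnorm(length(x), sd = s), dim = dim(x)), emb)))
  }, numeric(1))
  expect_gt(cor(lvls, d, method = "spearman"), 0.95)
})

test_that("noise regularizer matches a direct-summation oracle", {
  # independent oracle: literal double loop over pixels and pyramid levels
  oracle <- function(p) {
    total <- 0
    repeat {
      r <- nrow(p)
      sx <- 0; sy <- 0
      for (i in seq_len(r)) {
        for (j in seq_len(r)) {
          jl <- if (j == 1) r else j - 1
          il <- if (i == 1) r else i - 1
          sx <- sx + p[i, j] * p[i, jl]
          sy <- sy + p[i, j] * p[il, j]
        }
      }
      total <- total + (sx^2 + sy^2) / r^2
      if (r <= 8) break
      q <- matrix(0, r / 2, r / 2)
      for (i in seq_len(r / 2)) {
        for (j in seq_len(r / 2)) {
          q[i, j] <- 2 * mean(p[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
        }
      }
      p <- q
    }
    total
  }
  set.seed(15)
  m16 <- matrix(rnorm(256), 16, 16)
  expect_equal(noise_reg(list(m16)), oracle(m16), tolerance = 1e-10)
  expect_equal(noise_reg(list(matrix(0, 8, 8))), 0)
  expect_error(noise_reg(list(matrix(0, 4, 4))), "8x8")

  # white noise is O(1) per level; constant maps are Theta(r^2)
  ones16 <- matrix(1, 16, 16)
  set.seed(16)
  iid <- replicate(20, noise_reg(list(matrix(rnorm(256), 16, 16))))
  expect_gt(noise_reg(list(ones16)) / mean(iid), 10)
})

test_that("projection schedules hit their endpoints and stay smooth", {
  cfg <- projection_config()
  expect_equal(lr_schedule(0, cfg), 0.0)
  expect_equal(lr_schedule(50, cfg), 0.1)
  expect_equal(lr_schedule(1500, cfg), 0.1)
  expect_equal(lr_schedule(2999, cfg), 0.0)
  expect_error(lr_schedule(-1, cfg), "range")
  expect_error(lr_schedule(3000, cfg), "range")
  lr <- lr_schedule(0:2999, cfg)
  expect_lt(max(abs(diff(lr))), cfg$lr_max / 10)

  expect_equal(latent_noise_std(0, 1, cfg), 0.05)
  expect_equal(latent_noise_std(375, 1, cfg), 0.05 * 0.25)
  expect_equal(latent_noise_std(750, 1, cfg), 0)
  expect_equal(latent_noise_std(2000, 1, cfg), 0)
})

test_that("projection optimizes, keeps noise maps normalized, and is reproducible", {
  G <- tiny_generator(seed = 18)
  set.seed(19)
  target <- synth_to_intensity(synthesize(G, map_latent(G, rnorm(8))))
  cfg1 <- projection_config(iterations = 1, lr_rampup_iters = 1,
                            lr_rampdown_iters = 0, noise_ramp_iters = 1,
                            init_samples = 16, init_top_k = 4, seed = 23)
  pr1 <- project_image(G, target, cfg1)
  expect_equal(nrow(pr1$loss_trace), 1)

  cfg <- projection_config(iterations = 40, lr_rampup_iters = 5,
                           lr_rampdown_iters = 10, noise_ramp_iters = 10,
                           init_samples = 32, init_top_k = 8, seed = 23)
  pr <- project_image(G, target, cfg)
  expect_equal(nrow(pr$loss_trace), 40)
  expect_lt(pr$loss_trace$total[40], pr$loss_trace$total[1])
  for (m in pr$noise_maps) {
    expect_lt(abs(mean(m)), 1e-6)
    expect_lt(abs(mean(m^2) - 1), 1e-6)
  }
  pr2 <- project_image(G, target, cfg)
  expect_identical(pr$loss_trace, pr2$loss_trace)

  expect_error(project_image(G, target[1:4, 1:4, ], cfg), "shape")
})
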