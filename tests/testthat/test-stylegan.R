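test_that("mapping network is deterministic with a well-spread output", {
  G <- tiny_generator()
  z <- rnorm(8)
  expect_identical(map_latent(G, z), map_latent(G, z))
  expect_error(map_latent(G, rnorm(5)), "dimension")
  expect_error(map_latent(G, c(NA, rnorm(7))), "finite")

  set.seed(5)
  for (i in 1:5) {
    z2 <- rnorm(8)
    expect_false(isTRUE(all.equal(map_latent(G, z2), map_latent(G, z))))
  }

  # sampled W statistics: finite positive per-component spread
  Z <- matrix(rnorm(8 * 10000), 8)
  W <- asNamespace("latentmorph")$map_forward(G, Z)$w
  sds <- apply(W, 1, sd)
  expect_true(all(is.finite(sds)))
  expect_true(all(sds > 0))
})

test_that("synthesis is pure given fixed noise and broadcasts single w to all layers", {
  G <- tiny_generator(noise_gain = 0.2)
  set.seed(6)
  w <- map_latent(G, rnorm(8))
  expect_identical(synthesize(G, w), synthesize(G, w))

  wmat <- matrix(w, G$L, G$d, byrow = TRUE)
  expect_identical(synthesize(G, w), synthesize(G, wmat))
  expect_error(synthesize(G, wmat[1:3, ]), "rows")

  # fixed explicit noise reproduces exactly; random noise differs
  nz <- lapply(G$noise_res, function(r) matrix(rnorm(r * r), r, r))
  expect_identical(synthesize(G, wmat, nz), synthesize(G, wmat, nz))
  expect_false(identical(synthesize(G, wmat, "random"),
                         synthesize(G, wmat, "random")))
})

test_that("style rows are hierarchical: coarse rows move anatomy, fine rows mostly do not", {
  # on the trained study model, perturbing the 4x4 style row changes the
  # tissue-segmentation geometry far more (per unit intensity change) than
  # perturbing the finest conv row
  G <- e2e_result()$results$trained$model
  set.seed(9)
  lab_frac <- function(a, b) {
    sa <- segment_tissues(synth_to_intensity(a), "t1w", seed = 1)
    sb <- segment_tissues(synth_to_intensity(b), "t1w", seed = 1)
    mean(sa$labels != sb$labels)
  }
  ge <- gl <- me <- ml <- numeric(6)
  for (i in 1:6) {
    w <- map_latent(G, rnorm(G$d))
    wmat <- matrix(w, G$L, G$d, byrow = TRUE)
    base <- synthesize(G, wmat)
    dw <- rnorm(G$d, sd = 0.5 * sd(w))
    we <- wmat; we[1, ] <- we[1, ] + dw          # 4x4 conv row
    wl <- wmat; wl[G$L - 1, ] <- wl[G$L - 1, ] + dw  # finest conv row
    ie <- synthesize(G, we); il <- synthesize(G, wl)
    ge[i] <- lab_frac(ie, base); gl[i] <- lab_frac(il, base)
    me[i] <- mean(abs(ie - base)); ml[i] <- mean(abs(il - base))
  }
  expect_gt(sum(ge) / sum(me), sum(gl) / sum(ml))
})

test_that("training improves the Frechet feature distance over the run", {
  fh <- e2e_result()$results$trained$fid_history
  expect_gte(nrow(fh), 2)
  expect_lt(fh$fid[nrow(fh)], fh$fid[1])
})

test_that("R1 penalty matches analytic values for known discriminators", {
  # constant discriminator
  const_d <- list(score = function(x) rep(1, dim(x)[4]),
                  grad = function(x) x * 0)
  x <- array(rnorm(8 * 8 * 3 * 4), dim = c(8, 8, 3, 4))
  expect_equal(r1_penalty(const_d, x, gamma = 2), 0)

  # linear discriminator D(x) = <a, x>
  a <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  lin_d <- list(
    score = function(x) apply(x, 4, function(xx) sum(a * xx)),
    grad = function(x) {
      g <- x * 0
      for (i in seq_len(dim(x)[4])) g[, , , i] <- a
      g
    }
  )
  gamma <- 1.7
  expect_equal(r1_penalty(lin_d, x, gamma), gamma / 2 * sum(a^2),
               tolerance = 1e-12)

  # homogeneity: doubling the weights quadruples the penalty
  lin_d2 <- list(
    score = function(x) 2 * lin_d$score(x),
    grad = function(x) 2 * lin_d$grad(x)
  )
  expect_equal(r1_penalty(lin_d2, x, gamma), 4 * r1_penalty(lin_d, x, gamma))

  # a real discriminator gives a finite positive value
  D <- tiny_discriminator()
  expect_gt(r1_penalty(D, array(rnorm(8 * 8 * 3 * 2), dim = c(8, 8, 3, 2))), 0)
})

test_that("ADA controller steps and clamps the augmentation probability", {
  cfg <- train_config(ada_step = 0.05, ada_target = 0.6)
  expect_equal(ada_controller_step(1.0, 0.9, cfg), 1.0)
  expect_equal(ada_controller_step(0.0, 0.1, cfg), 0.0)
  expect_equal(ada_controller_step(0.5, 0.9, cfg), 0.55)
  expect_equal(ada_controller_step(0.5, 0.1, cfg), 0.45)
  expect_error(ada_controller_step(1.2, 0.5, cfg))
})

test_that("Frechet distance matches closed forms and validates inputs", {
  expect_equal(frechet_distance(c(0, 0), diag(2), c(0, 0), diag(2)), 0)
  mu2 <- c(2, 0, 0); mu1 <- c(0, 0, 0)
  expect_equal(frechet_distance(mu1, diag(3), mu2, diag(3)), 4)
  expect_equal(frechet_distance(0, matrix(1), 0, matrix(4)), 1)

  set.seed(10)
  A <- crossprod(matrix(rnorm(16), 4))
  B <- crossprod(matrix(rnorm(16), 4))
  m1 <- rnorm(4); m2 <- rnorm(4)
  expect_equal(frechet_distance(m1, A, m2, B),
               frechet_distance(m2, B, m1, A), tolerance = 1e-8)
  expect_gte(frechet_distance(m1, A, m2, B), 0)

  bad <- matrix(c(1, 0.5, -0.5, 1), 2)
  expect_error(frechet_distance(c(0, 0), bad, c(0, 0), diag(2)),
               "symmetric")
  npd <- diag(c(1, -1))
  expect_error(frechet_distance(c(0, 0), npd, c(0, 0), diag(2)),
               "positive semidefinite")
})

test_that("training runs, stays finite, and is seed-reproducible", {
  set.seed(11)
  ph <- sample_cohort(8, "HC", seed = 41, size = 32)
  imgs <- phantom_stack(ph)
  cfg <- train_config(kimg_budget = 2 * 16 / 1000, batch_size = 16, seed = 5)
  tr <- gan_train(imgs, cfg, d = 32,
                  channels = c(`4` = 16L, `8` = 16L, `16` = 8L, `32` = 8L))
  expect_true(all(is.finite(tr$history$d_loss)))
  expect_true(all(is.finite(tr$history$g_loss)))
  expect_true(all(tr$history$ada_p >= 0 & tr$history$ada_p <= 1))
  expect_false(any(vapply(tr$model$params,
                          function(p) any(!is.finite(p)), logical(1))))

  tr2 <- gan_train(imgs, cfg, d = 32,
                   channels = c(`4` = 16L, `8` = 16L, `16` = 8L, `32` = 8L))
  expect_equal(tr$history$d_loss[1], tr2$history$d_loss[1])
  expect_equal(tr$history$g_loss, tr2$history$g_loss)

  expect_error(gan_train(list(), cfg), "empty")
  expect_error(gan_train(list(array(0, c(32, 32, 3)), array(0, c(16, 16, 3))),
                         cfg), "mixed")
})
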