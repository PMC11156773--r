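# Finite-difference validation of the hand-written backward passes, on tiny
# networks where exhaustive central differences are affordable.

test_that("up/down sampling operators are exact adjoints", {
  set.seed(1)
  x <- array(rnorm(8 * 8 * 2 * 2), dim = c(8, 8, 2, 2))
  y <- array(rnorm(16 * 16 * 2 * 2), dim = c(16, 16, 2, 2))
  lm <- asNamespace("latentmorph")
  expect_equal(sum(lm$up2(x) * y), sum(x * lm$up2_bw(y)), tolerance = 1e-12)
  yd <- array(rnorm(4 * 4 * 2 * 2), dim = c(4, 4, 2, 2))
  expect_equal(sum(lm$down2(x) * yd), sum(x * lm$down2_bw(yd)),
               tolerance = 1e-12)
})

test_that("synthesis backward matches finite differences", {
  lm <- asNamespace("latentmorph")
  set.seed(2)
  G <- tiny_generator(noise_gain = 0.3)
  N <- 2
  wplus <- array(rnorm(G$L * G$d * N), dim = c(G$L, G$d, N))
  noise <- lm$make_noise(G, N, "random")
  tgt <- array(rnorm(8 * 8 * 3 * N), dim = c(8, 8, 3, N))
  loss <- function(Gm, wp = wplus, nz = noise) {
    out <- lm$synth_forward(Gm, wp, nz)
    sum((out$img - tgt)^2) / 2
  }
  fwd <- lm$synth_forward(G, wplus, noise, keep = TRUE)
  bw <- lm$synth_backward(G, fwd, fwd$img - tgt, want_params = TRUE,
                          want_noise = TRUE)
  for (nm in c("b8.conv0.w", "b8.conv0.aff.w", "b8.conv0.ngain", "b8.conv0.b",
               "torgb.w", "const")) {
    num <- fd_grad(function(v) { G2 <- G; G2$params[[nm]][] <- v; loss(G2) },
                   G$params[[nm]])
    expect_lt(rel_err(bw$grads[[nm]], num), 1e-6)
  }
  num_w <- fd_grad(function(v) { wp <- wplus; wp[] <- v; loss(G, wp = wp) },
                   as.vector(wplus))
  expect_lt(rel_err(as.vector(bw$dwplus), num_w), 1e-6)
  num_n <- fd_grad(function(v) {
    nz <- noise; nz[[2]][] <- v; loss(G, nz = nz)
  }, as.vector(noise[[2]]))
  expect_lt(rel_err(as.vector(bw$dnoise[[2]]), num_n), 1e-6)
})

test_that("mapping-network backward matches finite differences", {
  lm <- asNamespace("latentmorph")
  set.seed(3)
  G <- tiny_generator()
  N <- 2
  Z <- matrix(rnorm(G$d * N), G$d, N)
  noise <- lm$make_noise(G, N, "zero")
  tgt <- array(rnorm(8 * 8 * 3 * N), dim = c(8, 8, 3, N))
  loss <- function(Gm) {
    w <- lm$map_forward(Gm, Z)$w
    wp <- array(0, dim = c(Gm$L, Gm$d, N))
    for (s in seq_len(Gm$L)) wp[s, , ] <- w
    out <- lm$synth_forward(Gm, wp, noise)
    sum((out$img - tgt)^2) / 2
  }
  mp <- lm$map_forward(G, Z, keep = TRUE)
  wp <- array(0, dim = c(G$L, G$d, N))
  for (s in seq_len(G$L)) wp[s, , ] <- mp$w
  fwd <- lm$synth_forward(G, wp, noise, keep = TRUE)
  bw <- lm$synth_backward(G, fwd, fwd$img - tgt)
  mg <- lm$map_backward(G, mp$cache, apply(bw$dwplus, c(2, 3), sum))
  for (nm in c("map.fc1.w", "map.fc4.b")) {
    num <- fd_grad(function(v) { G2 <- G; G2$params[[nm]][] <- v; loss(G2) },
                   G$params[[nm]], eps = 1e-4)
    expect_lt(rel_err(mg[[nm]], num), 1e-5)
  }
})

test_that("discriminator backward matches finite differences", {
  lm <- asNamespace("latentmorph")
  set.seed(4)
  D <- tiny_discriminator()
  x <- array(rnorm(8 * 8 * 3 * 3), dim = c(8, 8, 3, 3))
  loss <- function(Dm, xx = x) sum(lm$disc_forward(Dm, xx)$score^2) / 2
  fwd <- lm$disc_forward(D, x, keep = TRUE)
  bw <- lm$disc_backward(D, fwd, fwd$score, want_dx = TRUE)
  for (nm in c("fromrgb.w", "d8.conv0.w", "d8.skip.w", "final.conv.w",
               "final.fc2.w", "final.fc1.b")) {
    num <- fd_grad(function(v) { D2 <- D; D2$params[[nm]][] <- v; loss(D2) },
                   D$params[[nm]])
    expect_lt(rel_err(bw$grads[[nm]], num), 1e-6)
  }
  num_x <- fd_grad(function(v) { xx <- x; xx[] <- v; loss(D, xx) },
                   as.vector(x))
  expect_lt(rel_err(as.vector(bw$dx), num_x), 1e-6)
})
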