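test_that("image round-trips preserve intensities", {
  set.seed(41)
  img <- array(runif(32 * 32 * 3), dim = c(32, 32, 3))

  f_nii <- tempfile(fileext = ".nii.gz")
  write_image(img, f_nii)
  back <- read_image(f_nii)
  expect_equal(dim(back$image), dim(img))
  expect_lt(max(abs(back$image - img)), 1 / 65535)
  expect_equal(back$meta$format, "nifti")

  f_png <- tempfile(fileext = ".png")
  write_image(img, f_png)
  back8 <- read_image(f_png)
  expect_equal(dim(back8$image), dim(img))
  expect_lt(max(abs(back8$image - img)), 1 / 255)

  gray <- matrix(runif(64), 8, 8)
  f_g <- tempfile(fileext = ".png")
  write_image(gray, f_g)
  expect_lt(max(abs(read_image(f_g)$image - gray)), 1 / 255)

  expect_error(read_image("no/such/file.png"), "no/such/file.png")
  expect_error(read_image(tempfile(fileext = ".bmp")), "format|found")
  expect_error(write_image(gray, tempfile(fileext = ".xyz")), "format")
})

test_that("phantom cohorts export with metadata", {
  ph <- sample_cohort(3, "MS", seed = 51, size = 32)
  d <- tempfile("export")
  tab <- export_cohort(ph, d, format = "nifti")
  expect_true(file.exists(file.path(d, "metadata.csv")))
  expect_equal(nrow(tab), 3)
  got <- read_image(tab$path[1])
  expect_equal(dim(got$image), c(32, 32, 3))
  expect_lt(max(abs(got$image - ph[[1]]$channels)), 1e-5)
})

test_that("pipeline configuration round-trips through YAML", {
  cfg <- pipeline_config(seed = 9, out_root = "somewhere", contrast = "adc")
  cfg$train$kimg <- 3.5
  f <- tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, f)
  cfg2 <- read_pipeline_config(f)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("checkpoints carry a version field", {
  G <- tiny_generator()
  f <- tempfile(fileext = ".rds")
  save_model(G, f)
  G2 <- load_model(f)
  expect_identical(G2$params, G$params)
  saveRDS(list(object = 1), f)
  expect_error(load_model(f), "version")
})

test_that("a tiny pipeline completes, caches, and validates its config", {
  cfg <- pipeline_config(seed = 3, out_root = tempfile("pipe"))
  cfg$phantom$n_per_cohort <- 20L
  cfg$phantom$size <- 32L
  cfg$train$kimg <- 0.35
  cfg$train$batch_size <- 8L
  cfg$train$d <- 16L
  cfg$train$channels <- c(`4` = 16L, `8` = 16L, `16` = 8L, `32` = 8L)
  cfg$project$n_per_cohort <- 3L
  cfg$project$iterations <- 20L
  cfg$project$init_samples <- 32L
  cfg$project$init_top_k <- 8L
  cfg$direction$folds <- 3L
  cfg$edit$n_alpha <- 3L

  res <- run_pipeline(cfg)
  m <- res$manifest
  expect_named(m$stages, c("simulate", "train", "project", "direction",
                           "edit", "analyze"))
  expect_true(all(vapply(m$stages, function(s) s$status == "complete",
                         logical(1))))
  expect_true(file.exists(file.path(cfg$out_root, "manifest.json")))
  expect_true(file.exists(file.path(cfg$out_root, "pipeline.log.jsonl")))
  expect_equal(dim(res$results$bpf_hc$bpf), c(3, 3))

  # second run: every stage is a cache hit and hashes agree
  res2 <- run_pipeline(cfg)
  expect_true(all(vapply(res2$manifest$stages, function(s) isTRUE(s$cached),
                         logical(1))))
  expect_identical(res$manifest$artifacts, res2$manifest$artifacts)

  bad <- cfg; bad$direction <- NULL
  expect_error(run_pipeline(bad), "direction")
})
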