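# Shared fixtures: tiny models and a central-difference gradient helper.

tiny_channels <- c(`4` = 6L, `8` = 5L)

tiny_generator <- function(seed = 3, noise_gain = 0) {
  G <- generator_model(res = 8, d = 8, channels = tiny_channels, seed = seed)
  if (noise_gain != 0) {
    for (nm in names(G$params)) {
      if (grepl("ngain", nm)) G$params[[nm]] <- noise_gain
    }
  }
  G
}

tiny_discriminator <- function(seed = 4) {
  discriminator_model(res = 8, channels = tiny_channels, seed = seed)
}

toy_generator <- function(seed = 1) {
  generator_model(res = 32, d = 64, seed = seed)
}

fd_grad <- function(f, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / (max(abs(b)) + 1e-12)
}

# The scaled-down end-to-end study shared by the acceptance test and the
# trained-model property tests. run_pipeline() caches stage artifacts under
# out_root, so repeated calls within (or across) test files are cheap.
e2e_config <- function() {
  cfg <- pipeline_config(seed = 7, out_root = file.path(tempdir(), "e2e-study"))
  cfg$train$fid_interval <- 100000L  # Frechet metric at start and end only
  cfg
}

e2e_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_pipeline(e2e_config())
    cache
  }
})

clean_phantom <- function(seed = 2, ...) {
  make_phantom(attribute_record(seed = seed, ...), size = 64, noise_sd = 0)
}

true_label_map <- function(p) {
  lab <- matrix("background", nrow(p$tissue_masks$csf), ncol(p$tissue_masks$csf))
  lab[p$tissue_masks$csf] <- "csf"
  lab[p$tissue_masks$gm] <- "gm"
  lab[p$tissue_masks$wm] <- "wm"
  lab
}
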