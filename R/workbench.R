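# Pipeline plumbing: image I/O (PNG, NIfTI), declarative configuration,
# checkpointing, and an end-to-end driver running
# simulate -> train -> project -> direction -> edit -> analyze with cached,
# hash-verified stage artifacts and a JSON manifest.

#' Read an image from PNG or NIfTI
#'
#' Intensities are rescaled to \[0, 1\] with the original range recorded in
#' the metadata. NIfTI volumes written by [write_image()] (H x W x 1 x C)
#' come back as (H, W, C) arrays.
#'
#' @param path File path ending in `.png`, `.nii`, or `.nii.gz`.
#' @return List with `image` (array in \[0, 1\]) and `meta` (format, path,
#'   original range).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    img <- png::readPNG(path)
    meta <- list(format = "png", path = path, original_range = c(0, 1))
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    vol <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop(sprintf(
                      "corrupt or unreadable NIfTI header in %s: %s",
                      path, conditionMessage(e))))
    img <- as.array(vol)
    d <- dim(img)
    if (length(d) == 4 && d[3] == 1) {
      img <- array(img, dim = c(d[1], d[2], d[4]))
    }
    rng <- range(img)
    meta <- list(format = "nifti", path = path, original_range = rng)
    if (rng[1] < 0 || rng[2] > 1) {
      span <- if (diff(rng) > 0) diff(rng) else 1
      img <- (img - rng[1]) / span
    }
  } else {
    stop(sprintf("unknown image format for %s (supported: PNG, NIfTI)", path))
  }
  list(image = img, meta = meta)
}

#' Write an image to PNG or NIfTI
#'
#' PNG output is 8-bit (single- or three-channel); NIfTI output stores the
#' exact floating-point intensities as an H x W x 1 x C volume and is the
#' lossless interchange format.
#'
#' @param img Matrix or (H, W, C) array with intensities in \[0, 1\].
#' @param path Output path ending in `.png`, `.nii`, or `.nii.gz`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  lower <- tolower(path)
  if (grepl("\\.png$", lower)) {
    png::writePNG(pmin(pmax(img, 0), 1), path)
  } else if (grepl("\\.nii(\\.gz)?$", lower)) {
    d <- dim(img)
    vol <- if (length(d) == 3) array(img, dim = c(d[1], d[2], 1L, d[3])) else img
    RNifti::writeNifti(RNifti::asNifti(vol), path)
  } else {
    stop(sprintf("unknown image format for %s (supported: PNG, NIfTI)", path))
  }
  invisible(path)
}

#' Save a model checkpoint
#'
#' Single-file archive holding the object (generator, discriminator, or a
#' whole [gan_train()] result) together with a mandatory format-version
#' field and the package version.
#'
#' @param object Object to store.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
save_model <- function(object, path) {
  saveRDS(list(
    checkpoint_version = 1L,
    package_version = as.character(utils::packageVersion("latentmorph")),
    object = object
  ), path)
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path Checkpoint file.
#' @return The stored object.
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$checkpoint_version)) stop("not a valid checkpoint: missing version field")
  ck$object
}

hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Default pipeline configuration
#'
#' Declarative configuration for [run_pipeline()], one block per stage.
#' Every stage seed is derived from the global seed. The edit-stage alpha
#' grid is scaled to the latent cloud: when `alpha_max` is `NULL` it is set
#' to `alpha_scale` times the median absolute hyperplane distance of the
#' projected codes.
#'
#' @param seed Global seed.
#' @param out_root Output/cache directory.
#' @param contrast `"t1w_multiecho"` or `"adc"`.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_root = tempfile("latentmorph_run"),
                            contrast = "t1w_multiecho") {
  structure(list(
    seed = as.integer(seed), out_root = out_root, contrast = contrast,
    phantom = list(n_per_cohort = 1000L, size = 32L, noise_sd = 0.02,
                   slice_position = NULL),
    train = list(kimg = 10, batch_size = 16L, d = 64L, r1_gamma = 1,
                 fid_interval = 0L,
                 channels = c(`4` = 48L, `8` = 48L, `16` = 24L, `32` = 12L)),
    project = list(n_per_cohort = 20L, iterations = 150L,
                   init_samples = 256L, init_top_k = 25L),
    direction = list(folds = 10L, cost = 1),
    edit = list(alpha_max = NULL, alpha_scale = 6, n_alpha = 6L),
    analyze = list(significance_threshold = 0.001)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Missing fields fall back to [pipeline_config()] defaults; the
#' configuration round-trips through [write_pipeline_config()] unchanged.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- pipeline_config()
  merged <- utils::modifyList(unclass(base), user, keep.null = TRUE)
  if (!is.null(merged$train$channels)) {
    ch <- unlist(merged$train$channels)
    merged$train$channels <- stats::setNames(as.integer(ch), names(ch))
  }
  structure(merged, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A `pipeline_config`.
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$train$channels)) {
    cfg$train$channels <- as.list(cfg$train$channels)  # keep names in YAML
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

log_line <- function(logfile, event, data = list()) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), data)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = logfile, append = TRUE, sep = "")
}

run_stage <- function(name, config, stage_input_hash, out_root, logfile,
                      compute) {
  key <- hash_obj(list(name = name, cfg = config, input = stage_input_hash))
  art_file <- file.path(out_root, paste0(name, ".rds"))
  meta_file <- file.path(out_root, paste0(name, ".hash"))
  if (file.exists(art_file) && file.exists(meta_file) &&
      identical(readLines(meta_file, warn = FALSE)[1], key)) {
    log_line(logfile, "stage_cached", list(stage = name, hash = key))
    return(list(value = readRDS(art_file), hash = key, cached = TRUE,
                file = art_file))
  }
  log_line(logfile, "stage_start", list(stage = name, hash = key))
  value <- tryCatch(compute(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  saveRDS(value, art_file)
  writeLines(key, meta_file)
  log_line(logfile, "stage_done",
           list(stage = name, artifact = basename(art_file),
                md5 = unname(tools::md5sum(art_file))))
  list(value = value, hash = key, cached = FALSE, file = art_file)
}

#' Run the full latent-manipulation pipeline
#'
#' Executes simulate -> train -> project -> direction -> edit -> analyze on
#' synthetic cohorts: samples HC and MS phantoms, trains the style-based
#' GAN, projects held-out subjects of both cohorts into W+, fits the
#' cohort-separating SVM direction, manipulates HC subjects toward MS
#' (positive alpha) and MS subjects toward HC (negative alpha), and computes
#' BPF trajectories with paired tests. Completed stages are cached on disk
#' and reused when their configuration hash matches.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return List with `manifest` (also written as JSON to the output root)
#'   and `results` (trained model, projections, direction, manipulation
#'   series, and `bpf_hc` / `bpf_ms` curves).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  for (block in c("phantom", "train", "project", "direction", "edit",
                  "analyze")) {
    if (is.null(config[[block]])) {
      stop(sprintf("pipeline config is missing the '%s' block", block))
    }
  }
  out_root <- config$out_root
  dir.create(out_root, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_root, "pipeline.log.jsonl")
  seed <- config$seed
  stages <- list()

  sim <- run_stage("simulate", config["phantom"], config$contrast, out_root,
                   logfile, function() {
    pc <- config$phantom
    list(
      hc = sample_cohort(pc$n_per_cohort, "HC", config$contrast,
                         seed = seed + 101L, size = pc$size,
                         noise_sd = pc$noise_sd,
                         slice_position = pc$slice_position),
      ms = sample_cohort(pc$n_per_cohort, "MS", config$contrast,
                         seed = seed + 102L, size = pc$size,
                         noise_sd = pc$noise_sd,
                         slice_position = pc$slice_position)
    )
  })
  stages$simulate <- list(hash = sim$hash, cached = sim$cached,
                          seed = seed + 101L)
  if (verbose) message("simulate: done (cached = ", sim$cached, ")")

  trn <- run_stage("train", config["train"], sim$hash, out_root, logfile,
                   function() {
    tc <- config$train
    images <- c(lapply(sim$value$hc, function(p) p$channels),
                lapply(sim$value$ms, function(p) p$channels))
    gan_train(images,
              train_config(kimg_budget = tc$kimg, batch_size = tc$batch_size,
                           r1_gamma = tc$r1_gamma,
                           fid_interval = tc$fid_interval,
                           seed = seed + 103L),
              d = tc$d,
              channels = if (!is.null(tc$channels)) {
                stats::setNames(as.integer(tc$channels), names(tc$channels))
              },
              verbose = verbose)
  })
  stages$train <- list(hash = trn$hash, cached = trn$cached,
                       seed = seed + 103L)
  if (verbose) message("train: done (cached = ", trn$cached, ")")

  prj <- run_stage("project", config["project"], trn$hash, out_root, logfile,
                   function() {
    pc <- config$project
    G <- trn$value$model
    emb <- perceptual_embedder(G$img_channels)
    project_cohort <- function(phantoms, base_seed) {
      lapply(seq_along(phantoms), function(i) {
        if (verbose) message(sprintf("  projecting subject %d/%d",
                                     i, length(phantoms)))
        project_image(G, phantoms[[i]],
                      projection_config(
                        iterations = pc$iterations,
                        noise_ramp_iters = min(750L, max(1L, pc$iterations %/% 4L)),
                        lr_rampdown_iters = min(250L, max(1L, pc$iterations %/% 3L)),
                        lr_rampup_iters = min(50L, max(1L, pc$iterations %/% 6L)),
                        init_samples = pc$init_samples,
                        init_top_k = pc$init_top_k,
                        seed = base_seed + i),
                      embedder = emb)
      })
    }
    list(hc = project_cohort(sim$value$hc[seq_len(pc$n_per_cohort)], seed + 2000L),
         ms = project_cohort(sim$value$ms[seq_len(pc$n_per_cohort)], seed + 3000L))
  })
  stages$project <- list(hash = prj$hash, cached = prj$cached,
                         seed = seed + 2000L)
  if (verbose) message("project: done (cached = ", prj$cached, ")")

  dir_ <- run_stage("direction", config["direction"], prj$hash, out_root,
                    logfile, function() {
    with_seed(seed + 104L, {
      fit_direction(prj$value$hc, prj$value$ms,
                    folds = config$direction$folds,
                    cost = config$direction$cost, attribute = "MS")
    })
  })
  stages$direction <- list(hash = dir_$hash, cached = dir_$cached,
                           seed = seed + 104L)
  if (verbose) message("direction: done (cached = ", dir_$cached, ")")

  edt <- run_stage("edit", config["edit"], dir_$hash, out_root, logfile,
                   function() {
    ec <- config$edit
    direction <- dir_$value
    alpha_max <- ec$alpha_max
    if (is.null(alpha_max)) {
      dists <- vapply(c(prj$value$hc, prj$value$ms), function(pr) {
        abs(sum(flatten_wplus(pr) * direction$n) - direction$hyperplane_offset)
      }, numeric(1))
      alpha_max <- ec$alpha_scale * stats::median(dists)
    }
    grid_pos <- seq(0, alpha_max, length.out = ec$n_alpha)
    grid_neg <- seq(-alpha_max, 0, length.out = ec$n_alpha)
    G <- trn$value$model
    list(
      alpha_max = alpha_max,
      hc = lapply(prj$value$hc, function(pr) {
        manipulate_latent(G, pr, direction, grid_pos)
      }),
      ms = lapply(prj$value$ms, function(pr) {
        manipulate_latent(G, pr, direction, grid_neg)
      })
    )
  })
  stages$edit <- list(hash = edt$hash, cached = edt$cached)
  if (verbose) message("edit: done (cached = ", edt$cached, ")")

  ana <- run_stage("analyze", config["analyze"], edt$hash, out_root, logfile,
                   function() {
    thr <- config$analyze$significance_threshold
    ctr <- if (config$contrast == "adc") "adc" else "t1w"
    list(
      bpf_hc = bpf_curve(edt$value$hc, ctr, seed = seed + 105L,
                         significance_threshold = thr),
      bpf_ms = bpf_curve(edt$value$ms, ctr, seed = seed + 106L,
                         significance_threshold = thr)
    )
  })
  stages$analyze <- list(hash = ana$hash, cached = ana$cached,
                         seed = seed + 105L)
  if (verbose) message("analyze: done (cached = ", ana$cached, ")")

  bpf_hc <- ana$value$bpf_hc
  manifest <- list(
    package = "latentmorph",
    package_version = as.character(utils::packageVersion("latentmorph")),
    r_version = R.version.string,
    global_seed = seed,
    contrast = config$contrast,
    stages = lapply(stages, function(s) {
      s$status <- "complete"; s
    }),
    artifacts = local({
      fs <- list.files(out_root, pattern = "\\.rds$", full.names = TRUE)
      as.list(tools::md5sum(fs))
    }),
    summary = list(
      alpha_max = edt$value$alpha_max,
      mean_bpf_hc = colMeans(bpf_hc$bpf),
      mean_bpf_ms = colMeans(ana$value$bpf_ms$bpf),
      significance_onset_alpha_hc = {
        sig <- which(bpf_hc$significant)
        if (length(sig)) min(bpf_hc$alpha_grid[sig]) else NA
      }
    )
  )
  jsonlite::write_json(manifest, file.path(out_root, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  list(manifest = manifest,
       results = list(trained = trn$value, projections = prj$value,
                      direction = dir_$value, edits = edt$value,
                      bpf_hc = ana$value$bpf_hc, bpf_ms = ana$value$bpf_ms))
}
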