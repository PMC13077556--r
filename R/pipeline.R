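## Pipeline driver: simulate -> preprocess -> detect (classical ring
## detector -> despeckle -> skeletonize -> Hough) -> size -> evaluate.
## Each stage writes its outputs into a flat run directory in standard
## formats (MRC, PNG, CSV, JSON, YAML) and is content-addressed by the hash
## of its configuration plus its upstream hash: re-running an unchanged
## configuration skips completed stages. Downstream stages always consume
## the *reloaded* stage outputs, so a skipped and a recomputed stage feed
## downstream identically and re-runs are byte-identical. nm is the single
## physical unit at every interface; file formats carry their native units
## (MRC headers in Angstrom).

#' Pipeline configuration
#'
#' @param scene a [scene_spec()] (its seed is overridden per image from the
#'   global seed).
#' @param n_images number of micrographs to simulate.
#' @param preprocess a [preprocess_config()]; the detection path uses its
#'   `bin_factor` (bandpass is reserved for lipoprotein/ice models and is
#'   not applied before bilayer detection).
#' @param hough a [hough_config()].
#' @param detector list of [classical_bilayer_detector()] arguments
#'   (`radii_px`, `snr_threshold`, ...).
#' @param bin_width size-distribution histogram bin width, nm.
#' @param eval_fraction fraction of images used for evaluation.
#' @param seed global seed; fully determines simulate and detect outputs.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(scene = scene_spec(), n_images = 5L,
                            preprocess = preprocess_config(),
                            hough = hough_config(r_max = 60L),
                            detector = list(radii_px = 6:40, snr_threshold = 6),
                            bin_width = 10, eval_fraction = 1, seed = 1L) {
  stopifnot(inherits(scene, "scene_spec"),
            inherits(preprocess, "preprocess_config"),
            inherits(hough, "hough_config"))
  if (n_images < 1) stop("n_images must be >= 1")
  structure(list(scene = scene, n_images = as.integer(n_images),
                 preprocess = preprocess, hough = hough, detector = detector,
                 bin_width = bin_width, eval_fraction = eval_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  h <- cfg$hough
  if (!(h$r_min > 0 && h$r_max > h$r_min))
    stop("config validation: need 0 < r_min < r_max in hough config")
  binned <- cfg$scene$image_shape %/% cfg$preprocess$bin_factor
  if (h$r_max >= min(binned) / 2)
    stop("config validation: hough r_max must be < half the binned image dimension")
  if (length(cfg$detector$radii_px %||% 6:40) == 0)
    stop("config validation: detector radius sweep is empty")
  invisible(TRUE)
}

read_manifest <- function(dir) {
  p <- file.path(dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else NULL
}

stage_done <- function(manifest, name, hash, files) {
  !is.null(manifest) && identical(manifest$hashes[[name]], unname(hash)) &&
    all(file.exists(files))
}

#' Run the full pipeline into a run directory
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir run directory (created if needed).
#' @param verbose print stage progress.
#' @return (invisibly) list with `records` (pooled particle records),
#'   `distribution` ([size_distribution()]), `metrics`, `size_errors`,
#'   `manifest`, and `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir, verbose = FALSE) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest0 <- read_manifest(out_dir)
  hashes <- list(); timings <- list(); skipped <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, hash, files, compute) {
    t0 <- Sys.time()
    if (stage_done(manifest0, name, hash, files)) {
      skipped <<- c(skipped, name)
      say("stage %s: up to date, skipped", name)
    } else {
      tryCatch(compute(),
               error = function(e) stop(sprintf("stage '%s' failed: %s",
                                                name, conditionMessage(e)),
                                        call. = FALSE))
      say("stage %s: computed (%.2fs)", name,
          as.numeric(Sys.time() - t0, units = "secs"))
    }
    hashes[[name]] <<- unname(hash)
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  }
  img_id <- sprintf("img%03d", seq_len(cfg$n_images))
  f <- cfg$preprocess$bin_factor

  ## --- simulate ---------------------------------------------------------
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth", "masks"), recursive = TRUE,
             showWarnings = FALSE)
  img_files <- file.path(out_dir, "images", paste0(img_id, ".mrc"))
  truth_file <- file.path(out_dir, "truth", "truth.csv")
  holes_file <- file.path(out_dir, "truth", "holes.csv")
  h_sim <- config_hash(list(scene = unclass(cfg$scene), n = cfg$n_images,
                            seed = cfg$seed))
  stage("simulate", h_sim, c(img_files, truth_file, holes_file), function() {
    sims <- simulate_dataset(cfg$scene, cfg$n_images, cfg$seed)
    tt <- list(); hh <- list()
    for (i in seq_along(sims)) {
      write_mrc(sims[[i]]$micrograph, img_files[i])
      tr <- sims[[i]]$truth
      if (nrow(tr$particles))
        tt[[i]] <- cbind(image = img_id[i], tr$particles)
      hh[[i]] <- data.frame(
        image = img_id[i],
        present = !is.null(tr$hole),
        cy = if (is.null(tr$hole)) NA_real_ else tr$hole$center[1],
        cx = if (is.null(tr$hole)) NA_real_ else tr$hole$center[2],
        radius_px = if (is.null(tr$hole)) NA_real_ else tr$hole$radius_px)
      for (cl in names(tr$class_masks))
        write_mask_png(tr$class_masks[[cl]],
                       file.path(out_dir, "truth", "masks",
                                 sprintf("%s_%s.png", img_id[i], cl)))
    }
    tt <- tt[!vapply(tt, is.null, TRUE)]
    write.csv(if (length(tt)) do.call(rbind, tt) else
                cbind(image = character(0), new_records())[0, ],
              truth_file, row.names = FALSE)
    write.csv(do.call(rbind, hh), holes_file, row.names = FALSE)
  })
  images <- lapply(img_files, read_micrograph)
  truth <- read.csv(truth_file, stringsAsFactors = FALSE)
  holes <- read.csv(holes_file, stringsAsFactors = FALSE)

  ## --- preprocess (bin; bilayer path stays unfiltered) ------------------
  dir.create(file.path(out_dir, "preproc"), showWarnings = FALSE)
  pre_files <- file.path(out_dir, "preproc", paste0(img_id, ".mrc"))
  h_pre <- config_hash(list(up = hashes$simulate, pre = unclass(cfg$preprocess)))
  stage("preprocess", h_pre, pre_files, function() {
    for (i in seq_along(images))
      write_mrc(bin_image(images[[i]], f), pre_files[i])
  })
  binned <- lapply(pre_files, read_micrograph)

  ## --- detect -----------------------------------------------------------
  dir.create(file.path(out_dir, "detect", "masks"), recursive = TRUE,
             showWarnings = FALSE)
  rec_file <- file.path(out_dir, "detect", "records.csv")
  mask_files <- file.path(out_dir, "detect", "masks",
                          paste0(img_id, "_EV_bilayer.png"))
  h_det <- config_hash(list(up = hashes$preprocess, det = cfg$detector,
                            hough = unclass(cfg$hough)))
  stage("detect", h_det, c(rec_file, mask_files), function() {
    out <- list()
    for (i in seq_along(binned)) {
      det <- do.call(classical_bilayer_detector,
                     c(list(m = binned[[i]]), cfg$detector))
      clean <- despeckle(det)
      write_mask_png(clean, mask_files[i])
      skel <- mask_to_outlines(clean, "skeleton")
      rec <- hough_circles(skel, cfg$hough, binned[[i]]$pixel_size, "rings")
      ctx <- list(image_shape = dim(binned[[i]]$pixels))
      if (isTRUE(holes$present[i]))
        ctx$hole <- list(center = c((holes$cy[i] - 0.5) / f + 0.5,
                                    (holes$cx[i] - 0.5) / f + 0.5),
                         radius_px = holes$radius_px[i] / f)
      ice_path <- file.path(out_dir, "truth", "masks",
                            sprintf("%s_ice.png", img_id[i]))
      if (file.exists(ice_path))
        ctx$ice_mask <- (bin_image(read_mask_png(ice_path) * 1, f) > 0.25) * 1L
      rec <- exclude_artifacts(rec, ctx)
      if (nrow(rec)) out[[length(out) + 1L]] <- cbind(image = img_id[i], rec)
    }
    write.csv(if (length(out)) do.call(rbind, out) else
                cbind(image = character(0), new_records())[0, ],
              rec_file, row.names = FALSE)
  })
  records <- read.csv(rec_file, stringsAsFactors = FALSE)
  if (nrow(records)) records$reason <- as.character(records$reason)

  ## --- size -------------------------------------------------------------
  dir.create(file.path(out_dir, "size"), showWarnings = FALSE)
  dist_file <- file.path(out_dir, "size", "distribution.json")
  histo_file <- file.path(out_dir, "size", "histogram.csv")
  h_size <- config_hash(list(up = hashes$detect, bin_width = cfg$bin_width))
  stage("size", h_size, c(dist_file, histo_file), function() {
    dist <- size_distribution(records, cfg$bin_width)
    jsonlite::write_json(
      list(class_name = dist$class_name, median_nm = dist$median,
           sd_nm = dist$sd, count = dist$count,
           median_defined = dist$median_defined, sd_defined = dist$sd_defined),
      dist_file, auto_unbox = TRUE, digits = NA, null = "null")
    write.csv(data.frame(bin_lo = head(dist$histogram$breaks, -1),
                         bin_hi = dist$histogram$breaks[-1],
                         count = dist$histogram$counts),
              histo_file, row.names = FALSE)
  })
  distribution <- size_distribution(records, cfg$bin_width)

  ## --- evaluate ---------------------------------------------------------
  dir.create(file.path(out_dir, "evaluate"), showWarnings = FALSE)
  met_file <- file.path(out_dir, "evaluate", "metrics.json")
  h_eval <- config_hash(list(up = hashes$detect, fraction = cfg$eval_fraction,
                             seed = cfg$seed))
  matches <- lapply(seq_along(img_id), function(i) {
    tr <- truth[truth$image == img_id[i] & truth$class_name == "EV_bilayer", ,
                drop = FALSE]
    tr$cy <- (tr$cy - 0.5) / f + 0.5
    tr$cx <- (tr$cx - 0.5) / f + 0.5
    tr$radius_px <- tr$radius_px / f
    match_particles(records[records$image == img_id[i], , drop = FALSE], tr)
  })
  pooled <- list(tp = sum(vapply(matches, `[[`, 1L, "tp")),
                 fp = sum(vapply(matches, `[[`, 1L, "fp")),
                 fn = sum(vapply(matches, `[[`, 1L, "fn")))
  metrics <- if (pooled$tp + pooled$fp + pooled$fn > 0)
    detection_metrics(pooled) else NULL
  errs <- unlist(lapply(matches, function(m) m$pairs$diameter_error_nm))
  errs <- errs[is.finite(errs)]
  size_errors <- if (length(errs))
    list(bias_nm = mean(errs), rmse_nm = sqrt(mean(errs^2)), n = length(errs))
  else NULL
  stage("evaluate", h_eval, met_file, function() {
    jsonlite::write_json(
      list(counts = pooled, metrics = metrics[c("precision", "recall",
                                                "f1", "accuracy")],
           size_errors = size_errors),
      met_file, auto_unbox = TRUE, digits = NA, null = "null")
  })

  manifest <- list(package_version = as.character(utils::packageVersion("cryosizer")),
                   seed = cfg$seed, hashes = hashes, timings = timings,
                   skipped = skipped)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  yaml::write_yaml(serialize_config(cfg), file.path(out_dir, "config.yaml"))
  invisible(list(records = records, distribution = distribution,
                 metrics = metrics, size_errors = size_errors,
                 matches = matches, manifest = manifest, out_dir = out_dir))
}

## config <-> plain-list serialization (lossless round trip through YAML)
serialize_config <- function(cfg) strip_classes(cfg)

#' Read a pipeline configuration from YAML
#'
#' Inverse of the `config.yaml` written by [run_pipeline()]; configurations
#' round-trip losslessly.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  scene <- scene_spec(
    image_shape = unlist(y$scene$image_shape),
    pixel_size = y$scene$pixel_size,
    classes = lapply(y$scene$classes, function(cl)
      class_spec(cl$class_name, diameter = cl$diameter, density = cl$density,
                 depth = cl$depth, leaflet_separation = cl$leaflet_separation,
                 leaflet_sigma = cl$leaflet_sigma, edge_width = cl$edge_width)),
    background_gradient_amplitude = y$scene$background_gradient_amplitude,
    noise = y$scene$noise, hole_rim = y$scene$hole_rim,
    background_level = y$scene$background_level,
    arc_completeness = if (!is.null(y$scene$arc_completeness))
      unlist(y$scene$arc_completeness),
    placement = y$scene$placement %||% "free",
    seed = y$scene$seed)
  pipeline_config(
    scene = scene, n_images = y$n_images,
    preprocess = preprocess_config(y$preprocess$filter_large,
                                   y$preprocess$filter_small,
                                   y$preprocess$bin_factor,
                                   unlist(y$preprocess$normalize_percentiles)),
    hough = hough_config(y$hough$r_min, y$hough$r_max,
                         y$hough$score_threshold_circles,
                         y$hough$score_threshold_rings),
    detector = list(radii_px = unlist(y$detector$radii_px),
                    snr_threshold = y$detector$snr_threshold),
    bin_width = y$bin_width, eval_fraction = y$eval_fraction, seed = y$seed)
}
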