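test_that("annotation sets validate boxes and report provenance arithmetic", {
  img <- matrix(0, 100, 100)
  items <- list(
    list(image_id = "a", box = c(5, 5, 10, 10),
         labels = matrix(1L, 10, 10), class_name = "EV_bilayer"),
    list(image_id = "b", box = c(1, 1, 5, 8),
         labels = matrix(0L, 5, 8), class_name = "EV_bilayer"))
  ann <- annotation_set(items)
  st <- annotation_stats(ann, list(a = img, b = img))
  expect_equal(st$n_rois, 2L)
  expect_equal(st$fraction_of_total_area, (100 + 40) / 20000)
  expect_equal(st$positive_px$EV_bilayer, 100)

  expect_error(annotation_set(list()), "empty")
  bad <- items; bad[[1]]$labels <- matrix(1L, 3, 3)
  expect_error(annotation_set(bad), "box-shaped")
  bad2 <- items; bad2[[1]]$class_name <- "nonsense"
  expect_error(annotation_set(bad2), "unknown class")
})

test_that("patch extraction tiles ROIs and counts positives like the raw masks", {
  img <- matrix(rnorm(128 * 128), 128, 128)
  cfg <- model_config("EV_bilayer", patch_size = 32)
  ## exactly patch-sized ROI -> one patch
  one <- annotation_set(list(list(image_id = "a", box = c(10, 10, 32, 32),
                                  labels = matrix(1L, 32, 32),
                                  class_name = "EV_bilayer")))
  expect_length(extract_training_patches(one, list(a = img), cfg), 1L)
  ## double-width ROI -> two non-overlapping tiles
  lab <- matrix(0L, 32, 64); lab[, 1:32] <- 1L
  two <- annotation_set(list(list(image_id = "a", box = c(10, 10, 32, 64),
                                  labels = lab, class_name = "EV_bilayer")))
  p2 <- extract_training_patches(two, list(a = img), cfg)
  expect_length(p2, 2L)
  expect_equal(attr(p2, "positive_fraction"), sum(lab) / length(lab))
  expect_equal(sum(p2[[1]]$labels) + sum(p2[[2]]$labels), sum(lab))
  ## the two tiles cover disjoint image regions
  expect_false(identical(p2[[1]]$pixels, p2[[2]]$pixels))

  ## truth-mask-derived annotations preserve the positive-pixel fraction
  sims <- mixed_training_sims(31, n = 3)
  ann <- annotations_from_truth(sims, "EV_bilayer", seed = 1)
  ## patch size larger than any ROI: one patch per ROI, no tiling crop
  cfgb <- model_config("EV_bilayer", patch_size = 128)
  patches <- extract_training_patches(ann$annotations, ann$images, cfgb)
  direct <- sum(vapply(ann$annotations$items, function(it) sum(it$labels), 1)) /
    sum(vapply(ann$annotations$items, function(it) prod(it$box[3:4]), 1))
  expect_equal(attr(patches, "positive_fraction"), direct, tolerance = 1e-12)

  expect_error(extract_training_patches(one, list(b = img), cfg), "unavailable")
  wrong <- model_config("VLDL", patch_size = 32)
  expect_error(extract_training_patches(one, list(a = img), wrong),
               "does not match")
})

test_that("training is seeded, logged, and learns separable toy patches", {
  ## dark disc on flat background vs flat-only patches: linearly separable
  set.seed(9)
  mk_patch <- function(with_disc) {
    px <- matrix(150 + rnorm(48 * 48, 0, 3), 48, 48)
    lab <- matrix(0L, 48, 48)
    if (with_disc) {
      lab <- draw_disc(lab, 24, 24, 10)
      px[lab > 0] <- px[lab > 0] - 40
    }
    list(pixels = px, labels = lab)
  }
  patches <- c(lapply(1:6, function(i) mk_patch(TRUE)),
               lapply(1:2, function(i) mk_patch(FALSE)))
  cfg <- model_config("small_dense", patch_size = 48, epochs = 20, seed = 7)
  mod <- train_pixel_model(patches, cfg)
  expect_equal(nrow(mod$log), 20L)
  expect_true(all(is.finite(mod$log$loss)))
  expect_lt(mod$log$loss[20], mod$log$loss[1])
  ## training-set pixel accuracy >= 0.95 within 20 epochs
  acc <- mean(vapply(patches, function(p)
    mean((predict_mask(mod, p$pixels)$binary > 0) == (p$labels > 0)), 1))
  expect_gte(acc, 0.95)

  ## determinism: identical data + seed -> identical loss trace and weights
  mod2 <- train_pixel_model(patches, cfg)
  expect_identical(mod$log$loss, mod2$log$loss)
  expect_identical(mod$weights, mod2$weights)

  ## all-negative labels violate the precondition
  neg <- lapply(patches, function(p) { p$labels[] <- 0L; p })
  expect_error(train_pixel_model(neg, cfg), "positive")
})

test_that("the trained classifier matches an independent nnet fit on the same features", {
  skip_if_not_installed("nnet")
  sims <- mixed_training_sims(51, n = 4)
  ann <- annotations_from_truth(sims, "EV_bilayer", seed = 1)
  cfg <- model_config("EV_bilayer", epochs = 20, seed = 2, max_pixels = 6000)
  patches <- extract_training_patches(ann$annotations, ann$images, cfg)
  mod <- train_pixel_model(patches, cfg)

  ## independent route: nnet on pixels sampled from the same patches
  set.seed(3)
  X <- do.call(rbind, lapply(patches, function(p) {
    f <- pixel_features(p$pixels, cfg$scales)
    matrix(f, ncol = dim(f)[3])
  }))
  y <- unlist(lapply(patches, function(p) as.vector(p$labels)))
  sel <- c(sample(which(y == 1), 2000), sample(which(y == 0), 2000))
  net <- nnet::nnet(scale(X[sel, ]), y[sel], size = 8, decay = 1e-4,
                    maxit = 200, trace = FALSE)
  ho <- mixed_training_sims(61, n = 1)[[1]]
  fho <- pixel_features(ho$micrograph$pixels, cfg$scales)
  Xho <- matrix(fho, ncol = dim(fho)[3])
  pred_net <- matrix(predict(net, scale(Xho, attr(scale(X[sel, ]), "scaled:center"),
                                        attr(scale(X[sel, ]), "scaled:scale"))) > 0.5,
                     nrow(fho), ncol(fho))
  truth <- ho$truth$class_masks$EV_bilayer > 0
  pred_mlp <- predict_mask(mod, ho$micrograph)$binary > 0
  acc_net <- mean(pred_net == truth)
  acc_mlp <- mean(pred_mlp == truth)
  expect_gte(acc_net, 0.9)
  expect_gte(acc_mlp, 0.9)
  expect_gte(mean(pred_net == pred_mlp), 0.9)
})

test_that("prediction is seamless under tiling and guards the preprocessing signature", {
  tb <- train_bilayer_model(seed = 21, n = 4)
  sim <- mixed_training_sims(71, n = 1)[[1]]
  whole <- predict_mask(tb$model, sim$micrograph)
  tiled <- predict_mask(tb$model, sim$micrograph, tile_size = 96, halo = 24)
  ## tile seams (at rows/cols 96 and 192) must be invisible; the outermost
  ## image band is excluded because periodic boundary context genuinely
  ## differs there between whole-image and per-tile filtering
  core <- 17:240
  expect_lt(max(abs(whole$probability[core, core] -
                    tiled$probability[core, core])), 0.05)
  expect_error(predict_mask(tb$model, sim$micrograph,
                            preprocess_signature = "bandpass50-2"),
               "signature mismatch")
})

test_that("pixel models serialize to JSON and round-trip predictions exactly", {
  tb <- train_bilayer_model(seed = 21, n = 3)
  path <- tempfile(fileext = ".json")
  write_pixel_model(tb$model, path)
  back <- read_pixel_model(path)
  sim <- mixed_training_sims(81, n = 1)[[1]]
  expect_equal(predict_mask(back, sim$micrograph)$probability,
               predict_mask(tb$model, sim$micrograph)$probability,
               tolerance = 1e-12)
  expect_identical(back$class_name, "EV_bilayer")
})

test_that("bilayer model segments vesicle rings but not dense particles or blanks", {
  tb <- train_bilayer_model(seed = 21)
  ## blank field: far below 1% positive pixels
  blank <- simulate_micrograph(blank_scene(seed = 5))
  expect_lt(mean(predict_mask(tb$model, blank$micrograph)$binary), 0.01)
  ## VLDL-only field: not detected (Figure-3B-style specificity)
  vf <- simulate_micrograph(one_class_scene("VLDL", 40, seed = 6))
  expect_lt(mean(despeckle(predict_mask(tb$model, vf$micrograph))$binary), 0.01)
  ## vesicle field: >= 80% of particles have ring Jaccard >= 0.5
  ev <- simulate_micrograph(one_class_scene("EV_bilayer", 25, seed = 7,
                                            depth = 40))
  pm <- predict_mask(tb$model, ev$micrograph)
  tr <- ev$truth
  ok <- tr$particles[!tr$particles$border_truncated, ]
  jac <- vapply(ok$id, function(i) {
    foot <- tr$instance_map == i
    ys <- range(which(rowSums(foot) > 0)); xs <- range(which(colSums(foot) > 0))
    jaccard(foot[ys[1]:ys[2], xs[1]:xs[2]],
            pm$binary[ys[1]:ys[2], xs[1]:xs[2]])
  }, 1)
  expect_gte(mean(jac >= 0.5), 0.8)
})

test_that("classical ring detector recovers rings deterministically", {
  ## single vesicle: detector mask covers >= 80% of the true ring footprint
  sp <- small_scene(list(class_spec("EV_bilayer", density = 15, depth = 40)),
                    seed = 19, shape = c(192, 192), placement = "interior")
  sim <- simulate_micrograph(sp)
  expect_gt(nrow(sim$truth$particles), 0)
  det <- classical_bilayer_detector(sim$micrograph, radii_px = 3:25)
  foot <- sim$truth$instance_map > 0
  expect_gte(sum(det$binary & foot) / sum(foot), 0.8)

  ## blank image: (near-)empty mask
  blank <- simulate_micrograph(blank_scene(seed = 23, shape = c(192, 192)))
  expect_lt(mean(classical_bilayer_detector(blank$micrograph,
                                            radii_px = 3:25)$binary), 0.005)

  ## two synthetic rings at radii 20 and 40 px both recovered
  m <- matrix(150, 256, 256)
  for (geom in list(c(70, 70, 20), c(170, 170, 40))) {
    d2 <- sqrt(outer((1:256 - geom[1])^2, (1:256 - geom[2])^2, `+`))
    m <- m - 40 * exp(-(d2 - geom[3])^2 / 2)
  }
  set.seed(1); m <- m + rnorm(length(m), 0, 1.2)
  det2 <- classical_bilayer_detector(micrograph(m, 2.2), radii_px = 10:50)
  for (geom in list(c(70, 70, 20), c(170, 170, 40))) {
    d2 <- sqrt(outer((1:256 - geom[1])^2, (1:256 - geom[2])^2, `+`))
    ring <- abs(d2 - geom[3]) <= 1.5
    expect_gte(sum(det2$binary & ring) / sum(ring), 0.7)
  }

  expect_error(classical_bilayer_detector(sim$micrograph, radii_px = integer(0)),
               "empty")
  ## determinism
  expect_identical(det$binary,
                   classical_bilayer_detector(sim$micrograph, radii_px = 3:25)$binary)
})
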