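## Supervised per-pixel segmentation. One independent binary model per
## structure class (bilayer, small_dense, HDL, LDL, VLDL, ice), trained from
## ROI-box annotations and applied to whole micrographs; overlapping
## predictions from different class models are permitted and resolved
## downstream. The classifier is a seeded one-hidden-layer MLP over a
## multi-scale rotation-invariant convolutional filter bank (intensity,
## Gaussian means, difference-of-Gaussians, gradient magnitude, local SD) --
## the pixel-classification idiom of ilastik/Weka-style tools. Bandpass
## preprocessing is applied before lipoprotein/ice models but not before the
## bilayer model (which is trained on unfiltered data); the preprocessing
## signature travels with the model and is checked at prediction time.
##
## A deterministic classical baseline, a ring-matched filter over a radius
## sweep, is provided so downstream sizing can be exercised without
## stochastic training.

#' Annotation set: ROI boxes with per-pixel labels
#'
#' @param items list; each element a list with `image_id`, `box`
#'   (`c(y0, x0, height, width)`, 1-based top-left corner), `labels`
#'   (binary matrix of dim `height x width`), `class_name`.
#' @return an `annotation_set`.
#' @export
annotation_set <- function(items) {
  if (length(items) == 0L) stop("empty annotation set")
  for (it in items) {
    stopifnot(!is.null(it$image_id), length(it$box) == 4L,
              is.matrix(it$labels))
    if (!all(dim(it$labels) == it$box[3:4]))
      stop("label mask must be box-shaped")
    assert_binary(it$labels, "label mask")
    if (!it$class_name %in% PARTICLE_CLASSES)
      stop("unknown class: ", it$class_name)
  }
  structure(list(items = items), class = "annotation_set")
}

#' Training-set provenance statistics
#'
#' The reportable arithmetic of an annotation campaign: number of ROIs,
#' annotated area as a fraction of the total image area, and per-class
#' positive pixel counts.
#'
#' @param ann an [annotation_set()].
#' @param images named list of micrographs (or matrices) the boxes refer to.
#' @return list with `n_rois`, `roi_area_px`, `total_area_px`,
#'   `fraction_of_total_area`, `positive_px` (named by class).
#' @export
annotation_stats <- function(ann, images) {
  roi_area <- sum(vapply(ann$items, function(it) prod(it$box[3:4]), 1))
  total <- sum(vapply(images, function(im)
    prod(dim(if (is_micrograph(im)) im$pixels else im)), 1))
  cls <- vapply(ann$items, function(it) it$class_name, "")
  pos <- tapply(vapply(ann$items, function(it) sum(it$labels > 0), 1), cls, sum)
  list(n_rois = length(ann$items), roi_area_px = roi_area,
       total_area_px = total, fraction_of_total_area = roi_area / total,
       positive_px = as.list(pos))
}

#' Build annotations from simulator ground truth
#'
#' Turns a simulated dataset's class masks into ROI-box annotations: one box
#' per (non-truncated) particle of the class, plus background boxes, so the
#' training-set machinery can be exercised with known provenance.
#'
#' @param sims list of [simulate_micrograph()] results.
#' @param class_name structure class to annotate.
#' @param box_margin_px margin added around each particle's footprint.
#' @param n_background background-only boxes per image.
#' @param background_box_px side of background boxes.
#' @param seed RNG seed for background-box placement.
#' @return list with `annotations` (an [annotation_set()]) and `images`
#'   (named list of pixel matrices).
#' @export
annotations_from_truth <- function(sims, class_name, box_margin_px = 6L,
                                   n_background = 2L, background_box_px = 48L,
                                   seed = 1L) {
  items <- list(); images <- list()
  withr::with_seed(seed, {
    for (i in seq_along(sims)) {
      id <- sprintf("img%03d", i)
      img <- sims[[i]]$micrograph$pixels
      images[[id]] <- img
      tr <- sims[[i]]$truth
      mask <- tr$class_masks[[class_name]]
      if (is.null(mask)) mask <- matrix(0L, nrow(img), ncol(img))
      pp <- tr$particles
      pp <- pp[pp$class_name == class_name & !pp$border_truncated, , drop = FALSE]
      for (k in seq_len(nrow(pp))) {
        e <- ceiling(pp$radius_px[k]) + box_margin_px
        y0 <- max(1L, floor(pp$cy[k] - e)); x0 <- max(1L, floor(pp$cx[k] - e))
        y1 <- min(nrow(img), ceiling(pp$cy[k] + e))
        x1 <- min(ncol(img), ceiling(pp$cx[k] + e))
        items[[length(items) + 1L]] <- list(
          image_id = id, box = c(y0, x0, y1 - y0 + 1L, x1 - x0 + 1L),
          labels = mask[y0:y1, x0:x1, drop = FALSE], class_name = class_name)
      }
      for (k in seq_len(n_background)) {
        b <- background_box_px
        if (nrow(img) <= b || ncol(img) <= b) next
        for (try in 1:50) {
          y0 <- sample.int(nrow(img) - b, 1L); x0 <- sample.int(ncol(img) - b, 1L)
          box <- mask[y0:(y0 + b - 1L), x0:(x0 + b - 1L)]
          if (sum(box) == 0) break
        }
        items[[length(items) + 1L]] <- list(
          image_id = id, box = c(y0, x0, b, b),
          labels = box, class_name = class_name)
      }
    }
  })
  list(annotations = annotation_set(items), images = images)
}

#' Pixel-model configuration
#'
#' @param class_name structure class the model is trained for.
#' @param patch_size training-patch tiling size, pixels.
#' @param scales Gaussian scales of the filter bank, pixels.
#' @param hidden hidden-layer width of the MLP.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param max_pixels pixels sampled (class-balanced) from the training set.
#' @param augment add dihedral flipped/rotated copies of the patches. The
#'   filter bank is rotation-invariant, so this mainly reweights sampling;
#'   off by default.
#' @param threshold default binarization threshold.
#' @param preprocess_signature string recording how training images were
#'   preprocessed (e.g. `"raw"`, `"bandpass50-2"`); checked at prediction.
#' @param seed RNG seed pinning initialization and sampling.
#' @return a `model_config` list.
#' @export
model_config <- function(class_name, patch_size = 64L, scales = c(1, 2, 4),
                         hidden = 8L, learning_rate = 0.05, epochs = 20L,
                         batch_size = 256L, max_pixels = 20000L,
                         augment = FALSE, threshold = 0.5,
                         preprocess_signature = "raw", seed = 1L) {
  class_name <- match.arg(class_name, PARTICLE_CLASSES)
  if (patch_size < 4 * max(scales))
    stop("patch_size incompatible with filter-bank scales (need >= 4 * max scale)")
  structure(list(class_name = class_name, patch_size = as.integer(patch_size),
                 scales = scales, hidden = as.integer(hidden),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 max_pixels = as.integer(max_pixels), augment = augment,
                 threshold = threshold,
                 preprocess_signature = preprocess_signature,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Multi-scale filter-bank features for per-pixel classification
#'
#' Rotation-invariant features per pixel: mean-centred intensity, Gaussian
#' means at each scale, difference-of-Gaussians between consecutive scales,
#' gradient magnitude at the two smallest scales, and local SD at the middle
#' scale. Convolutions are FFT-based with periodic boundary. Intensities are
#' centred but deliberately not variance-scaled per image: the absolute
#' contrast of a structure against the background is the discriminative
#' signal, so images must share one intensity calibration between training
#' and prediction (the pipeline's normalization stage provides it).
#' Feature standardization itself is learned from the training set and
#' stored in the model.
#'
#' @param pixels numeric matrix.
#' @param scales Gaussian sigmas, pixels.
#' @param center intensity offset subtracted before filtering; defaults to
#'   the mean of `pixels`. Tiled prediction passes the whole-image mean so
#'   tiles are centred consistently.
#' @return array `H x W x n_features`.
#' @export
pixel_features <- function(pixels, scales = c(1, 2, 4), center = mean(pixels)) {
  x <- pixels - center
  H <- nrow(x); W <- ncol(x)
  g <- lapply(scales, function(s) fft_gaussian_blur(x, s))
  feats <- c(list(x), g)
  for (i in seq_len(length(scales) - 1L))
    feats <- c(feats, list(g[[i]] - g[[i + 1L]]))
  for (i in seq_len(min(2L, length(scales)))) {
    gy <- (rbind(g[[i]][-1, , drop = FALSE], g[[i]][H, , drop = FALSE]) -
           rbind(g[[i]][1, , drop = FALSE], g[[i]][-H, , drop = FALSE])) / 2
    gx <- (cbind(g[[i]][, -1, drop = FALSE], g[[i]][, W, drop = FALSE]) -
           cbind(g[[i]][, 1, drop = FALSE], g[[i]][, -W, drop = FALSE])) / 2
    feats <- c(feats, list(sqrt(gy^2 + gx^2)))
  }
  s_mid <- scales[ceiling(length(scales) / 2)]
  m2 <- fft_gaussian_blur(x^2, s_mid)
  m1 <- fft_gaussian_blur(x, s_mid)
  feats <- c(feats, list(sqrt(pmax(m2 - m1^2, 0))))
  array(unlist(feats), dim = c(H, W, length(feats)))
}

#' Extract training patches from annotated ROI boxes
#'
#' Each ROI yields one patch if it is no larger than `patch_size`, otherwise
#' it is tiled into non-overlapping `patch_size` tiles (remainders cropped).
#' Per-class pixel counts are attached as attributes.
#'
#' @param ann an [annotation_set()].
#' @param images named list of (preprocessed) micrographs or matrices,
#'   indexed by the annotations' `image_id`s. Preprocessing must match what
#'   will be applied at prediction time.
#' @param cfg a [model_config()]; only its `class_name` and `patch_size`
#'   are used here.
#' @return list of patches, each `list(pixels, labels, image_id)`, with
#'   attributes `positive_px`, `total_px`, `positive_fraction`.
#' @export
extract_training_patches <- function(ann, images, cfg) {
  stopifnot(inherits(ann, "annotation_set"), inherits(cfg, "model_config"))
  patches <- list()
  for (it in ann$items) {
    if (it$class_name != cfg$class_name)
      stop(sprintf("annotation class '%s' does not match model class '%s'",
                   it$class_name, cfg$class_name))
    im <- images[[it$image_id]]
    if (is.null(im)) stop("annotation references unavailable image: ", it$image_id)
    px <- if (is_micrograph(im)) im$pixels else im
    y0 <- it$box[1]; x0 <- it$box[2]; h <- it$box[3]; w <- it$box[4]
    if (y0 < 1 || x0 < 1 || y0 + h - 1 > nrow(px) || x0 + w - 1 > ncol(px))
      stop("ROI box outside its image")
    ps <- cfg$patch_size
    ty <- if (h <= ps) 1L else h %/% ps
    tx <- if (w <= ps) 1L else w %/% ps
    hh <- if (h <= ps) h else ps
    ww <- if (w <= ps) w else ps
    for (iy in seq_len(ty)) for (ix in seq_len(tx)) {
      yy <- y0 + (iy - 1L) * hh; xx <- x0 + (ix - 1L) * ww
      patches[[length(patches) + 1L]] <- list(
        pixels = px[yy:(yy + hh - 1L), xx:(xx + ww - 1L), drop = FALSE],
        labels = (it$labels[(1:hh) + (iy - 1L) * hh,
                            (1:ww) + (ix - 1L) * ww, drop = FALSE] > 0) * 1L,
        image_id = it$image_id)
    }
  }
  pos <- sum(vapply(patches, function(p) sum(p$labels), 1))
  tot <- sum(vapply(patches, function(p) length(p$labels), 1))
  attr(patches, "positive_px") <- pos
  attr(patches, "total_px") <- tot
  attr(patches, "positive_fraction") <- pos / tot
  patches
}

flip_patch <- function(p, k) {
  ops <- list(identity, function(m) m[nrow(m):1, , drop = FALSE],
              function(m) m[, ncol(m):1, drop = FALSE],
              function(m) m[nrow(m):1, ncol(m):1, drop = FALSE])
  list(pixels = ops[[k]](p$pixels), labels = ops[[k]](p$labels),
       image_id = p$image_id)
}

mlp_forward <- function(X, w) {
  h <- tanh(sweep(X %*% w$w1, 2, w$b1, `+`))
  stats::plogis(drop(h %*% w$w2) + w$b2)
}

#' Train a per-pixel classification model
#'
#' Computes filter-bank features per patch, samples a class-balanced pixel
#' set, and trains a one-hidden-layer MLP with minibatch Adam on binary
#' cross-entropy. Fully seeded and repeatable; the per-epoch loss is
#' recorded in the training log, and a non-finite loss raises an error
#' naming the epoch.
#'
#' @param patches output of [extract_training_patches()] (or any list of
#'   `list(pixels, labels)` patches).
#' @param cfg a [model_config()].
#' @return a `pixel_model`: weights, feature standardization, class name,
#'   preprocessing signature, `log` (data frame `epoch`, `loss`).
#' @export
train_pixel_model <- function(patches, cfg) {
  stopifnot(inherits(cfg, "model_config"))
  if (length(patches) == 0L) stop("empty training set")
  if (isTRUE(cfg$augment))
    patches <- unlist(lapply(patches, function(p)
      lapply(1:4, flip_patch, p = p)), recursive = FALSE)
  Xl <- list(); yl <- list()
  for (p in patches) {
    f <- pixel_features(p$pixels, cfg$scales)
    Xl[[length(Xl) + 1L]] <- matrix(f, ncol = dim(f)[3])
    yl[[length(yl) + 1L]] <- as.vector(p$labels)
  }
  X <- do.call(rbind, Xl); y <- unlist(yl)
  if (sum(y == 1) == 0L) stop("training set has no positive pixels")
  if (sum(y == 0) == 0L) stop("training set has no negative pixels")
  withr::with_seed(cfg$seed, {
    ## class-balanced subsample
    n_half <- cfg$max_pixels %/% 2L
    ip <- which(y == 1); im <- which(y == 0)
    ip <- if (length(ip) > n_half) sample(ip, n_half) else ip
    im <- if (length(im) > n_half) sample(im, n_half) else im
    sel <- sample(c(ip, im))
    X <- X[sel, , drop = FALSE]; y <- y[sel]
    mu <- colMeans(X); sg <- pmax(apply(X, 2, sd), 1e-9)
    X <- sweep(sweep(X, 2, mu), 2, sg, `/`)
    nf <- ncol(X); nh <- cfg$hidden; n <- nrow(X)
    w <- list(w1 = matrix(runif(nf * nh, -0.5, 0.5) / sqrt(nf), nf, nh),
              b1 = numeric(nh),
              w2 = runif(nh, -0.5, 0.5) / sqrt(nh), b2 = 0)
    adam <- lapply(w, function(p) list(m = p * 0, v = p * 0))
    b1 <- 0.9; b2m <- 0.999; eps <- 1e-8; t <- 0
    log_loss <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      nb <- max(1L, n %/% cfg$batch_size)
      for (bi in seq_len(nb)) {
        ix <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
        Xb <- X[ix, , drop = FALSE]; yb <- y[ix]
        hpre <- sweep(Xb %*% w$w1, 2, w$b1, `+`)
        h <- tanh(hpre)
        p_hat <- stats::plogis(drop(h %*% w$w2) + w$b2)
        d_out <- (p_hat - yb) / length(yb)
        g <- list(w2 = drop(crossprod(h, d_out)), b2 = sum(d_out))
        dh <- outer(d_out, w$w2) * (1 - h^2)
        g$w1 <- crossprod(Xb, dh); g$b1 <- colSums(dh)
        t <- t + 1
        for (nm in names(w)) {
          adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * g[[nm]]
          adam[[nm]]$v <- b2m * adam[[nm]]$v + (1 - b2m) * g[[nm]]^2
          w[[nm]] <- w[[nm]] - cfg$learning_rate *
            (adam[[nm]]$m / (1 - b1^t)) /
            (sqrt(adam[[nm]]$v / (1 - b2m^t)) + eps)
        }
      }
      p_all <- mlp_forward(X, w)
      p_all <- clamp(p_all, 1e-12, 1 - 1e-12)
      log_loss[epoch] <- -mean(y * log(p_all) + (1 - y) * log(1 - p_all))
      if (!is.finite(log_loss[epoch]))
        stop(sprintf("training diverged: non-finite loss at epoch %d", epoch))
    }
  })
  structure(list(class_name = cfg$class_name, weights = w,
                 feat_mean = mu, feat_sd = sg, scales = cfg$scales,
                 threshold = cfg$threshold,
                 preprocess_signature = cfg$preprocess_signature,
                 config = cfg,
                 log = data.frame(epoch = seq_len(cfg$epochs), loss = log_loss)),
            class = "pixel_model")
}

#' @export
print.pixel_model <- function(x, ...) {
  cat(sprintf("<pixel_model> class '%s', %d features, hidden %d, final loss %.4f (%d epochs)\n",
              x$class_name, length(x$feat_mean), length(x$weights$b1),
              utils::tail(x$log$loss, 1), nrow(x$log)))
  invisible(x)
}

#' Write / read a pixel model as JSON
#'
#' The model artifact is plain JSON: weights, feature standardization, class
#' and preprocessing signature, plus the training configuration as a sidecar
#' block.
#'
#' @param model a `pixel_model`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_pixel_model <- function(model, path) {
  obj <- model
  obj$weights$w1 <- as.vector(obj$weights$w1)
  obj$dims <- c(length(obj$feat_mean), length(obj$weights$b1))
  obj$config <- unclass(obj$config)
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pixel_model
#' @export
read_pixel_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$weights$w1 <- matrix(obj$weights$w1, obj$dims[1], obj$dims[2])
  obj$log <- as.data.frame(obj$log)
  obj$config <- structure(as.list(obj$config), class = "model_config")
  obj$dims <- NULL
  structure(obj, class = "pixel_model")
}

forward_features <- function(model, f) {
  X <- matrix(f, ncol = dim(f)[3])
  X <- sweep(sweep(X, 2, model$feat_mean), 2, model$feat_sd, `/`)
  matrix(mlp_forward(X, model$weights), dim(f)[1], dim(f)[2])
}

#' Predict a segmentation mask on a micrograph
#'
#' Applies the model's filter bank and MLP to every pixel. Large images can
#' be processed in tiles with a feature halo: each tile is cut with `halo`
#' pixels of context, features are computed on the padded tile and the
#' centre is kept, so tile boundaries introduce no visible probability
#' discontinuity.
#'
#' @param model a `pixel_model` from [train_pixel_model()].
#' @param m a [micrograph()] or matrix, preprocessed as at training time.
#' @param threshold binarization threshold (default: the model's).
#' @param tile_size side of processing tiles, or `NULL` for whole-image.
#' @param halo context margin around tiles, pixels.
#' @param preprocess_signature if given, must equal the model's signature
#'   (guards against filtered/unfiltered mix-ups).
#' @return a [segmentation_mask()].
#' @export
predict_mask <- function(model, m, threshold = NULL, tile_size = NULL,
                         halo = 16L, preprocess_signature = NULL) {
  stopifnot(inherits(model, "pixel_model"))
  if (!is.null(preprocess_signature) &&
      !identical(preprocess_signature, model$preprocess_signature))
    stop(sprintf("preprocessing signature mismatch: model '%s', requested '%s'",
                 model$preprocess_signature, preprocess_signature))
  px <- if (is_micrograph(m)) m$pixels else m
  threshold <- threshold %||% model$threshold
  H <- nrow(px); W <- ncol(px)
  if (is.null(tile_size) || tile_size >= max(H, W)) {
    prob <- forward_features(model, pixel_features(px, model$scales))
  } else {
    prob <- matrix(0, H, W)
    ts <- as.integer(tile_size)
    mu <- mean(px)
    for (y0 in seq(1L, H, by = ts)) for (x0 in seq(1L, W, by = ts)) {
      y1 <- min(H, y0 + ts - 1L); x1 <- min(W, x0 + ts - 1L)
      yy <- max(1L, y0 - halo):min(H, y1 + halo)
      xx <- max(1L, x0 - halo):min(W, x1 + halo)
      p <- forward_features(model, pixel_features(px[yy, xx, drop = FALSE],
                                                  model$scales, center = mu))
      prob[y0:y1, x0:x1] <- p[(y0 - yy[1] + 1L):(y1 - yy[1] + 1L),
                              (x0 - xx[1] + 1L):(x1 - xx[1] + 1L)]
    }
  }
  segmentation_mask(model$class_name, clamp(prob, 0, 1), threshold)
}

template_cache <- new.env(parent = emptyenv())

#' Deterministic classical bilayer-ring detector
#'
#' A ring-matched filter: the image (high-pass filtered against the smooth
#' background) is correlated with zero-mean, unit-norm double-leaflet ring
#' templates over a radius sweep; peaks above an SNR threshold are kept
#' after the same non-maximum suppression rule as the Hough stage, and for
#' every accepted peak the annulus around its radius is intersected with the
#' dark-pixel set to form the bilayer mask — so partial rings yield partial
#' arcs. Entirely deterministic, providing a baseline independent of
#' stochastic training.
#'
#' @param m a [micrograph()].
#' @param radii_px radius sweep, pixels; error if empty.
#' @param snr_threshold matched-filter peak threshold, in units of the
#'   image's robust noise SD.
#' @param leaflet_separation,leaflet_sigma bilayer template geometry, nm.
#' @param dark_k a pixel belongs to the ring footprint when it is darker
#'   than `-dark_k * noise SD` after background removal.
#' @param annulus_halfwidth_nm half-width of the painted annulus, nm.
#' @param lumen_k shell-contrast acceptance: the mean intensity on the
#'   annulus must be at least `lumen_k * noise SD` darker than the mean of
#'   both the inner shell (towards the lumen) and the outer shell. A
#'   bilayer is a thin dark *line* with background-level intensity on both
#'   sides; a filled dense disc (VLDL and the like) is dark on one side of
#'   its edge and fails the test. This is what makes the detector
#'   bilayer-specific. (Known limitation: tightly nested multilamellar
#'   rings can suppress each other's shells.)
#' @return a [segmentation_mask()] for class `EV_bilayer`.
#' @export
classical_bilayer_detector <- function(m, radii_px = 6:40, snr_threshold = 6,
                                       leaflet_separation = 4,
                                       leaflet_sigma = 1,
                                       dark_k = 2.5,
                                       annulus_halfwidth_nm = 4,
                                       lumen_k = 2) {
  stopifnot(is_micrograph(m))
  if (length(radii_px) == 0L) stop("radius sweep is empty")
  x <- m$pixels
  H <- nrow(x); W <- ncol(x)
  ## remove smooth background (ice-thickness gradient + mean)
  bg <- fft_gaussian_blur(x, max(radii_px))
  xs <- x - bg
  sdn <- mad(xs)
  ## ring-template FFTs depend only on geometry; cache across calls so
  ## per-image cost is one forward FFT plus one inverse per radius
  key <- paste(H, W, signif(m$pixel_size, 8), leaflet_separation,
               leaflet_sigma, paste(radii_px, collapse = ","), sep = "|")
  tf <- template_cache[[key]]
  if (is.null(tf)) {
    cs <- class_spec("EV_bilayer", leaflet_separation = leaflet_separation,
                     leaflet_sigma = leaflet_sigma, depth = 1)
    ## wrapped distance-from-origin grid for corner-centred templates
    dy <- pmin(0:(H - 1), H - (0:(H - 1)))
    dx <- pmin(0:(W - 1), W - (0:(W - 1)))
    rho_nm <- sqrt(outer(dy^2, dx^2, `+`)) * m$pixel_size
    tf <- lapply(radii_px, function(r) {
      att <- radial_attenuation(cs, rho_nm, 2 * r * m$pixel_size)
      tmpl <- -(att - mean(att))
      fft(tmpl / sqrt(sum(tmpl^2)))
    })
    template_cache[[key]] <- tf
  }
  ## best response over the radius sweep, per pixel
  Fx <- fft(xs)
  best <- matrix(-Inf, H, W); best_r <- matrix(radii_px[1], H, W)
  for (j in seq_along(radii_px)) {
    resp <- Re(fft(Fx * Conj(tf[[j]]), inverse = TRUE)) / (length(xs) * sdn)
    upd <- resp > best
    best[upd] <- resp[upd]; best_r[upd] <- radii_px[j]
  }
  ## candidate centres: 3x3 local maxima of the collapsed response
  is_max <- best >= snr_threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    sh <- matrix(-Inf, H, W)
    ys <- max(1, 1 + dy):min(H, H + dy); xs2 <- max(1, 1 + dx):min(W, W + dx)
    sh[ys, xs2] <- best[ys - dy, xs2 - dx]
    is_max <- is_max & (best >= sh)
  }
  cand <- which(is_max, arr.ind = TRUE)
  mask <- matrix(0L, H, W)
  if (nrow(cand)) {
    sc <- best[cand]; r <- best_r[cand]
    ord <- order(-sc, r, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]; r <- r[ord]
    keep <- integer(0)
    for (i in seq_along(sc)) {
      ok <- TRUE
      for (k in keep) {
        d <- sqrt((cand[i, 1] - cand[k, 1])^2 + (cand[i, 2] - cand[k, 2])^2)
        rmax <- max(r[i], r[k])
        if (d < rmax / 2 && abs(r[i] - r[k]) / rmax < 0.25) { ok <- FALSE; break }
      }
      if (ok) keep <- c(keep, i)
    }
    dark <- xs < -dark_k * sdn
    w_px <- max(1.5, annulus_halfwidth_nm / m$pixel_size)
    for (i in keep) {
      cy <- cand[i, 1]; cx <- cand[i, 2]; rr <- r[i]
      e <- ceiling(rr + 3 * w_px)
      ys <- max(1L, cy - e):min(H, cy + e)
      xxs <- max(1L, cx - e):min(W, cx + e)
      rho <- sqrt(outer((ys - cy)^2, (xxs - cx)^2, `+`))
      ann <- abs(rho - rr) <= w_px
      inner <- rho < rr - w_px & rho >= max(0, rr - 3 * w_px)
      outer_sh <- rho > rr + w_px & rho <= rr + 3 * w_px
      patch <- xs[ys, xxs]
      ann_mean <- mean(patch[ann])
      if (sum(inner) >= 4 && ann_mean > mean(patch[inner]) - lumen_k * sdn)
        next
      if (sum(outer_sh) >= 4 && ann_mean > mean(patch[outer_sh]) - lumen_k * sdn)
        next
      sub <- mask[ys, xxs]
      sub[ann & dark[ys, xxs]] <- 1L
      mask[ys, xxs] <- sub
    }
  }
  segmentation_mask("EV_bilayer", mask, 0.5)
}
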