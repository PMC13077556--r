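## Scene and drawing helpers shared across tests. All fixtures are generated
## in code; nothing is read from disk.

jaccard <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

## small scene at the binned working pixel size (2.2 nm) to keep tests fast
small_scene <- function(classes, seed, shape = c(256, 256), pixel_size = 2.2,
                        rim = FALSE, ...) {
  scene_spec(shape, pixel_size, classes,
             hole_rim = list(present = rim, diameter = 2000),
             seed = seed, ...)
}

one_class_scene <- function(class_name, density, seed, depth = 35, ...)
  small_scene(list(class_spec(class_name, density = density, depth = depth)),
              seed = seed, ...)

blank_scene <- function(seed, ...) small_scene(list(), seed = seed, ...)

## draw rasterized rings/arcs into a binary matrix (package rasterization,
## so a complete ring scores exactly 1 by construction)
draw_ring <- function(mask, cy, cx, r, arc = 1, theta0 = 0) {
  pts <- circle_offsets(r, arc, theta0)
  yy <- cy + pts[, 1L]; xx <- cx + pts[, 2L]
  ok <- yy >= 1 & yy <= nrow(mask) & xx >= 1 & xx <= ncol(mask)
  mask[cbind(yy[ok], xx[ok])] <- 1L
  mask
}

## filled disc mask
draw_disc <- function(mask, cy, cx, r) {
  ys <- max(1, cy - r):min(nrow(mask), cy + r)
  xs <- max(1, cx - r):min(ncol(mask), cx + r)
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sub <- mask[ys, xs]
  sub[d2 <= r^2] <- 1L
  mask[ys, xs] <- sub
  mask
}

## standard mixed-field training setup for the bilayer pixel model
mixed_training_sims <- function(seed, n = 8, shape = c(256, 256)) {
  simulate_dataset(
    small_scene(list(class_spec("EV_bilayer", density = 20, depth = 40),
                     class_spec("VLDL", density = 15, depth = 35),
                     class_spec("small_dense", density = 10, depth = 35)),
                seed = seed, shape = shape),
    n, seed)
}

train_bilayer_model <- function(seed = 21, epochs = 20L, n = 8) {
  sims <- mixed_training_sims(seed, n = n)
  ann <- annotations_from_truth(sims, "EV_bilayer", seed = seed + 1L)
  cfg <- model_config("EV_bilayer", epochs = epochs, seed = seed + 2L)
  list(model = train_pixel_model(
         extract_training_patches(ann$annotations, ann$images, cfg), cfg),
       cfg = cfg, ann = ann)
}
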