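## Synthetic micrograph simulator.
##
## Emulates the appearance of defocused bright-field cryo-EM fields of
## extracellular vesicles and co-isolated particles: dark double-leaflet
## bilayer rings (leaflets ~4 nm apart), filled dense discs (HDL, LDL, VLDL,
## exomere-like "small dense" particles), irregular high-contrast surface-ice
## blobs, the dark rim of the carbon-foil hole, a smooth ice-thickness
## background gradient, and dose-dependent shot noise (Gaussian approximation,
## variance proportional to 1/dose). Particles are darker than the background.
## No electron-optical CTF is modelled: the radial contrast profiles are
## phenomenological stand-ins sufficient to exercise segmentation, Hough
## detection and sizing against known ground truth.

PARTICLE_CLASSES <- c("EV_bilayer", "small_dense", "HDL", "LDL", "VLDL", "ice")

#' Specification of one particle class in a synthetic scene
#'
#' @param class_name one of `"EV_bilayer"`, `"small_dense"`, `"HDL"`,
#'   `"LDL"`, `"VLDL"`, `"ice"`.
#' @param diameter named list describing the diameter distribution (nm):
#'   `list(dist = "lognormal", median =, sdlog =)`,
#'   `list(dist = "normal", mean =, sd =)` (truncated at > 0), or
#'   `list(dist = "uniform", min =, max =)`. Defaults are per-class:
#'   EV bilayers lognormal(median 60, sdlog 0.3); small dense particles
#'   normal(45, 4.5); HDL uniform(7, 12); LDL uniform(18, 25); VLDL
#'   uniform(30, 70); ice uniform(40, 150).
#' @param density particles per square micrometre (>= 0).
#' @param depth contrast depth: attenuation below background, grey levels.
#' @param leaflet_separation bilayer leaflet separation (nm), EV class only.
#' @param leaflet_sigma Gaussian half-width of one leaflet dip (nm).
#' @param edge_width logistic edge softness of dense discs (nm).
#' @return a `class_spec` list.
#' @export
class_spec <- function(class_name, diameter = NULL, density = 0, depth = 40,
                       leaflet_separation = 4, leaflet_sigma = 1,
                       edge_width = 1) {
  class_name <- match.arg(class_name, PARTICLE_CLASSES)
  if (density < 0) stop("density must be >= 0")
  diameter <- diameter %||% switch(class_name,
    EV_bilayer  = list(dist = "lognormal", median = 60, sdlog = 0.3),
    small_dense = list(dist = "normal", mean = 45, sd = 4.5),
    HDL         = list(dist = "uniform", min = 7,  max = 12),
    LDL         = list(dist = "uniform", min = 18, max = 25),
    VLDL        = list(dist = "uniform", min = 30, max = 70),
    ice         = list(dist = "uniform", min = 40, max = 150))
  check_diameter_support(diameter)
  structure(list(class_name = class_name, diameter = diameter,
                 density = density, depth = depth,
                 leaflet_separation = leaflet_separation,
                 leaflet_sigma = leaflet_sigma, edge_width = edge_width),
            class = "class_spec")
}

check_diameter_support <- function(d) {
  lo <- switch(d$dist,
    lognormal = 0 + (d$median > 0) - 1e-12,  # support strictly positive
    normal = d$mean - 6 * d$sd,
    uniform = d$min,
    stop("unknown diameter distribution: ", d$dist))
  if (d$dist == "uniform" && (d$min <= 0 || d$max <= d$min))
    stop("uniform diameter distribution needs 0 < min < max")
  if (d$dist == "lognormal" && (d$median <= 0 || d$sdlog < 0))
    stop("lognormal diameter distribution needs median > 0, sdlog >= 0")
  if (d$dist == "normal" && d$mean <= 0)
    stop("normal diameter distribution needs mean > 0")
  invisible(TRUE)
}

sample_diameters <- function(d, n) {
  if (n == 0) return(numeric(0))
  x <- switch(d$dist,
    lognormal = rlnorm(n, meanlog = log(d$median), sdlog = d$sdlog),
    normal = {
      v <- rnorm(n, d$mean, d$sd)
      while (any(v <= 0)) v[v <= 0] <- rnorm(sum(v <= 0), d$mean, d$sd)
      v
    },
    uniform = runif(n, d$min, d$max))
  x
}

#' Specification of a synthetic micrograph scene
#'
#' The defaults reproduce the imaging geometry the pipeline targets: a pixel
#' size of 0.55 nm at the specimen level and a total dose of ~32 e/A^2, with
#' a 2 um carbon-foil hole whose rim may clip the field of view.
#'
#' @param image_shape integer (height, width) in pixels, each >= 64.
#' @param pixel_size nm/pixel (> 0).
#' @param classes list of [class_spec()]s.
#' @param background_gradient_amplitude peak amplitude of the smooth
#'   ice-thickness background modulation, as a fraction of the background
#'   level.
#' @param noise list `dose` (e/A^2) and `gain`; Gaussian shot-noise SD is
#'   `gain * background_level / sqrt(dose * pixel_area_A2)` so variance
#'   scales as 1/dose.
#' @param hole_rim list `present` flag and `diameter` (nm) of the carbon
#'   hole whose dark rim arc is rendered where it crosses the field.
#' @param background_level mean background grey level.
#' @param arc_completeness `NULL` for complete vesicle rings, or a length-2
#'   range, e.g. `c(0.5, 1)`: each EV ring is rendered as a partial arc with
#'   a uniform completeness fraction drawn from the range.
#' @param placement `"free"` places centroids uniformly over the whole field
#'   (particles may be clipped at the border and are then flagged
#'   border-truncated); `"interior"` places each particle wholly inside the
#'   field, emulating the full-hole imaging protocol where edge clipping is
#'   negligible — use it for size-recovery experiments, where border
#'   clipping would otherwise select against large particles.
#' @param seed integer RNG seed; fully determines the scene.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(image_shape = c(512, 512), pixel_size = 0.55,
                       classes = list(class_spec("EV_bilayer", density = 5)),
                       background_gradient_amplitude = 0.05,
                       noise = list(dose = 32, gain = 1),
                       hole_rim = list(present = FALSE, diameter = 2000),
                       background_level = 150,
                       arc_completeness = NULL,
                       placement = c("free", "interior"),
                       seed = 1L) {
  placement <- match.arg(placement)
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 2L || any(image_shape < 64L))
    stop("image_shape must be two integers >= 64")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (!is.list(classes) || !all(vapply(classes, inherits, TRUE, "class_spec")))
    stop("classes must be a list of class_spec objects")
  if (!is.null(arc_completeness) &&
      (length(arc_completeness) != 2L || any(arc_completeness <= 0) ||
       any(arc_completeness > 1)))
    stop("arc_completeness must be NULL or a range within (0, 1]")
  structure(list(image_shape = image_shape, pixel_size = pixel_size,
                 classes = classes,
                 background_gradient_amplitude = background_gradient_amplitude,
                 noise = noise, hole_rim = hole_rim,
                 background_level = background_level,
                 arc_completeness = arc_completeness,
                 placement = placement,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

## continuous radial attenuation (grey levels >= 0) at radius rho_nm
radial_attenuation <- function(cs, rho_nm, diameter_nm) {
  r <- diameter_nm / 2
  if (cs$class_name == "EV_bilayer") {
    s <- cs$leaflet_separation / 2
    sig <- cs$leaflet_sigma
    cs$depth * (exp(-(rho_nm - (r - s))^2 / (2 * sig^2)) +
                exp(-(rho_nm - (r + s))^2 / (2 * sig^2)))
  } else {
    ## filled disc: darkest at centre, logistic edge at rho = r
    cs$depth * stats::plogis((r - rho_nm) / cs$edge_width)
  }
}

#' Radial intensity profile of a particle class
#'
#' Intensity relative to the local background (0 far from the particle,
#' negative inside dark structures), sampled on a fine radial grid. For the
#' bilayer class the profile has two minima whose radial positions differ by
#' the leaflet separation whenever the diameter is large relative to it;
#' when the dips are too close to the centre to resolve, the returned
#' `leaflet_resolved` attribute is `FALSE`.
#'
#' @param class_spec a [class_spec()].
#' @param diameter particle diameter, nm.
#' @param pixel_size nm/pixel (sets the degenerate-size limit and default
#'   sampling step).
#' @param step radial sampling step, nm (default `pixel_size / 4`).
#' @return data frame with columns `r_nm`, `intensity`; attributes
#'   `minima_r_nm` (radial positions of local intensity minima) and, for the
#'   bilayer class, `leaflet_resolved`.
#' @export
render_radial_profile <- function(class_spec, diameter, pixel_size,
                                  step = pixel_size / 4) {
  stopifnot(inherits(class_spec, "class_spec"))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (diameter < 2 * pixel_size)
    stop(sprintf("degenerate particle: diameter %.3g nm < 2 pixels at %.3g nm/pixel",
                 diameter, pixel_size))
  margin <- if (class_spec$class_name == "EV_bilayer")
    class_spec$leaflet_separation / 2 + 4 * class_spec$leaflet_sigma
  else 4 * class_spec$edge_width
  r_nm <- seq(0, diameter / 2 + margin, by = step)
  intensity <- -radial_attenuation(class_spec, r_nm, diameter)
  ## local minima of the sampled profile (strictly below both neighbours)
  n <- length(intensity)
  i <- which(intensity[2:(n - 1)] < intensity[1:(n - 2)] &
             intensity[2:(n - 1)] < intensity[3:n]) + 1L
  minima <- r_nm[i]
  out <- data.frame(r_nm = r_nm, intensity = intensity)
  attr(out, "minima_r_nm") <- minima
  if (class_spec$class_name == "EV_bilayer") {
    sep <- class_spec$leaflet_separation
    ## the separation check is relaxed for tiny vesicles: when the inner
    ## leaflet dip sits within 2 sigma of the centre it interacts with the
    ## profile origin and the two-minima geometry is no longer trustworthy
    attr(out, "leaflet_resolved") <-
      length(minima) == 2L && abs(diff(minima) - sep) < sep * 0.25 &&
      (diameter - sep) / 2 > 2 * class_spec$leaflet_sigma
  }
  out
}

## render one particle into the image; returns modified image and the
## footprint pixel indices (attenuation >= half depth)
render_particle <- function(img, cs, cy, cx, diameter_nm, pixel_size,
                            arc = 1, theta0 = 0) {
  r_px <- (diameter_nm / 2) / pixel_size
  margin_px <- (if (cs$class_name == "EV_bilayer")
    cs$leaflet_separation / 2 + 4 * cs$leaflet_sigma
  else 4 * cs$edge_width) / pixel_size
  e <- ceiling(r_px + margin_px)
  H <- nrow(img); W <- ncol(img)
  ys <- max(1L, floor(cy - e)):min(H, ceiling(cy + e))
  xs <- max(1L, floor(cx - e)):min(W, ceiling(cx + e))
  if (length(ys) == 0L || length(xs) == 0L)
    return(list(img = img, idx = integer(0)))
  dy <- ys - cy; dx <- xs - cx
  rho <- sqrt(outer(dy^2, dx^2, `+`)) * pixel_size
  att <- radial_attenuation(cs, rho, diameter_nm)
  if (arc < 1) {
    th <- atan2(outer(dy, rep(1, length(dx))), outer(rep(1, length(dy)), dx))
    rel <- (th - theta0) %% (2 * pi)
    att[rel > 2 * pi * arc] <- 0
  }
  img[ys, xs] <- img[ys, xs] - att
  foot <- att >= cs$depth / 2
  idx <- which(foot)
  gidx <- (rep(xs, each = length(ys))[idx] - 1L) * H + rep(ys, length(xs))[idx]
  list(img = img, idx = gidx)
}

## irregular ice blob: union of sub-discs jittered around the centre
render_ice_blob <- function(img, cs, cy, cx, diameter_nm, pixel_size) {
  r <- diameter_nm / 2
  k <- sample(3:6, 1L)
  sub_r <- runif(k, 0.35, 0.7) * r
  ang <- runif(k, 0, 2 * pi)
  off <- runif(k, 0, 0.45) * r
  idx <- integer(0)
  for (j in seq_len(k)) {
    scy <- cy + off[j] * sin(ang[j]) / pixel_size
    scx <- cx + off[j] * cos(ang[j]) / pixel_size
    res <- render_particle(img, cs, scy, scx, 2 * sub_r[j], pixel_size)
    ## blobs darken as max, not sum, to keep a hard irregular silhouette
    img <- pmin(img, res$img)
    idx <- union(idx, res$idx)
  }
  list(img = img, idx = idx)
}

render_hole_rim <- function(img, spec) {
  H <- nrow(img); W <- ncol(img)
  R_px <- (spec$hole_rim$diameter / 2) / spec$pixel_size
  ## anchor the rim at a random point on the image border, hole centre a full
  ## radius away, so an arc of the 2 um circle clips the field of view
  side <- sample(4L, 1L)
  p <- switch(side,
    c(1, runif(1, 1, W)), c(H, runif(1, 1, W)),
    c(runif(1, 1, H), 1), c(runif(1, 1, H), W))
  phi <- runif(1, 0, 2 * pi)
  cy <- p[1] + R_px * sin(phi); cx <- p[2] + R_px * cos(phi)
  w_px <- max(2, 8 / spec$pixel_size / 2)     # rim half-width ~4 nm
  dist <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`))
  rim <- abs(dist - R_px) <= w_px
  img[rim] <- img[rim] - 50
  list(img = img, center = c(cy, cx), radius_px = R_px, mask = rim)
}

background_gradient <- function(H, W, amp, bg) {
  if (amp <= 0) return(matrix(0, H, W))
  a <- runif(3, -1, 1)
  th <- runif(1, 0, 2 * pi)
  lam <- max(H, W) * runif(1, 0.7, 1.5)
  y <- (seq_len(H) - H / 2) / H; x <- (seq_len(W) - W / 2) / W
  g <- a[1] * outer(y, rep(1, W)) + a[2] * outer(rep(1, H), x) +
    a[3] * sin(2 * pi * (outer(seq_len(H) * sin(th), rep(1, W)) +
                         outer(rep(1, H), seq_len(W) * cos(th))) / lam)
  g <- g / max(abs(g), 1e-12)
  amp * bg * g
}

#' Shot-noise standard deviation implied by a scene's noise model
#'
#' Gaussian approximation to Poisson counting noise: with `N = dose *
#' pixel_area_A2` electrons per pixel, the relative SD is `gain / sqrt(N)`.
#'
#' @param spec a [scene_spec()].
#' @return SD in grey levels.
#' @export
noise_sd <- function(spec) {
  n_e <- spec$noise$dose * (spec$pixel_size * 10)^2
  spec$noise$gain * spec$background_level / sqrt(n_e)
}

#' Simulate one synthetic micrograph with ground truth
#'
#' Deterministic for a fixed spec (including its seed). Per-class particle
#' counts are Poisson with mean `density * field_area_um2`; particles are
#' placed by rejection sampling that forbids centroid pairs closer than
#' half the sum of their radii (an `overcrowding` error is raised after 100
#' failed retries). The background gradient and shot noise are added after
#' particle rendering.
#'
#' @param spec a [scene_spec()].
#' @return list with elements `micrograph` (a [micrograph()]) and `truth`
#'   (a `scene_truth`: `particles` data frame with class, centroid (px),
#'   true diameter (nm), arc completeness and border flag; `class_masks`,
#'   one binary matrix per class; `instance_map`, integer per-particle
#'   label matrix; `hole`, rim geometry or `NULL`).
#' @export
simulate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  withr::with_seed(spec$seed, simulate_micrograph_impl(spec))
}

simulate_micrograph_impl <- function(spec) {
  H <- spec$image_shape[1]; W <- spec$image_shape[2]
  px <- spec$pixel_size
  area_um2 <- (H * px / 1000) * (W * px / 1000)
  img <- matrix(spec$background_level, H, W)
  instance <- matrix(0L, H, W)
  masks <- setNames(
    lapply(PARTICLE_CLASSES, function(.) NULL), PARTICLE_CLASSES)
  hole <- NULL
  if (isTRUE(spec$hole_rim$present)) {
    res <- render_hole_rim(img, spec)
    img <- res$img
    hole <- list(center = res$center, radius_px = res$radius_px)
  }
  rows <- list()
  placed_y <- numeric(0); placed_x <- numeric(0); placed_r <- numeric(0)
  id <- 0L
  for (cs in spec$classes) {
    n <- rpois(1L, cs$density * area_um2)
    if (n == 0) next
    diam <- sample_diameters(cs$diameter, n)
    for (k in seq_len(n)) {
      r_px <- (diam[k] / 2) / px
      ok <- FALSE
      interior <- identical(spec$placement, "interior")
      if (interior && (2 * r_px >= H - 2 || 2 * r_px >= W - 2))
        stop(sprintf("particle of diameter %.3g nm cannot fit inside the field", diam[k]))
      for (try in seq_len(100L)) {
        if (interior) {
          cy <- runif(1, 1 + r_px, H - r_px); cx <- runif(1, 1 + r_px, W - r_px)
        } else {
          cy <- runif(1, 1, H); cx <- runif(1, 1, W)
        }
        if (length(placed_r) == 0 ||
            all(sqrt((placed_y - cy)^2 + (placed_x - cx)^2) >=
                0.5 * (placed_r + r_px))) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("overcrowding: could not place %s particle after 100 retries (density %.3g/um^2)",
                     cs$class_name, cs$density))
      arc <- 1; theta0 <- 0
      if (cs$class_name == "EV_bilayer" && !is.null(spec$arc_completeness)) {
        arc <- runif(1, spec$arc_completeness[1], spec$arc_completeness[2])
        theta0 <- runif(1, 0, 2 * pi)
      }
      res <- if (cs$class_name == "ice")
        render_ice_blob(img, cs, cy, cx, diam[k], px)
      else
        render_particle(img, cs, cy, cx, diam[k], px, arc, theta0)
      img <- res$img
      id <- id + 1L
      instance[res$idx] <- id
      if (is.null(masks[[cs$class_name]])) masks[[cs$class_name]] <- matrix(0L, H, W)
      masks[[cs$class_name]][res$idx] <- 1L
      placed_y <- c(placed_y, cy); placed_x <- c(placed_x, cx)
      placed_r <- c(placed_r, r_px)
      rows[[id]] <- data.frame(
        id = id, class_name = cs$class_name, cy = cy, cx = cx,
        diameter_nm = diam[k], radius_px = r_px,
        arc_completeness = arc, arc_theta0 = theta0,
        border_truncated = (cy - r_px < 1 || cy + r_px > H ||
                            cx - r_px < 1 || cx + r_px > W))
    }
  }
  img <- img + background_gradient(H, W, spec$background_gradient_amplitude,
                                   spec$background_level)
  img <- img + rnorm(H * W, 0, noise_sd(spec))
  particles <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), class_name = character(0), cy = numeric(0),
               cx = numeric(0), diameter_nm = numeric(0),
               radius_px = numeric(0), arc_completeness = numeric(0),
               arc_theta0 = numeric(0), border_truncated = logical(0))
  truth <- structure(list(particles = particles,
                          class_masks = masks[!vapply(masks, is.null, TRUE)],
                          instance_map = instance, hole = hole),
                     class = "scene_truth")
  meta <- acquisition_metadata(total_dose = spec$noise$dose, detector = "DED")
  list(micrograph = micrograph(img, px, meta), truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d particles (%s)%s\n", nrow(x$particles),
              paste(sprintf("%s: %d", names(table(x$particles$class_name)),
                            table(x$particles$class_name)), collapse = ", "),
              if (!is.null(x$hole)) "; carbon-hole rim present" else ""))
  invisible(x)
}

#' Simulate a dataset of independent micrographs
#'
#' Per-image seeds are derived deterministically from `base_seed` with
#' [derive_seeds()]; `simulate_dataset(spec, 1, s)` equals
#' `simulate_micrograph` on the spec with seed `derive_seeds(s, 1)`.
#'
#' @param spec a [scene_spec()] (its own seed is ignored).
#' @param n_images number of micrographs (>= 1).
#' @param base_seed integer seed for the whole collection.
#' @return list of `n_images` results of [simulate_micrograph()].
#' @export
simulate_dataset <- function(spec, n_images, base_seed = 1L) {
  stopifnot(n_images >= 1)
  seeds <- derive_seeds(base_seed, n_images)
  lapply(seq_len(n_images), function(i) {
    spec$seed <- seeds[i]
    simulate_micrograph(spec)
  })
}
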