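## Particle detection and sizing: mask -> outlines (edge / skeleton) ->
## Hough circle transform -> particle records -> artifact exclusion ->
## size distribution. All radii are handled in pixels internally and
## converted to nm only in the records (diameter_nm = 2 * r * pixel_size).

#' Hough circle transform configuration
#'
#' Defaults follow the ring/circle sizing protocol: radii between 6 and 100
#' pixels are detected (26.4 and 440 nm diameter at a 2.2 nm binned pixel),
#' with a score threshold of 0.8 for complete circles and 0.5 for rings,
#' so that substantially incomplete bilayer rings are still detected.
#'
#' @param r_min,r_max radius sweep bounds, pixels (`0 < r_min < r_max`).
#' @param score_threshold_circles accumulator score threshold for filled-
#'   particle outlines (complete circles).
#' @param score_threshold_rings threshold for bilayer ring skeletons
#'   (tolerates partial arcs).
#' @return a `hough_config` list.
#' @export
hough_config <- function(r_min = 6L, r_max = 100L,
                         score_threshold_circles = 0.8,
                         score_threshold_rings = 0.5) {
  if (!(r_min > 0 && r_max > r_min)) stop("need 0 < r_min < r_max")
  thr <- c(score_threshold_circles, score_threshold_rings)
  if (any(thr <= 0) || any(thr > 1)) stop("score thresholds must lie in (0, 1]")
  structure(list(r_min = as.integer(r_min), r_max = as.integer(r_max),
                 score_threshold_circles = score_threshold_circles,
                 score_threshold_rings = score_threshold_rings),
            class = "hough_config")
}

#' Rasterized circle perimeter offsets
#'
#' Midpoint-style rasterization: the union, over both axis sweeps, of the
#' integer points `(dy, +/-round(sqrt(r^2 - dy^2)))` and
#' `(+/-round(sqrt(r^2 - dx^2)), dx)`. The same point set is used for Hough
#' voting templates, for score normalization (a complete ideal ring scores
#' exactly 1) and for drawing test rings, so the three agree by construction.
#'
#' @param r integer radius in pixels (>= 0).
#' @param arc arc completeness fraction in `(0, 1]`; offsets are restricted
#'   to angles `[theta0, theta0 + 2*pi*arc)`.
#' @param theta0 arc start angle, radians (atan2 convention on (dy, dx)).
#' @return integer matrix with columns `dy`, `dx`.
#' @export
circle_offsets <- function(r, arc = 1, theta0 = 0) {
  r <- as.integer(round(r))
  if (r < 0) stop("radius must be >= 0")
  if (r == 0L) return(matrix(0L, 1, 2, dimnames = list(NULL, c("dy", "dx"))))
  d <- seq(-r, r)
  o <- round(sqrt(r^2 - d^2))
  pts <- rbind(cbind(d, o), cbind(d, -o), cbind(o, d), cbind(-o, d))
  pts <- unique(pts)
  colnames(pts) <- c("dy", "dx")
  if (arc < 1) {
    th <- atan2(pts[, 1], pts[, 2])
    rel <- (th - theta0) %% (2 * pi)
    pts <- pts[rel < 2 * pi * arc, , drop = FALSE]
  }
  storage.mode(pts) <- "integer"
  pts
}

#' Extract outlines from a segmentation mask
#'
#' Edge mode traces the boundary pixels of filled components (foreground
#' pixels with at least one 4-neighbour of background), as used for filled
#' particle segmentations; skeleton mode thins ring-shaped components to
#' 1-pixel-wide medial lines (Zhang-Suen), as used for bilayer
#' segmentations. Both preserve topology: a filled disc yields one closed
#' boundary and an annulus skeletonizes to one closed ring.
#'
#' @param mask binary matrix or [segmentation_mask()].
#' @param mode `"edge"` or `"skeleton"`.
#' @return binary outline matrix of the same shape.
#' @export
mask_to_outlines <- function(mask, mode = c("edge", "skeleton")) {
  mode <- match.arg(mode)
  if (inherits(mask, "segmentation_mask")) mask <- mask$binary
  assert_binary(mask)
  m <- (mask > 0) * 1L
  if (mode == "skeleton") return(zhang_suen_thin(m))
  H <- nrow(m); W <- ncol(m)
  ## 4-neighbour erosion with background padding
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  core <- pad[2:(H + 1L), 2:(W + 1L)] &
    pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  (m & !core) * 1L
}

## canonical particle-record data frame
new_records <- function(class_name = character(0), cy = numeric(0),
                        cx = numeric(0), radius_px = numeric(0),
                        diameter_nm = numeric(0), score = numeric(0),
                        source = character(0),
                        border_truncated = logical(0)) {
  data.frame(class_name = class_name, cy = cy, cx = cx,
             radius_px = radius_px, diameter_nm = diameter_nm,
             score = score, source = source,
             border_truncated = border_truncated,
             excluded = logical(length(cy)),
             reason = rep(NA_character_, length(cy)))
}

#' Hough circle transform on an outline mask
#'
#' Votes every outline pixel into a `(y, x, r)` accumulator over the radius
#' sweep; the score of a candidate circle is its votes divided by the number
#' of perimeter pixels of the ideal rasterized circle of that radius, so a
#' complete ideal ring scores 1 and a partial arc scores approximately its
#' arc fraction. Peaks at or above the mode's threshold are kept after
#' non-maximum suppression: candidates are processed in descending score
#' (ties: smaller radius, then raster order) and a candidate is suppressed
#' when its centre lies within `max(r_accepted, r_candidate)/2` of an
#' accepted peak *and* the radii differ by less than 25% — concentric rings
#' of multilamellar vesicles survive, near-duplicate peaks do not.
#'
#' @param outline binary outline matrix (from [mask_to_outlines()]).
#' @param cfg a [hough_config()].
#' @param pixel_size nm/pixel, for reported diameters.
#' @param mode `"rings"` (threshold 0.5 default, source `hough_ring`) or
#'   `"circles"` (threshold 0.8 default, source `hough_circle`).
#' @param class_name class label to attach to the records.
#' @param return_accumulator also return the raw score array (for
#'   diagnostics and oracle comparison).
#' @return particle-record data frame (columns `class_name`, `cy`, `cx`,
#'   `radius_px`, `diameter_nm`, `score`, `source`, `border_truncated`,
#'   `excluded`, `reason`); if `return_accumulator`, a list with elements
#'   `records` and `scores` (array `H x W x n_radii`).
#' @export
hough_circles <- function(outline, cfg = hough_config(), pixel_size = 2.2,
                          mode = c("rings", "circles"),
                          class_name = "EV_bilayer",
                          return_accumulator = FALSE) {
  mode <- match.arg(mode)
  if (inherits(outline, "segmentation_mask")) outline <- outline$binary
  assert_binary(outline, "outline")
  H <- nrow(outline); W <- ncol(outline)
  if (cfg$r_max >= min(H, W) / 2)
    stop("r_max must be smaller than half the smaller image dimension")
  radii <- seq.int(cfg$r_min, cfg$r_max)
  offs <- lapply(radii, circle_offsets)
  idx <- which(outline > 0, arr.ind = TRUE)
  threshold <- if (mode == "rings") cfg$score_threshold_rings
               else cfg$score_threshold_circles
  source <- if (mode == "rings") "hough_ring" else "hough_circle"
  if (nrow(idx) == 0L) {
    rec <- new_records()
    return(if (return_accumulator)
      list(records = rec, scores = array(0, c(H, W, length(radii)))) else rec)
  }
  votes <- hough_accumulate_cpp(H, W, idx[, 1L], idx[, 2L], offs)
  perim <- vapply(offs, nrow, 1L)
  scores <- array(as.numeric(votes), dim(votes)) /
    rep(perim, each = H * W)
  cand <- which(scores >= threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    rec <- new_records()
    return(if (return_accumulator) list(records = rec, scores = scores) else rec)
  }
  sc <- scores[cand]
  r <- radii[cand[, 3L]]
  ## descending score, ties by smaller radius then raster order (row, col)
  ord <- order(-sc, r, cand[, 1L], cand[, 2L])
  cand <- cand[ord, , drop = FALSE]; sc <- sc[ord]; r <- r[ord]
  keep <- integer(0)
  for (i in seq_along(sc)) {
    ok <- TRUE
    for (k in keep) {
      d <- sqrt((cand[i, 1L] - cand[k, 1L])^2 + (cand[i, 2L] - cand[k, 2L])^2)
      rmax <- max(r[i], r[k])
      if (d < rmax / 2 && abs(r[i] - r[k]) / rmax < 0.25) { ok <- FALSE; break }
    }
    if (ok) keep <- c(keep, i)
  }
  cy <- cand[keep, 1L]; cx <- cand[keep, 2L]; rk <- r[keep]
  rec <- new_records(class_name = rep(class_name, length(keep)),
                     cy = cy, cx = cx, radius_px = rk,
                     diameter_nm = 2 * rk * pixel_size,
                     score = sc[keep],
                     source = rep(source, length(keep)),
                     border_truncated = (cy - rk < 1 | cy + rk > H |
                                         cx - rk < 1 | cx + rk > W))
  if (return_accumulator) list(records = rec, scores = scores) else rec
}

#' Area-equivalent particle diameter
#'
#' `d = 2 * sqrt(A / pi)`: the diameter of the circle with the same area as
#' the segmented particle, which also applies to oval particles.
#'
#' @param area surface area(s), nm^2 (> 0).
#' @return diameter(s), nm.
#' @export
area_to_diameter <- function(area) {
  if (any(area <= 0)) stop("area must be positive")
  2 * sqrt(area / pi)
}

#' Particle records from connected components of a filled mask
#'
#' 8-connected components with pixel area of at least `min_area` become
#' area-sourced records: centroid, pixel area converted to nm^2 and then to
#' the area-equivalent diameter. Touching particles merge into one
#' component (a known limitation of surface-based sizing). Components
#' touching the image border are flagged `border_truncated`.
#'
#' @param mask binary matrix or [segmentation_mask()].
#' @param pixel_size nm/pixel.
#' @param min_area minimum component area, pixels.
#' @param class_name class label for the records.
#' @return particle-record data frame (`source = "area"`, `score = NA`).
#' @export
component_records <- function(mask, pixel_size, min_area = 5L,
                              class_name = "unknown") {
  if (inherits(mask, "segmentation_mask")) {
    if (class_name == "unknown") class_name <- mask$class_name
    mask <- mask$binary
  }
  assert_binary(mask)
  lab <- label_components8((mask > 0) * 1L)
  n <- max(lab)
  if (n == 0L) return(new_records())
  H <- nrow(lab); W <- ncol(lab)
  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  area_px <- tabulate(lv, n)
  cy <- tapply(idx[, 1L], lv, mean)
  cx <- tapply(idx[, 2L], lv, mean)
  on_border <- tapply(idx[, 1L] == 1L | idx[, 1L] == H |
                      idx[, 2L] == 1L | idx[, 2L] == W, lv, any)
  keep <- which(area_px >= min_area)
  if (length(keep) == 0L) return(new_records())
  d_nm <- area_to_diameter(area_px[keep] * pixel_size^2)
  new_records(class_name = rep(class_name, length(keep)),
              cy = as.numeric(cy[as.character(keep)]),
              cx = as.numeric(cx[as.character(keep)]),
              radius_px = d_nm / 2 / pixel_size,
              diameter_nm = d_nm,
              score = rep(NA_real_, length(keep)),
              source = rep("area", length(keep)),
              border_truncated = as.logical(on_border[as.character(keep)]))
}

#' Flag artifact detections
#'
#' Rule-based exclusion with logged reasons; nothing is deleted, records are
#' flagged only. Rules: (a) `hole_rim` — the detected circle is consistent
#' with the carbon-hole rim: nearly concentric with it at a similar radius;
#' osculating it (centre at distance `rim_radius +/- r` from the hole
#' centre, the locus of circles fitted to rim-arc votes); or crossing it
#' with a large on-rim perimeter fraction. The on-rim fraction threshold is
#' derived from geometry: a circle of radius `r` tangent to a straight dark
#' band of half-width `tol` has `acos(1 - tol/r)/pi` of its perimeter
#' inside the band, so the default threshold is 80% of that value (a
#' radius-dependent bound, never above what tangency can produce).
#' (b) `border` — the record is border-truncated; (c) `ice` — the detected
#' circle overlaps the ice-class mask above `ice_overlap`.
#'
#' @param records particle-record data frame.
#' @param context list with optional elements `image_shape` (c(H, W)),
#'   `hole` (list `center` = c(y, x) px, `radius_px`), `ice_mask` (binary
#'   matrix, same shape as the image the records came from).
#' @param rim_tol_px distance tolerance to the rim circle, pixels.
#' @param ice_overlap overlap fraction threshold for rule (c).
#' @return `records` with `excluded`/`reason` filled in.
#' @export
exclude_artifacts <- function(records, context = list(), rim_tol_px = 3,
                              ice_overlap = 0.5) {
  if (nrow(records) == 0L) return(records)
  reason <- rep(NA_character_, nrow(records))
  if (!is.null(context$hole)) {
    hc <- context$hole$center; hr <- context$hole$radius_px
    for (i in seq_len(nrow(records))) {
      r_i <- records$radius_px[i]
      dc <- sqrt((records$cy[i] - hc[1])^2 + (records$cx[i] - hc[2])^2)
      concentric <- dc < rim_tol_px && abs(r_i - hr) < 2 * rim_tol_px
      osculating <- abs(abs(dc - hr) - r_i) <= rim_tol_px
      pts <- circle_offsets(r_i)
      on_rim <- mean(abs(sqrt((records$cy[i] + pts[, 1L] - hc[1])^2 +
                              (records$cx[i] + pts[, 2L] - hc[2])^2) - hr)
                     <= rim_tol_px)
      tangent_frac <- acos(max(-1, 1 - rim_tol_px / r_i)) / pi
      hit <- concentric ||
        (osculating && on_rim >= 0.5 * tangent_frac) ||
        on_rim >= 0.8 * tangent_frac
      if (hit) reason[i] <- "hole_rim"
    }
  }
  if (!is.null(context$ice_mask)) {
    ice <- context$ice_mask > 0
    H <- nrow(ice); W <- ncol(ice)
    for (i in seq_len(nrow(records))) {
      if (!is.na(reason[i])) next
      pts <- circle_offsets(records$radius_px[i])
      yy <- round(records$cy[i]) + pts[, 1L]
      xx <- round(records$cx[i]) + pts[, 2L]
      inb <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      if (!any(inb)) next
      if (mean(ice[cbind(yy[inb], xx[inb])]) > ice_overlap) reason[i] <- "ice"
    }
  }
  border <- is.na(reason) & records$border_truncated
  reason[border] <- "border"
  records$excluded <- !is.na(reason)
  records$reason <- reason
  records
}

#' Size distribution of detected particles
#'
#' Median, sample standard deviation (n-1 denominator; reported as 0 with
#' `sd_defined = FALSE` for a single particle), count, and a histogram with
#' half-open bins `[lo, hi)` of configurable width. Records flagged
#' `excluded` are dropped first.
#'
#' @param records particle-record data frame (or numeric diameters, nm).
#' @param bin_width histogram bin width, nm.
#' @param class_name restrict to one class (default: all records together).
#' @return a `size_distribution` list: `class_name`, `diameters`, `median`,
#'   `sd`, `count`, `histogram` (`breaks`, `counts`), `median_defined`,
#'   `sd_defined`.
#' @export
size_distribution <- function(records, bin_width = 10, class_name = NULL) {
  if (is.data.frame(records)) {
    if (!is.null(class_name)) records <- records[records$class_name == class_name, ]
    d <- records$diameter_nm[!records$excluded]
  } else d <- as.numeric(records)
  n <- length(d)
  med <- if (n > 0) median(d) else NA_real_
  s <- if (n > 1) sd(d) else 0
  breaks <- if (n > 0) seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
            else seq(0, bin_width, by = bin_width)
  counts <- if (n > 0)
    graphics::hist(d, breaks = breaks, right = FALSE, plot = FALSE)$counts
  else rep(0L, length(breaks) - 1L)
  structure(list(class_name = class_name %||% "all", diameters = d,
                 median = med, sd = s, count = n,
                 histogram = list(breaks = breaks, counts = counts),
                 median_defined = n > 0, sd_defined = n > 1),
            class = "size_distribution")
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("<size_distribution> class %s: n = %d, median = %s nm, SD = %s nm\n",
              x$class_name, x$count,
              if (x$median_defined) sprintf("%.1f", x$median) else "undefined",
              if (x$sd_defined) sprintf("%.1f", x$sd) else "undefined (0)"))
  invisible(x)
}

#' @export
plot.size_distribution <- function(x, main = NULL, ...) {
  h <- x$histogram
  graphics::barplot(h$counts, names.arg = head(h$breaks, -1),
                    space = 0, xlab = "diameter (nm)", ylab = "count",
                    main = main %||% sprintf("%s: n=%d, median %.1f nm, SD %.1f nm",
                                             x$class_name, x$count, x$median, x$sd),
                    ...)
  invisible(x)
}
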