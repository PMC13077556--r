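test_that("circle rasterization is closed, symmetric, and arc-restricted", {
  expect_equal(nrow(circle_offsets(0)), 1L)
  for (r in c(5L, 17L, 40L)) {
    pts <- circle_offsets(r)
    rad <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    expect_lt(max(abs(rad - r)), 0.75)
    ## 4-fold symmetry
    expect_true(all(paste(-pts[, 1], pts[, 2]) %in% paste(pts[, 1], pts[, 2])))
    ## arc fraction of points ~ arc fraction of angle
    for (a in c(0.3, 0.6)) {
      na <- nrow(circle_offsets(r, arc = a, theta0 = 0.7))
      expect_equal(na / nrow(pts), a, tolerance = 0.06)
    }
  }
})

test_that("outline extraction: disc boundaries and annulus skeletons sit at the true radius", {
  disc <- draw_disc(matrix(0L, 96, 96), 48, 48, 20)
  edge <- mask_to_outlines(disc, "edge")
  pts <- which(edge > 0, arr.ind = TRUE)
  rad <- sqrt((pts[, 1] - 48)^2 + (pts[, 2] - 48)^2)
  expect_true(all(rad >= 19 & rad <= 21))
  ## closed boundary: every edge pixel has at least two 8-neighbours
  nb <- sapply(seq_len(nrow(pts)), function(i)
    sum(edge[max(1, pts[i,1]-1):min(96, pts[i,1]+1),
             max(1, pts[i,2]-1):min(96, pts[i,2]+1)]) - 1)
  expect_true(all(nb >= 2))

  ## annulus of width 5 at mean radius 30 -> 1-px ring at 30 +/- 1
  ann <- matrix(0L, 96, 96)
  d2 <- outer((1:96 - 48)^2, (1:96 - 48)^2, `+`)
  ann[d2 >= 27.5^2 & d2 <= 32.5^2] <- 1L
  skel <- mask_to_outlines(ann, "skeleton")
  sp <- which(skel > 0, arr.ind = TRUE)
  srad <- sqrt((sp[, 1] - 48)^2 + (sp[, 2] - 48)^2)
  expect_true(all(abs(srad - 30) <= 1.3))
  snb <- sapply(seq_len(nrow(sp)), function(i)
    sum(skel[max(1, sp[i,1]-1):min(96, sp[i,1]+1),
             max(1, sp[i,2]-1):min(96, sp[i,2]+1)]) - 1)
  expect_true(all(snb >= 2))  # closed ring, no loose ends

  expect_equal(sum(mask_to_outlines(matrix(0L, 16, 16), "edge")), 0)
  expect_error(mask_to_outlines(matrix(0.5, 8, 8), "edge"), "binary")
})

test_that("hough transform finds perfect rings with score 1 and converts units", {
  o <- draw_ring(matrix(0L, 128, 128), 64, 64, 30)
  cfg <- hough_config(r_min = 6, r_max = 50)
  rec <- hough_circles(o, cfg, pixel_size = 2.2, mode = "rings")
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$radius_px, 30)
  expect_gte(rec$score, 0.95)
  expect_equal(rec$diameter_nm, 2 * 30 * 2.2)
  expect_identical(rec$source, "hough_ring")

  ## empty outline -> no records
  expect_equal(nrow(hough_circles(matrix(0L, 64, 64),
                                  hough_config(r_min = 4, r_max = 20), 2.2)), 0L)
  expect_error(hough_circles(o, hough_config(r_min = 6, r_max = 70), 2.2),
               "r_max")
})

test_that("a 60% arc passes the ring threshold and fails the circle threshold", {
  o <- draw_ring(matrix(0L, 128, 128), 60, 70, 30, arc = 0.6, theta0 = 1.1)
  cfg <- hough_config(r_min = 20, r_max = 40)
  rings <- hough_circles(o, cfg, 2.2, mode = "rings")
  expect_equal(nrow(rings), 1L)
  expect_equal(rings$radius_px, 30)
  expect_equal(rings$score, 0.6, tolerance = 0.09)
  circles <- hough_circles(o, cfg, 2.2, mode = "circles")
  expect_equal(nrow(circles), 0L)
})

test_that("non-maximum suppression keeps concentric rings and drops near-duplicates", {
  o <- matrix(0L, 160, 160)
  o <- draw_ring(o, 80, 80, 20)
  o <- draw_ring(o, 80, 80, 40)   # concentric multilamellar pair
  rec <- hough_circles(o, hough_config(r_min = 10, r_max = 60), 2.2, "rings")
  expect_equal(sort(rec$radius_px), c(20, 40))

  ## one ring plus clutter produces exactly one accepted peak
  o2 <- draw_ring(matrix(0L, 128, 128), 64, 64, 25)
  set.seed(2)
  o2[sample(length(o2), 60)] <- 1L
  rec2 <- hough_circles(o2, hough_config(r_min = 15, r_max = 40), 2.2, "rings")
  expect_equal(rec2$radius_px[1], 25)
  expect_true(all(abs(rec2$radius_px - 25) / 25 >= 0.25 |
                  sqrt((rec2$cy - 64)^2 + (rec2$cx - 64)^2) >= 12.5 |
                  seq_len(nrow(rec2)) == 1))
})

test_that("fast accumulator agrees with the brute-force oracle", {
  set.seed(42)
  for (i in 1:5) {
    o <- matrix(0L, 128, 128)
    for (k in 1:4)
      o <- draw_ring(o, sample(30:98, 1), sample(30:98, 1), sample(8:22, 1),
                     arc = runif(1, 0.4, 1), theta0 = runif(1, 0, 2 * pi))
    o[sample(length(o), 80)] <- 1L
    cfg <- hough_config(r_min = 8, r_max = 22, score_threshold_rings = 0.3)
    fast <- hough_circles(o, cfg, 2.2, "rings", return_accumulator = TRUE)
    oracle <- oracle_hough_scores(o, 8:22)
    expect_lt(max(abs(fast$scores - oracle)), 1e-9)
  }
})

test_that("area-equivalent diameters follow d = 2 sqrt(A/pi)", {
  expect_equal(area_to_diameter(pi), 2)
  expect_equal(area_to_diameter(pi * 30^2), 60)
  expect_equal(area_to_diameter(2827.43), 60, tolerance = 1e-4)
  ## 2:1 ellipse with semi-axes 40/20 nm: A = 800 pi
  expect_equal(area_to_diameter(800 * pi), 2 * sqrt(800))
  expect_equal(2 * sqrt(800), 56.5685, tolerance = 1e-4)
  expect_error(area_to_diameter(0), "positive")
  ## unit round trip for arbitrary diameters
  d <- c(0.5, 7, 26.4, 113.2, 440)
  expect_equal(area_to_diameter(pi * (d / 2)^2), d, tolerance = 1e-12)
})

test_that("component records measure areas, merge touching discs, and flag borders", {
  m <- matrix(0L, 64, 64)
  m[10:19, 10:19] <- 1L                     # 100 px component
  rec <- component_records(m, pixel_size = 2.2, min_area = 5)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$diameter_nm, 2 * sqrt(100 * 2.2^2 / pi))
  expect_equal(rec$diameter_nm, 24.8, tolerance = 0.01)
  expect_identical(rec$source, "area")
  expect_false(rec$border_truncated)

  ## touching discs merge into one record (8-connectivity)
  two <- draw_disc(draw_disc(matrix(0L, 64, 64), 32, 20, 8), 32, 36, 8)
  expect_equal(nrow(component_records(two, 2.2, 5)), 1L)

  ## sub-threshold component dropped; border touch flagged
  m2 <- matrix(0L, 32, 32); m2[1:6, 1:6] <- 1L; m2[20, 20:22] <- 1L
  rec2 <- component_records(m2, 2.2, min_area = 5)
  expect_equal(nrow(rec2), 1L)
  expect_true(rec2$border_truncated)
})

test_that("artifact exclusion flags rim-consistent, border and ice detections", {
  rec <- data.frame(
    class_name = "EV_bilayer", cy = c(100, 60, 100), cx = c(100, 60, 30),
    radius_px = c(80, 10, 10), diameter_nm = c(352, 44, 44),
    score = c(0.9, 0.8, 0.7), source = "hough_ring",
    border_truncated = c(FALSE, FALSE, FALSE), excluded = FALSE,
    reason = NA_character_)
  ctx <- list(image_shape = c(200, 200),
              hole = list(center = c(100, 100), radius_px = 80))
  out <- exclude_artifacts(rec, ctx)
  expect_true(out$excluded[1]); expect_identical(out$reason[1], "hole_rim")
  expect_false(out$excluded[2])

  ## detection whose perimeter lies on the rim arc (centre on the rim line)
  rec2 <- rec[3, ]; rec2$cy <- 100 + 80; rec2$cx <- 100; rec2$radius_px <- 6
  out2 <- exclude_artifacts(rec2, ctx)
  expect_true(out2$excluded)

  ## border truncation flag leads to exclusion with reason "border"
  rec3 <- rec[2, ]; rec3$border_truncated <- TRUE
  out3 <- exclude_artifacts(rec3, list(image_shape = c(200, 200)))
  expect_identical(out3$reason, "border")

  ## ice overlap
  ice <- draw_disc(matrix(0L, 200, 200), 60, 60, 15)
  out4 <- exclude_artifacts(rec[2, ], list(ice_mask = ice))
  expect_identical(out4$reason, "ice")
  ## nothing is deleted, only flagged
  expect_equal(nrow(out), 3L)
})

test_that("size distributions report median, SD, count and half-open histograms", {
  d <- size_distribution(c(40, 50, 60))
  expect_equal(d$median, 50); expect_equal(d$count, 3L)
  expect_equal(d$sd, sd(c(40, 50, 60)))

  one <- size_distribution(55)
  expect_equal(one$sd, 0); expect_false(one$sd_defined)

  empty <- size_distribution(numeric(0))
  expect_equal(empty$count, 0L); expect_false(empty$median_defined)

  ## half-open bins [lo, hi): a diameter on a break counts in the upper bin
  h <- size_distribution(c(50, 59.99, 60))$histogram
  i50 <- which(h$breaks == 50)
  expect_equal(h$counts[i50], 2L)       # 50 and 59.99
  expect_equal(h$counts[i50 + 1L], 1L)  # 60

  ## excluded records are dropped
  rec <- data.frame(class_name = "EV_bilayer", cy = 1, cx = 1, radius_px = 10,
                    diameter_nm = c(44, 88), score = 1, source = "hough_ring",
                    border_truncated = FALSE, excluded = c(FALSE, TRUE),
                    reason = c(NA, "border"))
  expect_equal(size_distribution(rec)$count, 1L)
})

test_that("detections are equivariant under integer translation and rotation", {
  o <- matrix(0L, 128, 128)
  o <- draw_ring(o, 50, 44, 17)
  o <- draw_ring(o, 90, 90, 11, arc = 0.7, theta0 = 0.3)
  cfg <- hough_config(r_min = 8, r_max = 25)
  base <- hough_circles(o, cfg, 2.2, "rings")

  ## translate by whole pixels
  t_o <- matrix(0L, 128, 128)
  t_o[(1:118) + 10, (1:121) + 7] <- o[1:118, 1:121]
  tr <- hough_circles(t_o, cfg, 2.2, "rings")
  expect_equal(tr$cy, base$cy + 10)
  expect_equal(tr$cx, base$cx + 7)
  expect_equal(tr$radius_px, base$radius_px)
  expect_equal(tr$score, base$score)

  ## 90 degree rotation permutes coordinates, preserves radius and score
  ro <- t(o)[, nrow(o):1]    # ro[a, b] = o[H + 1 - b, a]
  rr <- hough_circles(ro, cfg, 2.2, "rings")
  key <- function(y, x, r, s) paste(round(y), round(x), r, signif(s, 9))
  expect_setequal(key(base$cx, 129 - base$cy, base$radius_px, base$score),
                  key(rr$cy, rr$cx, rr$radius_px, rr$score))
})
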