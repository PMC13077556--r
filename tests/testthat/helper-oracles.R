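## Independent oracles, implemented without touching the package's fast
## paths: a pure-R gather-style Hough accumulator (the package scatters
## votes in C++), an independent circle rasterizer, and a direct 3x3 median.

## same rasterization *definition* as the package (union of the two axis
## sweeps of rounded circle points), derived independently on a full grid
oracle_circle_offsets <- function(r) {
  if (r == 0) return(cbind(dy = 0L, dx = 0L))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- abs(g$dx) == round(sqrt(r^2 - g$dy^2)) |
          abs(g$dy) == round(sqrt(r^2 - g$dx^2))
  as.matrix(g[keep, , drop = FALSE])
}

## votes[cy, cx] = sum over offsets of outline[cy + dy, cx + dx]
oracle_hough_scores <- function(outline, radii) {
  H <- nrow(outline); W <- ncol(outline)
  out <- array(0, c(H, W, length(radii)))
  for (j in seq_along(radii)) {
    off <- oracle_circle_offsets(radii[j])
    acc <- matrix(0, H, W)
    for (k in seq_len(nrow(off))) {
      dy <- off[k, 1L]; dx <- off[k, 2L]
      ys_dst <- max(1, 1 - dy):min(H, H - dy)
      xs_dst <- max(1, 1 - dx):min(W, W - dx)
      acc[ys_dst, xs_dst] <- acc[ys_dst, xs_dst] +
        outline[ys_dst + dy, xs_dst + dx]
    }
    out[, , j] <- acc / nrow(off)
  }
  out
}

## direct 3x3 median with replicated borders, via explicit sorting
oracle_median3x3 <- function(x) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    ii <- pmin(pmax(i + (-1:1), 1), H)
    jj <- pmin(pmax(j + (-1:1), 1), W)
    out[i, j] <- median(x[ii, jj])
  }
  out
}

## amplitude of a sinusoid of known period along one axis, measured by
## projecting the axis-mean profile onto the exact sine/cosine pair
sinusoid_amplitude <- function(x, period, axis = 2) {
  n <- dim(x)[axis]
  idx <- seq_len(n)
  basis_c <- cos(2 * pi * idx / period); basis_s <- sin(2 * pi * idx / period)
  prof <- if (axis == 2) colMeans(x) else rowMeans(x)
  2 * sqrt(mean(prof * basis_c)^2 + mean(prof * basis_s)^2)
}
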