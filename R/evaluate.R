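## Detection performance against ground truth: one-to-one greedy matching of
## predicted and true particles, precision/recall/F1/accuracy, and diameter
## error reporting. "Accuracy" for a detection task with no true negatives
## is defined here as tp / (tp + fp + fn) (Jaccard-style) and is always
## reported alongside precision, recall and F1.

#' Match predicted particles to ground truth
#'
#' Greedy one-to-one matching in descending prediction score (ties broken by
#' raster order: row, then column). A pair is valid when the centroid
#' distance is at most `max(5, 0.5 * r_truth)` pixels and the relative
#' radius error is at most 25%; among valid candidates the nearest is taken.
#' Unmatched predictions are false positives, unmatched truths false
#' negatives.
#'
#' @param predicted particle-record data frame (pixel centroids/radii);
#'   rows flagged `excluded` are ignored.
#' @param truth data frame with columns `cy`, `cx` (px) and `radius_px`
#'   (e.g. the simulator's `truth$particles`).
#' @param dist_floor_px centroid tolerance floor, pixels.
#' @param dist_factor centroid tolerance as a fraction of the true radius.
#' @param radius_tol maximum relative radius error.
#' @return a `match_result`: `pairs` (data frame `truth_id`, `pred_id`,
#'   `dist_px`, `diameter_error_nm` when diameters are available), `tp`,
#'   `fp`, `fn`.
#' @export
match_particles <- function(predicted, truth, dist_floor_px = 5,
                            dist_factor = 0.5, radius_tol = 0.25) {
  pred <- predicted[!predicted$excluded, , drop = FALSE]
  np <- nrow(pred); nt <- nrow(truth)
  sc <- pred$score
  sc[is.na(sc)] <- -Inf
  ord <- order(-sc, pred$cy, pred$cx)
  used <- logical(nt)
  pairs <- NULL
  for (i in ord) {
    d <- sqrt((truth$cy - pred$cy[i])^2 + (truth$cx - pred$cx[i])^2)
    tol <- pmax(dist_floor_px, dist_factor * truth$radius_px)
    rel <- abs(pred$radius_px[i] - truth$radius_px) /
      pmax(truth$radius_px, 1e-9)
    okm <- !used & d <= tol & rel <= radius_tol
    if (!any(okm)) next
    j <- which(okm)[which.min(d[okm])]
    used[j] <- TRUE
    derr <- if (!is.null(truth$diameter_nm) && !is.null(pred$diameter_nm))
      pred$diameter_nm[i] - truth$diameter_nm[j] else NA_real_
    pairs <- rbind(pairs, data.frame(
      truth_id = j, pred_id = i, dist_px = d[j], diameter_error_nm = derr,
      class_name = if (!is.null(truth$class_name)) truth$class_name[j]
                   else NA_character_))
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  structure(list(pairs = pairs %||% data.frame(
                   truth_id = integer(0), pred_id = integer(0),
                   dist_px = numeric(0), diameter_error_nm = numeric(0),
                   class_name = character(0)),
                 tp = tp, fp = np - tp, fn = nt - tp),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> tp = %d, fp = %d, fn = %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Detection metrics from a match result
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`, `f1` their harmonic
#' mean, and `accuracy = tp/(tp+fp+fn)` (this package's Jaccard-style
#' definition for a detection task without true negatives; `defined`
#' records which metrics are well-defined rather than propagating NaN).
#'
#' @param match a `match_result` (or list with `tp`, `fp`, `fn`).
#' @return list `precision`, `recall`, `f1`, `accuracy`, `defined`.
#' @export
detection_metrics <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  if (tp + fp + fn < 1) stop("no detections or truths to evaluate")
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec)
        else if (is.na(prec) || is.na(rec)) NA_real_ else 0
  acc <- tp / (tp + fp + fn)
  list(precision = prec, recall = rec, f1 = f1, accuracy = acc,
       defined = c(precision = !is.na(prec), recall = !is.na(rec),
                   f1 = !is.na(f1), accuracy = TRUE))
}

#' Diameter-error report over matched pairs
#'
#' Bias (mean of predicted minus true) and RMSE of particle diameters, in
#' nm, overall and per class.
#'
#' @param match a `match_result` with diameter errors.
#' @return list `bias_nm`, `rmse_nm`, `n`, `by_class` (data frame).
#' @export
size_error_report <- function(match) {
  e <- match$pairs$diameter_error_nm
  e <- e[is.finite(e)]
  if (length(e) == 0L) stop("no matched pairs with diameters")
  cls <- match$pairs$class_name[is.finite(match$pairs$diameter_error_nm)]
  by_class <- do.call(rbind, lapply(split(seq_along(e), cls), function(ix)
    data.frame(class_name = cls[ix[1]], n = length(ix),
               bias_nm = mean(e[ix]), rmse_nm = sqrt(mean(e[ix]^2)))))
  rownames(by_class) <- NULL
  list(bias_nm = mean(e), rmse_nm = sqrt(mean(e^2)), n = length(e),
       by_class = by_class)
}

#' Seeded image-subset evaluation
#'
#' Mirrors the protocol of visually inspecting a fixed fraction of a large
#' dataset: selects a deterministic random subset of images and pools their
#' match counts.
#'
#' @param matches list of `match_result`s, one per image.
#' @param fraction fraction of images to evaluate.
#' @param seed RNG seed for the subset draw.
#' @return list with `images` (indices used) and the pooled
#'   [detection_metrics()].
#' @export
evaluate_subset <- function(matches, fraction = 1, seed = 1L) {
  n <- length(matches)
  k <- max(1L, round(fraction * n))
  ix <- withr::with_seed(seed, sort(sample.int(n, k)))
  pooled <- list(tp = sum(vapply(matches[ix], `[[`, 1L, "tp")),
                 fp = sum(vapply(matches[ix], `[[`, 1L, "fp")),
                 fn = sum(vapply(matches[ix], `[[`, 1L, "fn")))
  list(images = ix, metrics = detection_metrics(pooled))
}
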