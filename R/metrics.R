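## Derived metrics on an OGD series: AOI Hits, the fixation rate and its
## distance-threshold sweep, visual-field band summaries, and mask IoU.

aoi_subset <- function(series, aoi_label) {
  stopifnot(inherits(series, "ogd_series") || is.data.frame(series))
  labs <- unique(series$aoi_label)
  if (!aoi_label %in% labs)
    stop("unknown AOI '", aoi_label, "'; series contains: ",
         paste(labs, collapse = ", "), call. = FALSE)
  series[series$aoi_label == aoi_label, , drop = FALSE]
}

#' Fixation rate of an AOI at a distance threshold
#'
#' The fraction of all fixations assigned to an AOI:
#' `FR = (number of fixations assigned to the AOI) / (total fixations)`,
#' where a fixation is assigned when its OGD is at or below the threshold.
#' At threshold 0 this is the classical AOI-Hit rate. Sentinel (undetected)
#' records count in the denominator and sit at the frame-diagonal cap, so
#' they are only assigned at the cap threshold.
#'
#' When the series carries a `trial` column and `per_trial = TRUE`
#' (default in that case), the rate is computed per trial and averaged;
#' otherwise all fixations are pooled.
#'
#' @param series An `ogd_series`.
#' @param aoi_label AOI to score.
#' @param threshold_px Distance threshold in pixels (>= 0); comparison is
#'   inclusive (`ogd <= threshold`).
#' @param weight `"count"` (the definition above) or `"duration"` to weight
#'   each fixation by its duration (requires `durations`).
#' @param durations Named numeric vector of fixation durations keyed by
#'   `fixation_id`; only used for `weight = "duration"`.
#' @param per_trial Average per-trial rates instead of pooling.
#' @return Fraction in `[0, 1]`.
#' @export
fixation_rate <- function(series, aoi_label, threshold_px,
                          weight = c("count", "duration"), durations = NULL,
                          per_trial = !is.null(series$trial)) {
  weight <- match.arg(weight)
  if (!is.numeric(threshold_px) || length(threshold_px) != 1L || threshold_px < 0)
    stop("threshold_px must be a single non-negative number", call. = FALSE)
  s <- aoi_subset(series, aoi_label)
  w <- if (weight == "count") rep(1, nrow(s)) else {
    if (is.null(durations))
      stop("weight = 'duration' requires the 'durations' vector", call. = FALSE)
    as.numeric(durations[as.character(s$fixation_id)])
  }
  assigned <- s$ogd_px <= threshold_px
  if (per_trial && !is.null(s$trial)) {
    rates <- tapply(seq_len(nrow(s)), s$trial, function(ii)
      sum(w[ii][assigned[ii]]) / sum(w[ii]))
    mean(rates)
  } else {
    sum(w[assigned]) / sum(w)
  }
}

#' Fixation-rate curve over a distance-threshold sweep
#'
#' Evaluates [fixation_rate()] on the grid `{0, step, 2*step, ..., max}`
#' (default 0 to the frame diagonal in 10 px steps). The curve is
#' non-decreasing in the threshold and reaches 1 at the frame diagonal,
#' where sentinel records are included.
#'
#' @inheritParams fixation_rate
#' @param step_px Grid step in pixels (> 0), default 10.
#' @param max_px Grid maximum, default the series camera's frame diagonal.
#' @return An `fr_curve` data frame: `aoi_label`, `distance_px`, `fr`.
#' @export
fr_curve <- function(series, aoi_label, step_px = 10, max_px = NULL,
                     weight = c("count", "duration"), durations = NULL,
                     per_trial = !is.null(series$trial)) {
  if (!is.numeric(step_px) || length(step_px) != 1L || step_px <= 0)
    stop("step_px must be a single positive number", call. = FALSE)
  if (is.null(max_px)) {
    camera <- attr(series, "camera")
    if (is.null(camera))
      stop("max_px not given and series carries no camera", call. = FALSE)
    max_px <- frame_diagonal_px(camera)
  }
  grid <- seq(0, max_px, by = step_px)
  if (grid[length(grid)] < max_px) grid <- c(grid, max_px)
  fr <- vapply(grid, function(d)
    fixation_rate(series, aoi_label, d, weight = weight,
                  durations = durations, per_trial = per_trial),
    numeric(1))
  structure(data.frame(aoi_label = aoi_label, distance_px = grid, fr = fr),
            class = c("fr_curve", "data.frame"))
}

#' @export
plot.fr_curve <- function(x, ...) {
  graphics::plot(x$distance_px, x$fr, type = "s", ylim = c(0, 1),
                 xlab = "OGD threshold [px]", ylab = "fixation rate", ...)
  invisible(x)
}

#' AOI Hits of a series
#'
#' Fixations whose gaze coordinate fell inside the AOI's mask (OGD exactly
#' 0 and not sentinel) — the traditional one-to-one AOI Hit mapping.
#'
#' @inheritParams fixation_rate
#' @return Vector of fixation ids.
#' @export
aoi_hits <- function(series, aoi_label) {
  s <- aoi_subset(series, aoi_label)
  s$fixation_id[s$ogd_px == 0 & !s$sentinel]
}

#' Visual-field band summary of an AOI
#'
#' Classifies each of the AOI's OGD records into visual-field bands via
#' [classify_vision_field()] and tabulates counts and fractions. Fractions
#' partition unity over the six bands.
#'
#' @inheritParams fixation_rate
#' @param spec A [vision_field_spec()].
#' @return A data frame with one row per band: `aoi_label`, `band`,
#'   `count`, `fraction`.
#' @export
band_summary <- function(series, aoi_label, spec) {
  s <- aoi_subset(series, aoi_label)
  band <- classify_vision_field(s$ogd_px, spec, s$sentinel)
  counts <- table(band)
  data.frame(aoi_label = aoi_label, band = names(counts),
             count = as.integer(counts),
             fraction = as.numeric(counts) / nrow(s))
}

#' Intersection over union of two masks
#'
#' The area of overlap between a predicted and a reference mask divided by
#' the area of their union — the mask-quality metric used to evaluate
#' segmentation output against manual labels. Two empty masks score 0 by
#' convention (with a warning): there is no area whose agreement could be
#' credited.
#'
#' @param pred,truth Logical matrices of equal dimensions.
#' @return Fraction in `[0, 1]`.
#' @export
mask_iou <- function(pred, truth) {
  if (!is.matrix(pred) || !is.matrix(truth) ||
      !is.logical(pred) || !is.logical(truth))
    stop("masks must be logical matrices", call. = FALSE)
  if (!all(dim(pred) == dim(truth)))
    stop("mask dimensions differ: ", paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), call. = FALSE)
  union <- sum(pred | truth)
  if (union == 0L) {
    warning("both masks are empty; IoU defined as 0", call. = FALSE)
    return(0)
  }
  sum(pred & truth) / union
}

#' Per-frame IoU report between two mask streams
#'
#' @param pred_frames,truth_frames Lists of [frame_segmentation()] of equal
#'   length. Instances per label are merged before comparison; a label
#'   missing from one stream in a frame scores IoU 0 for that frame.
#' @return Data frame: `frame_index`, `aoi_label`, `iou`.
#' @export
iou_report <- function(pred_frames, truth_frames) {
  if (length(pred_frames) != length(truth_frames))
    stop("frame streams differ in length", call. = FALSE)
  rows <- list()
  for (i in seq_along(pred_frames)) {
    p <- pred_frames[[i]]; t <- truth_frames[[i]]
    labs <- union(names(p$masks), names(t$masks))
    for (lab in labs) {
      pm <- merge_instances(p$masks[[lab]])
      tm <- merge_instances(t$masks[[lab]])
      if (is.null(pm) && is.null(tm)) next
      iou <- if (is.null(pm) || is.null(tm)) 0 else mask_iou(pm, tm)
      rows[[length(rows) + 1L]] <- data.frame(
        frame_index = p$frame_index, aoi_label = lab, iou = iou)
    }
  }
  if (!length(rows))
    return(data.frame(frame_index = integer(), aoi_label = character(),
                      iou = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

merge_instances <- function(inst) {
  if (is.null(inst) || length(inst) == 0L) return(NULL)
  out <- inst[[1L]]
  for (m in inst[-1L]) out <- out | m
  out
}
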