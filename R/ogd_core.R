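## The object-gaze distance (OGD): the minimal 2D Euclidean pixel distance
## between a fixation's gaze coordinate and each AOI's segmented mask.
## Distances are measured to mask pixel centers; a gaze whose containing
## pixel is part of the mask scores exactly 0 (an AOI Hit). When an AOI is
## not detected in the frame the record takes the frame-diagonal sentinel.

round_half_up <- function(x) floor(x + 0.5)

## Boundary pixels of a mask: true pixels with at least one false (or
## out-of-frame) 4-neighbour. For a gaze point whose containing pixel is
## outside the mask, the nearest true pixel center is always a boundary
## pixel, so the minimum can be taken over this much smaller set.
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  interior <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  mask & !interior
}

## Precomputed query structure: containing-pixel grid + boundary coordinates.
mask_distance_index <- function(mask) {
  idx <- which(mask_boundary(mask))
  h <- nrow(mask)
  list(mask = mask,
       bx = as.numeric((idx - 1L) %/% h),   # 0-based pixel x
       by = as.numeric((idx - 1L) %% h))    # 0-based pixel y
}

query_distance_index <- function(index, gaze_x, gaze_y) {
  mask <- index$mask
  rx <- round_half_up(gaze_x); ry <- round_half_up(gaze_y)
  if (rx >= 0 && rx < ncol(mask) && ry >= 0 && ry < nrow(mask) &&
      mask[ry + 1L, rx + 1L])
    return(0)
  min(sqrt((index$bx - gaze_x)^2 + (index$by - gaze_y)^2))
}

#' Minimal Euclidean distance from a gaze point to a mask
#'
#' The minimum over all mask pixels of the Euclidean distance between the
#' (possibly sub-pixel) gaze coordinate and the pixel's center; exactly 0
#' when the gaze's containing pixel (nearest pixel center) belongs to the
#' mask, i.e. an AOI Hit. The minimum is evaluated over the mask's boundary
#' pixels, which is exact: for any gaze point outside the mask the nearest
#' mask pixel center lies on the 4-connected boundary.
#'
#' @param gaze_x,gaze_y Gaze coordinate in pixels (0-based, pixel centers at
#'   integers; see the coordinate convention in the package vignette).
#' @param mask Logical matrix of dim (height, width) with at least one
#'   `TRUE` pixel. Empty masks are rejected: an undetected AOI must be
#'   routed to the sentinel by the caller, not given a distance.
#' @return Distance in pixels (>= 0).
#' @export
min_distance_to_mask <- function(gaze_x, gaze_y, mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("mask must be a logical matrix", call. = FALSE)
  if (!any(mask))
    stop("empty mask: an undetected AOI has no distance; use the sentinel",
         call. = FALSE)
  if (!is.finite(gaze_x) || !is.finite(gaze_y))
    stop("gaze coordinates must be finite", call. = FALSE)
  query_distance_index(mask_distance_index(mask), gaze_x, gaze_y)
}

#' Map a fixation to scene-video frame indices
#'
#' Frame `k` covers the time interval `[k/fps, (k+1)/fps)`. Policy
#' `"midpoint"` selects the single frame at the fixation's temporal
#' midpoint, `round((start + duration/2) * fps)` (half-up rounding);
#' `"all_frames"` selects every frame overlapped by the half-open span
#' `[start, start + duration)`.
#'
#' @param fixation One fixation (a 1-row data frame or list with `start_s`,
#'   `duration_s` and `fixation_id`).
#' @param camera A [camera_model()]; its `fps` must match the mask stream's
#'   frame rate (subsampled mask streams declare their own fps).
#' @param policy `"midpoint"` or `"all_frames"`.
#' @param n_frames Optional frame count; when given, indices outside
#'   `[0, n_frames)` raise an error naming the fixation.
#' @return Integer frame index (midpoint) or vector of indices (all_frames).
#' @export
fixation_frame <- function(fixation, camera, policy = c("midpoint", "all_frames"),
                           n_frames = NULL) {
  assert_camera(camera)
  policy <- match.arg(policy)
  s <- as.numeric(fixation$start_s); d <- as.numeric(fixation$duration_s)
  fps <- camera$fps
  idx <- if (policy == "midpoint") {
    as.integer(round_half_up((s + d / 2) * fps))
  } else {
    first <- as.integer(floor(s * fps + 1e-9))
    last <- as.integer(ceiling((s + d) * fps - 1e-9)) - 1L
    first:max(first, last)
  }
  if (!is.null(n_frames) && (min(idx) < 0L || max(idx) >= n_frames))
    stop("fixation ", fixation$fixation_id, " maps to frame(s) outside the ",
         "range [0, ", n_frames, ")", call. = FALSE)
  idx
}

## Distance for one fixation against one AOI across its selected frames.
## index_cache: environment keyed "<frame>|<label>" -> list of instance
## indexes, or NA when the AOI is absent in that frame.
ogd_one <- function(gaze_x, gaze_y, frame_idx, aoi_label, frames, diagonal,
                    aggregate, index_cache) {
  per_frame <- vapply(frame_idx, function(k) {
    key <- paste0(k, "|", aoi_label)
    entry <- index_cache[[key]]
    if (is.null(entry)) {
      inst <- frames[[k + 1L]]$masks[[aoi_label]]
      entry <- if (is.null(inst) || length(inst) == 0L) NA else
        lapply(inst, mask_distance_index)
      index_cache[[key]] <- entry
    }
    if (identical(entry, NA)) return(NA_real_)
    min(vapply(entry, query_distance_index, numeric(1),
               gaze_x = gaze_x, gaze_y = gaze_y))
  }, numeric(1))
  absent <- is.na(per_frame)
  per_frame[absent] <- diagonal           # undetected frames sit at the cap
  per_frame <- pmin(per_frame, diagonal)  # cap (gaze may be out of frame)
  val <- switch(aggregate,
                median = stats::median(per_frame),
                mean = mean(per_frame),
                min = min(per_frame))
  list(ogd_px = val, sentinel = all(absent))
}

#' OGD record for a single fixation and AOI
#'
#' Computes the minimal gaze-to-mask distance for one fixation against one
#' AOI. Per selected frame the distance is the minimum over the AOI's
#' instance masks, or the frame-diagonal sentinel when the AOI has no
#' instances in that frame; multi-frame values are combined with
#' `aggregate`. The record is flagged sentinel only when the AOI is absent
#' in every selected frame.
#'
#' @inheritParams fixation_frame
#' @param frames List of [frame_segmentation()] covering the fixation.
#' @param aoi_label AOI to score; must be a known label.
#' @param aggregate `"median"` (default), `"mean"` or `"min"` across the
#'   selected frames.
#' @param known_labels Labels considered valid; defaults to those present
#'   anywhere in `frames`.
#' @return A one-row data frame: `fixation_id`, `aoi_label`, `ogd_px`,
#'   `sentinel`, `frame_index_used`.
#' @export
ogd_for_fixation <- function(fixation, frames, aoi_label, camera,
                             policy = c("midpoint", "all_frames"),
                             aggregate = c("median", "mean", "min"),
                             known_labels = NULL) {
  assert_camera(camera)
  policy <- match.arg(policy); aggregate <- match.arg(aggregate)
  if (is.null(known_labels))
    known_labels <- unique(unlist(lapply(frames, function(f) names(f$masks))))
  if (!aoi_label %in% known_labels)
    stop("unknown AOI label '", aoi_label, "'; known labels: ",
         paste(known_labels, collapse = ", "), call. = FALSE)
  idx <- fixation_frame(fixation, camera, policy, n_frames = length(frames))
  res <- ogd_one(as.numeric(fixation$gaze_x), as.numeric(fixation$gaze_y),
                 idx, aoi_label, frames, frame_diagonal_px(camera),
                 aggregate, new.env(parent = emptyenv()))
  data.frame(fixation_id = fixation$fixation_id, aoi_label = aoi_label,
             ogd_px = res$ogd_px, sentinel = res$sentinel,
             frame_index_used = idx[ceiling(length(idx) / 2)])
}

new_ogd_series <- function(df, camera) {
  assert_camera(camera)
  structure(df, camera = camera, class = c("ogd_series", "data.frame"))
}

#' Compute the full OGD series of a trial
#'
#' Maps every fixation to every AOI label of the trial — the continuous
#' extension of one-to-one AOI Hit mapping — producing the complete
#' fixation x AOI grid of distance records, ordered by fixation time then
#' AOI label.
#'
#' @param bundle A [trial_bundle()].
#' @param policy Frame-selection policy, see [fixation_frame()].
#' @param aggregate Multi-frame aggregation, see [ogd_for_fixation()].
#' @return An `ogd_series`: a data frame with columns `fixation_id`,
#'   `aoi_label`, `ogd_px`, `sentinel`, `frame_index_used` (plus `trial`
#'   when the fixation table has one), carrying the camera as an attribute.
#' @examples
#' sc <- generate_scene(scene_spec(
#'   camera = camera_model(160, 120, 60, 46, 30), n_frames = 4,
#'   objects = list(scene_object("disk1", "disk", c(80, 60), radius = 12)),
#'   fixations = data.frame(fixation_id = 1:2, start_s = c(0, 0.05),
#'                          duration_s = 0.04, gaze_x = c(80, 20),
#'                          gaze_y = c(60, 60)),
#'   seed = 1))
#' compute_ogd_series(sc$bundle)
#' @export
compute_ogd_series <- function(bundle, policy = c("midpoint", "all_frames"),
                               aggregate = c("median", "mean", "min")) {
  stopifnot(inherits(bundle, "trial_bundle"))
  policy <- match.arg(policy); aggregate <- match.arg(aggregate)
  fix <- bundle$fixations
  labels <- bundle$aoi_labels
  if (length(labels) == 0L) stop("bundle has no AOI labels", call. = FALSE)
  diagonal <- frame_diagonal_px(bundle$camera)
  cache <- new.env(parent = emptyenv())
  n <- nrow(fix)
  rows <- vector("list", n * length(labels))
  r <- 0L
  for (i in seq_len(n)) {
    idx <- fixation_frame(fix[i, ], bundle$camera, policy,
                          n_frames = length(bundle$frames))
    for (lab in labels) {
      res <- ogd_one(fix$gaze_x[i], fix$gaze_y[i], idx, lab, bundle$frames,
                     diagonal, aggregate, cache)
      r <- r + 1L
      rows[[r]] <- data.frame(
        fixation_id = fix$fixation_id[i], aoi_label = lab,
        ogd_px = res$ogd_px, sentinel = res$sentinel,
        frame_index_used = idx[ceiling(length(idx) / 2)])
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(fix$trial))
    out$trial <- fix$trial[match(out$fixation_id, fix$fixation_id)]
  rownames(out) <- NULL
  new_ogd_series(out, bundle$camera)
}

#' @export
print.ogd_series <- function(x, ...) {
  cat(sprintf("OGD series: %d records (%d fixations x %d AOIs)\n",
              nrow(x), length(unique(x$fixation_id)),
              length(unique(x$aoi_label))))
  NextMethod()
}

#' @export
summary.ogd_series <- function(object, spec = NULL, ...) {
  camera <- attr(object, "camera")
  if (is.null(spec)) spec <- default_field_spec(camera, "derived_from_camera")
  labs <- sort(unique(object$aoi_label))
  do.call(rbind, lapply(labs, function(lab) {
    s <- object[object$aoi_label == lab, ]
    data.frame(aoi_label = lab, n = nrow(s),
               hits = sum(s$ogd_px == 0 & !s$sentinel),
               sentinels = sum(s$sentinel),
               median_ogd_px = stats::median(s$ogd_px[!s$sentinel]),
               foveal_frac = mean(
                 classify_vision_field(s$ogd_px, spec, s$sentinel) == "foveal"))
  }))
}

#' Multi-OGD plot
#'
#' Plots the OGD of each AOI against fixation order on one axis — the
#' multi-object gaze-distance graph — with horizontal lines at the
#' visual-field thresholds and AOI Hits (0 px) marked.
#'
#' @param x An `ogd_series`.
#' @param spec Optional [vision_field_spec()] for the threshold lines.
#' @param ... Passed to [graphics::matplot()].
#' @return The plotted wide matrix, invisibly.
#' @export
plot.ogd_series <- function(x, spec = NULL, ...) {
  camera <- attr(x, "camera")
  if (is.null(spec)) spec <- default_field_spec(camera, "derived_from_camera")
  labs <- sort(unique(x$aoi_label))
  ids <- unique(x$fixation_id)
  wide <- sapply(labs, function(lab)
    x$ogd_px[x$aoi_label == lab][match(ids, x$fixation_id[x$aoi_label == lab])])
  graphics::matplot(seq_along(ids), wide, type = "l", lty = 1:5,
                    xlab = "fixation", ylab = "OGD [px]", ...)
  graphics::abline(h = c(spec$foveal_px, spec$parafoveal_px,
                         spec$perifoveal_px, spec$near_peripheral_px),
                   col = "grey60", lty = 3)
  hits <- wide == 0
  for (j in seq_along(labs))
    graphics::points(which(hits[, j]), rep(0, sum(hits[, j])), pch = 3, col = j)
  graphics::legend("topright", legend = labs, col = seq_along(labs),
                   lty = 1:5, bty = "n")
  invisible(wide)
}
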