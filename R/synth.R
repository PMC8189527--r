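## Synthetic scenes with analytic ground truth, the brute-force distance
## oracle, and embedded-pattern series: the test bed for the whole pipeline.
## All generators are pure functions of (spec, seed); random streams are
## split per purpose (gaze positions, gaze noise, dropout) by deriving a
## fixed offset sub-seed for each, so changing one does not perturb another.

#' Brute-force minimal gaze-to-mask distance (reference oracle)
#'
#' The exhaustive minimum of the Euclidean distance from the gaze
#' coordinate to the center of every true pixel of the mask, with a gaze
#' whose containing pixel is true scoring 0. Shares no code with the fast
#' path in [min_distance_to_mask()]; it exists to check it.
#'
#' @inheritParams min_distance_to_mask
#' @return Distance in pixels.
#' @export
brute_force_min_distance <- function(gaze_x, gaze_y, mask) {
  if (!any(mask)) stop("empty mask", call. = FALSE)
  coords <- which(mask, arr.ind = TRUE)
  px <- unname(coords[, 2L]) - 1  # 0-based x
  py <- unname(coords[, 1L]) - 1  # 0-based y
  rx <- floor(gaze_x + 0.5); ry <- floor(gaze_y + 0.5)
  if (any(px == rx & py == ry)) return(0)
  best <- Inf
  for (i in seq_along(px)) {
    d <- sqrt((px[i] - gaze_x)^2 + (py[i] - gaze_y)^2)
    if (d < best) best <- d
  }
  best
}

#' A rigid scene object
#'
#' @param label AOI label.
#' @param shape `"disk"` or `"rectangle"` (axis-aligned).
#' @param center Either a length-2 `(x, y)` center (static object) or an
#'   `n_frames` x 2 matrix of per-frame centers, in pixel coordinates.
#' @param radius Disk radius in pixels.
#' @param width,height Rectangle side lengths in pixels.
#' @return An object of class `scene_object`.
#' @export
scene_object <- function(label, shape = c("disk", "rectangle"), center,
                         radius = NULL, width = NULL, height = NULL) {
  shape <- match.arg(shape)
  if (is.numeric(center) && length(center) == 2L)
    center <- matrix(center, nrow = 1L)
  center <- as.matrix(center)
  if (ncol(center) != 2L) stop("center must be (x, y)", call. = FALSE)
  if (shape == "disk") {
    if (is.null(radius) || radius <= 0) stop("disk needs radius > 0", call. = FALSE)
  } else {
    if (is.null(width) || is.null(height) || width <= 0 || height <= 0)
      stop("rectangle needs width, height > 0", call. = FALSE)
  }
  structure(list(label = label, shape = shape, center = center,
                 radius = radius, width = width, height = height),
            class = "scene_object")
}

object_center_at <- function(obj, frame_index, n_frames) {
  if (nrow(obj$center) == 1L) return(obj$center[1L, ])
  if (nrow(obj$center) != n_frames)
    stop("object '", obj$label, "' trajectory has ", nrow(obj$center),
         " rows for ", n_frames, " frames", call. = FALSE)
  obj$center[frame_index + 1L, ]
}

#' Linear trajectory helper
#' @param from,to `(x, y)` endpoints in pixels.
#' @param n_frames Number of frames.
#' @return An `n_frames` x 2 matrix of centers.
#' @export
linear_trajectory <- function(from, to, n_frames) {
  t <- if (n_frames == 1L) 0 else (seq_len(n_frames) - 1) / (n_frames - 1)
  cbind(from[1] + t * (to[1] - from[1]), from[2] + t * (to[2] - from[2]))
}

#' Specification of a synthetic scene
#'
#' Describes a trial that [generate_scene()] can realise: 1-3 rigid objects
#' (disks or axis-aligned rectangles) moving through the scene frame, with
#' per-label intermittent detection dropout, and a fixation track whose
#' gaze points have closed-form distances to the objects.
#'
#' Defaults emulate the conditions of an instrumented manual task recorded
#' with the reference glasses: a 1280 x 960 px frame, two tool-sized
#' objects (a disk of radius 40 px and a 220 x 60 px rectangle) drifting
#' slowly, a mask stream subsampled to 5 fps over ~22 s, fixations with
#' mean duration ~0.65 s, and 10% detection dropout per label.
#'
#' @param camera A [camera_model()]. For subsampled mask streams, `fps` is
#'   the mask-stream rate.
#' @param objects List of [scene_object()].
#' @param n_frames Number of mask frames.
#' @param dropout Named per-label dropout probability per frame (labels
#'   missing from the vector get 0), or a single number applied to all.
#' @param fixations Optional fixation table (see [as_fixations()]); when
#'   `NULL`, a seeded track of `n_fixations` is generated.
#' @param n_fixations Number of fixations to generate when `fixations` is
#'   `NULL`.
#' @param gaze_noise_px Standard deviation of isotropic Gaussian noise
#'   added to generated gaze points (0 disables; noise is applied before
#'   ground truth is computed, so truth always matches the emitted track).
#' @param seed Integer seed; generation is a pure function of (spec, seed).
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(camera = NULL, objects = NULL, n_frames = 112L,
                       dropout = 0.1, fixations = NULL, n_fixations = 26L,
                       gaze_noise_px = 0, seed = 1L) {
  if (is.null(camera)) camera <- camera_model(1280L, 960L, 60, 46, 5)
  assert_camera(camera)
  if (is.null(objects)) {
    w <- camera$width_px; h <- camera$height_px
    ## trajectories drift but keep the two objects disjoint in every frame:
    ## a label image cannot encode overlapping instances
    objects <- list(
      scene_object("screw", "disk",
                   linear_trajectory(c(0.32 * w, 0.55 * h),
                                     c(0.42 * w, 0.45 * h), n_frames),
                   radius = 40 * w / 1280),
      scene_object("screwdriver", "rectangle",
                   linear_trajectory(c(0.72 * w, 0.35 * h),
                                     c(0.62 * w, 0.5 * h), n_frames),
                   width = 220 * w / 1280, height = 60 * w / 1280))
  }
  labels <- vapply(objects, function(o) o$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate object labels", call. = FALSE)
  if (length(dropout) == 1L && is.null(names(dropout)))
    dropout <- stats::setNames(rep(dropout, length(labels)), labels)
  if (any(dropout < 0 | dropout > 1))
    stop("dropout probabilities must be in [0, 1]", call. = FALSE)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  structure(list(camera = camera, objects = objects,
                 n_frames = as.integer(n_frames), dropout = dropout,
                 fixations = fixations, n_fixations = as.integer(n_fixations),
                 gaze_noise_px = gaze_noise_px, seed = as.integer(seed)),
            class = "scene_spec")
}

## Objects are realized on the pixel grid before rasterization: the center
## is rounded to a whole pixel per frame and the radius / half-extents to
## whole pixels. Ground truth describes the realized geometry exactly, so
## closed-form agreement measures pure rasterization error. With integer
## box edges the rasterized rectangle boundary deviates from the realized
## box by at most half a pixel per axis, which is what keeps the
## half-pixel-diagonal agreement bound valid; a box realized at arbitrary
## sub-pixel positions can be off by a full pixel.
realize_geometry <- function(obj, center) {
  cx <- round_half_up(center[1]); cy <- round_half_up(center[2])
  if (obj$shape == "disk")
    list(cx = cx, cy = cy, r = max(1, round_half_up(obj$radius)))
  else
    list(cx = cx, cy = cy,
         hw = max(1, round_half_up(obj$width / 2)),
         hh = max(1, round_half_up(obj$height / 2)))
}

## Rasterize one realized object: a pixel is set when its center lies
## inside the shape (center-in test, boundary inclusive).
rasterize_object <- function(obj, center, camera) {
  h <- camera$height_px; w <- camera$width_px
  mask <- matrix(FALSE, h, w)
  g <- realize_geometry(obj, center)
  if (obj$shape == "disk") {
    x0 <- max(0L, g$cx - g$r); x1 <- min(w - 1L, g$cx + g$r)
    y0 <- max(0L, g$cy - g$r); y1 <- min(h - 1L, g$cy + g$r)
    if (x1 < x0 || y1 < y0) return(mask)
    xs <- x0:x1; ys <- y0:y1
    sub <- outer((ys - g$cy)^2, (xs - g$cx)^2, `+`) <= g$r^2
    mask[ys + 1L, xs + 1L] <- sub
  } else {
    x0 <- max(0L, g$cx - g$hw); x1 <- min(w - 1L, g$cx + g$hw)
    y0 <- max(0L, g$cy - g$hh); y1 <- min(h - 1L, g$cy + g$hh)
    if (x1 < x0 || y1 < y0) return(mask)
    mask[(y0:y1) + 1L, (x0:x1) + 1L] <- TRUE
  }
  mask
}

## Closed-form distance from a gaze point to the realized shape (0 inside).
analytic_distance <- function(obj, center, gx, gy) {
  g <- realize_geometry(obj, center)
  if (obj$shape == "disk") {
    max(0, sqrt((gx - g$cx)^2 + (gy - g$cy)^2) - g$r)
  } else {
    dx <- max(g$cx - g$hw - gx, 0, gx - g$cx - g$hw)
    dy <- max(g$cy - g$hh - gy, 0, gy - g$cy - g$hh)
    sqrt(dx^2 + dy^2)
  }
}

## Sub-seeds per purpose; kept below 2^31.
sub_seed <- function(seed, k) (seed %% 1000000L) * 1000L + k

generate_gaze_track <- function(spec) {
  camera <- spec$camera
  n <- spec$n_fixations
  trial_dur <- spec$n_frames / camera$fps
  set.seed(sub_seed(spec$seed, 1L))
  ## durations ~ 0.1 + Exp(mean 0.55): mean ~0.65 s, right-skewed like
  ## recorded fixation durations; rescaled to fit the trial with gaps
  dur <- 0.1 + stats::rexp(n, rate = 1 / 0.55)
  gap <- stats::runif(n, 0.01, 0.05)
  total <- sum(dur + gap)
  ## keep the last fixation's span strictly before the last frame's midpoint
  ## so both frame policies stay inside [0, n_frames)
  scale <- ((spec$n_frames - 0.5) / camera$fps) / total
  dur <- dur * scale; gap <- gap * scale
  start <- cumsum(c(0, (dur + gap)[-n]))
  ## gaze: half the fixations land near an object, half roam the frame
  near <- stats::runif(n) < 0.5
  obj_pick <- sample(length(spec$objects), n, replace = TRUE)
  gx <- stats::runif(n, 0, camera$width_px - 1)
  gy <- stats::runif(n, 0, camera$height_px - 1)
  for (i in which(near)) {
    obj <- spec$objects[[obj_pick[i]]]
    mid_frame <- min(spec$n_frames - 1L,
                     max(0L, round_half_up((start[i] + dur[i] / 2) * camera$fps)))
    ctr <- object_center_at(obj, mid_frame, spec$n_frames)
    gx[i] <- ctr[1] + stats::rnorm(1, 0, 80 * camera$width_px / 1280)
    gy[i] <- ctr[2] + stats::rnorm(1, 0, 80 * camera$width_px / 1280)
  }
  gx <- pmin(pmax(gx, 0), camera$width_px - 1)
  gy <- pmin(pmax(gy, 0), camera$height_px - 1)
  data.frame(fixation_id = seq_len(n), start_s = start, duration_s = dur,
             gaze_x = gx, gaze_y = gy)
}

#' Generate a synthetic scene with analytic ground truth
#'
#' Rasterizes each object's trajectory into per-frame binary masks (disk:
#' pixels whose centers fall within the radius; rectangle: centers inside
#' the axis-aligned box), applies seeded per-label detection dropout, and
#' computes for every fixation x label the closed-form distance from the
#' gaze point to the continuous (pre-rasterization) shape at the
#' fixation's midpoint frame, together with a detected flag.
#'
#' @param spec A [scene_spec()].
#' @return List with `bundle` (a [trial_bundle()]) and `truth` (data frame:
#'   `fixation_id`, `aoi_label`, `analytic_px`, `detected`,
#'   `frame_index`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  camera <- spec$camera
  fix <- spec$fixations
  if (is.null(fix)) fix <- generate_gaze_track(spec)
  fix <- as_fixations(fix, camera = camera)
  if (spec$gaze_noise_px > 0) {
    set.seed(sub_seed(spec$seed, 2L))
    fix$gaze_x <- fix$gaze_x + stats::rnorm(nrow(fix), 0, spec$gaze_noise_px)
    fix$gaze_y <- fix$gaze_y + stats::rnorm(nrow(fix), 0, spec$gaze_noise_px)
  }
  labels <- vapply(spec$objects, function(o) o$label, character(1))
  ## dropout draws, one stream per label in fixed label order
  set.seed(sub_seed(spec$seed, 3L))
  dropped <- sapply(labels, function(lab) {
    p <- spec$dropout[[lab]] %||% 0
    stats::runif(spec$n_frames) < p
  })
  dropped <- matrix(dropped, nrow = spec$n_frames,
                    dimnames = list(NULL, labels))
  any_raster <- FALSE
  frames <- lapply(seq_len(spec$n_frames) - 1L, function(k) {
    masks <- list()
    for (oi in seq_along(spec$objects)) {
      obj <- spec$objects[[oi]]
      if (dropped[k + 1L, obj$label]) next
      m <- rasterize_object(obj, object_center_at(obj, k, spec$n_frames), camera)
      if (any(m)) {
        masks[[obj$label]] <- list(m)
        any_raster <<- TRUE
      }
    }
    frame_segmentation(k, masks)
  })
  if (!any_raster)
    warning("no object rasterized to any pixel in any frame", call. = FALSE)
  bundle <- trial_bundle(camera, fix, frames, aoi_labels = labels)
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    k <- fixation_frame(fix[i, ], camera, "midpoint",
                        n_frames = spec$n_frames)
    for (oi in seq_along(spec$objects)) {
      obj <- spec$objects[[oi]]
      ctr <- object_center_at(obj, k, spec$n_frames)
      rows[[length(rows) + 1L]] <- data.frame(
        fixation_id = fix$fixation_id[i], aoi_label = obj$label,
        analytic_px = analytic_distance(obj, ctr, fix$gaze_x[i], fix$gaze_y[i]),
        detected = !dropped[k + 1L, obj$label] &&
          !is.null(frames[[k + 1L]]$masks[[obj$label]]),
        frame_index = k)
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(bundle = bundle, truth = truth)
}

#' Remove a label's masks from a random subset of frames
#'
#' Simulates intermittent detection dropout: a seeded Bernoulli draw per
#' frame removes the label's masks with probability `rate`.
#'
#' @param frames List of [frame_segmentation()].
#' @param label AOI label to drop (must occur in the frames).
#' @param rate Dropout probability per frame in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified frame list.
#' @export
inject_dropout <- function(frames, label, rate, seed) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  known <- unique(unlist(lapply(frames, function(f) names(f$masks))))
  if (!label %in% known)
    stop("unknown label '", label, "'; frames contain: ",
         paste(known, collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  drop <- stats::runif(length(frames)) < rate
  for (i in which(drop)) frames[[i]]$masks[[label]] <- NULL
  frames
}

#' Build a series pair containing exactly one gaze pattern
#'
#' Constructs two aligned OGD vectors of the requested length holding one
#' instance of the requested pattern in the middle, padded elsewhere with
#' flat in-band values (one AOI parked mid-parafoveal, the other between
#' the parafoveal and perifoveal thresholds). The construction satisfies
#' the corresponding detector's rule with a margin of at least
#' `2 * tolerance_px` against every threshold it touches, and triggers
#' none of the other three detectors.
#'
#' @param pattern One of `"glance"`, `"convergence"`, `"joint_excursion"`,
#'   `"disappearance"`.
#' @param params A [pattern_params()]; thresholds are read from its
#'   `field_spec`.
#' @param length Series length in fixations (>= the pattern's footprint + 2).
#' @param at Index at which the pattern's core is placed; default centred.
#' @return List with numeric vectors `a` and `b` (names are fixation ids)
#'   and the expected event span `span = c(start, end)` in indices.
#' @export
embed_pattern_series <- function(pattern = c("glance", "convergence",
                                             "joint_excursion", "disappearance"),
                                 params = pattern_params(), length = 10L,
                                 at = NULL) {
  pattern <- match.arg(pattern)
  fs <- params$field_spec
  tol <- params$tolerance_px
  base_a <- (fs$foveal_px + fs$parafoveal_px) / 2
  base_b <- (fs$parafoveal_px + fs$perifoveal_px) / 2
  footprint <- switch(pattern, glance = 3L, convergence = 3L,
                      joint_excursion = 3L, disappearance = 2L)
  if (length < footprint + 2L)
    stop("length must be >= ", footprint + 2L, " for pattern '", pattern, "'",
         call. = FALSE)
  if (is.null(at)) at <- max(2L, (length - footprint) %/% 2L + 1L)
  if (at < 2L || at + footprint - 1L > length - 1L)
    stop("pattern does not fit at index ", at, call. = FALSE)
  a <- rep(base_a, length); b <- rep(base_b, length)
  i <- at
  span <- switch(pattern,
    glance = {
      a[i + 1L] <- 0
      b[i + 1L] <- base_b + max(3 * tol, 15)
      c(i, i + 2L)
    },
    convergence = {
      a[i:(i + 2L)] <- c((fs$parafoveal_px + fs$perifoveal_px) / 2,
                         base_a, fs$foveal_px / 2)
      b[i:(i + 2L)] <- c(fs$perifoveal_px + 20, fs$parafoveal_px, 0)
      c(i, i + 2L)
    },
    joint_excursion = {
      a[i + 1L] <- fs$perifoveal_px + 70
      b[i + 1L] <- fs$perifoveal_px + 120
      c(i, i + 2L)
    },
    disappearance = {
      a[i:(i + 1L)] <- fs$near_peripheral_px * 1.25
      c(i - 1L, i + 1L)
    })
  names(a) <- names(b) <- seq_len(length)
  list(a = a, b = b, span = span, pattern = pattern)
}
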