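# Shared fixture builders. Everything is generated in code at test time.

# A 20 x 15 px camera with a 60 deg horizontal FOV: diagonal is exactly 25
# (a 4-3-5 triple scaled by 5), which keeps sentinel arithmetic readable.
tiny_camera <- function(fps = 10) camera_model(20L, 15L, 60, 46, fps)

# A small scene camera for pipeline tests.
small_camera <- function(fps = 30) camera_model(160L, 120L, 60, 46, fps)

# Wrap raw distance vectors into an ogd_series the metrics accept.
make_series <- function(ogd_px, aoi_label = "screw", sentinel = NULL,
                        camera = reference_camera(), fixation_id = NULL,
                        trial = NULL) {
  n <- length(ogd_px)
  if (is.null(sentinel)) sentinel <- ogd_px >= frame_diagonal_px(camera)
  df <- data.frame(fixation_id = fixation_id %||% seq_len(n),
                   aoi_label = aoi_label, ogd_px = ogd_px,
                   sentinel = sentinel, frame_index_used = 0L)
  if (!is.null(trial)) df$trial <- trial
  structure(df, camera = camera, class = c("ogd_series", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random sparse logical mask guaranteed non-empty.
rand_mask <- function(h, w, p = 0.15) {
  m <- matrix(stats::runif(h * w) < p, h, w)
  if (!any(m)) m[sample(h * w, 1L)] <- TRUE
  m
}

# Non-overlapping fixation table with one fixation per frame midpoint.
frame_fixations <- function(gaze, fps, t0 = 0) {
  # gaze: matrix with columns x, y; fixation i sits inside frame i-1
  n <- nrow(gaze)
  data.frame(fixation_id = seq_len(n),
             start_s = t0 + (seq_len(n) - 1) / fps + 0.1 / fps,
             duration_s = 0.5 / fps,
             gaze_x = gaze[, 1], gaze_y = gaze[, 2])
}

# A two-object static scene on the small camera: disk + rectangle.
two_object_spec <- function(n_frames = 6, n_fixations = 12, dropout = 0,
                            seed = 1, camera = small_camera(),
                            fixations = NULL) {
  scene_spec(
    camera = camera, n_frames = n_frames,
    objects = list(
      scene_object("screw", "disk", c(0.5 * camera$width_px,
                                      0.5 * camera$height_px),
                   radius = 0.075 * camera$width_px),
      scene_object("screwdriver", "rectangle",
                   c(0.25 * camera$width_px, 0.25 * camera$height_px),
                   width = 0.2 * camera$width_px,
                   height = 0.067 * camera$width_px)),
    dropout = dropout, fixations = fixations, n_fixations = n_fixations,
    seed = seed)
}
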