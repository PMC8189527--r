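#' Scene-camera model
#'
#' Describes the geometry of a head-mounted scene camera: pixel resolution,
#' horizontal/vertical field of view in degrees, and frame rate. The camera
#' model is the source of the pixels-per-degree scale used to convert
#' visual-angle diameters into pixel distance thresholds, and of the frame
#' diagonal used as the upper bound and undetected-AOI sentinel for the
#' object-gaze distance (OGD).
#'
#' @param width_px,height_px Scene frame resolution in pixels.
#' @param hfov_deg,vfov_deg Horizontal and vertical viewing angle in degrees.
#' @param fps Scene video frame rate in frames per second.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- camera_model(1280, 960, 60, 46, 60)
#' pixels_per_degree(cam)   # 21.33 px per degree
#' frame_diagonal_px(cam)   # 1600 px
#' @export
camera_model <- function(width_px, height_px, hfov_deg, vfov_deg, fps) {
  for (nm in c("width_px", "height_px", "hfov_deg", "vfov_deg", "fps")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("camera_model: '", nm, "' must be a single positive number", call. = FALSE)
  }
  if (width_px != round(width_px) || height_px != round(height_px))
    stop("camera_model: resolution must be integer pixels", call. = FALSE)
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         hfov_deg = as.numeric(hfov_deg), vfov_deg = as.numeric(vfov_deg),
         fps = as.numeric(fps)),
    class = "camera_model"
  )
}

#' The reference eye-tracker scene camera
#'
#' A 1280 x 960 px scene camera with a 60 degree horizontal and 46 degree
#' vertical viewing angle recording at 60 Hz. On this camera the frame
#' diagonal (and the undetected-AOI sentinel) is exactly 1600 px and the
#' near-peripheral 60 degree field maps to exactly 640 px.
#'
#' @return A `camera_model`.
#' @export
reference_camera <- function() camera_model(1280L, 960L, 60, 46, 60)

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Scene camera: %d x %d px, FOV %g x %g deg, %g fps\n",
              x$width_px, x$height_px, x$hfov_deg, x$vfov_deg, x$fps))
  cat(sprintf("  scale %.4g px/deg, frame diagonal %.6g px\n",
              pixels_per_degree(x), frame_diagonal_px(x)))
  invisible(x)
}

assert_camera <- function(camera) {
  if (!inherits(camera, "camera_model"))
    stop("expected a 'camera_model' object; see camera_model()", call. = FALSE)
  invisible(camera)
}

#' Pixels-per-degree scale of a camera
#'
#' The ratio between the horizontal scene resolution and the horizontal
#' viewing angle. The horizontal axis is the reference scale for all
#' degree-to-pixel conversions; the vertical field of view is retained for
#' validation only.
#'
#' @param camera A [camera_model()].
#' @return Scale in pixels per degree.
#' @export
pixels_per_degree <- function(camera) {
  assert_camera(camera)
  camera$width_px / camera$hfov_deg
}

#' Convert a visual-angle diameter to an OGD pixel threshold
#'
#' Fields of vision are specified as diameters of visual angle centred on
#' the gaze point; the OGD is a radial distance from the gaze point, so the
#' conversion halves the diameter before applying the camera's
#' pixels-per-degree scale. On the reference camera a 60 degree diameter
#' maps to exactly 640 px.
#'
#' @param camera A [camera_model()].
#' @param diameter_deg Visual-angle diameter in degrees (vectorised, >= 0).
#' @return Threshold distance(s) in pixels.
#' @export
deg_diameter_to_px <- function(camera, diameter_deg) {
  assert_camera(camera)
  if (!is.numeric(diameter_deg) || any(!is.finite(diameter_deg)) || any(diameter_deg < 0))
    stop("deg_diameter_to_px: diameter_deg must be non-negative", call. = FALSE)
  (diameter_deg / 2) * pixels_per_degree(camera)
}

#' Frame diagonal in pixels
#'
#' The length of the scene frame's diagonal, `sqrt(width^2 + height^2)`.
#' This is the upper bound of the OGD and the sentinel value assigned when
#' an AOI is not detected in a frame (1600 px on the reference camera).
#'
#' @param camera A [camera_model()].
#' @return Diagonal length in pixels.
#' @export
frame_diagonal_px <- function(camera) {
  assert_camera(camera)
  sqrt(camera$width_px^2 + camera$height_px^2)
}

#' Visual-field pixel thresholds
#'
#' Bundles the pixel-distance thresholds delimiting the concentric fields
#' of vision around the gaze point: foveal (2 degree diameter), parafoveal
#' (9 degrees), perifoveal (18 degrees) and near-peripheral (60 degrees,
#' the maximum measurable viewing angle of the reference device).
#'
#' @param foveal_px,parafoveal_px,perifoveal_px,near_peripheral_px
#'   Strictly increasing pixel thresholds.
#' @param source How the thresholds were obtained: `"table_defaults"`
#'   (the published rounded values) or `"derived_from_camera"`.
#' @return An object of class `vision_field_spec`.
#' @seealso [default_field_spec()], [classify_vision_field()]
#' @export
vision_field_spec <- function(foveal_px, parafoveal_px, perifoveal_px,
                              near_peripheral_px,
                              source = c("derived_from_camera", "table_defaults")) {
  source <- match.arg(source)
  th <- c(foveal_px, parafoveal_px, perifoveal_px, near_peripheral_px)
  if (!is.numeric(th) || length(th) != 4L || any(!is.finite(th)))
    stop("vision_field_spec: thresholds must be finite numbers", call. = FALSE)
  if (!(0 < th[1] && all(diff(th) > 0)))
    stop("vision_field_spec: thresholds must satisfy 0 < foveal < parafoveal < perifoveal < near_peripheral",
         call. = FALSE)
  structure(
    list(foveal_px = th[1], parafoveal_px = th[2], perifoveal_px = th[3],
         near_peripheral_px = th[4], source = source),
    class = "vision_field_spec"
  )
}

#' @export
print.vision_field_spec <- function(x, ...) {
  cat(sprintf("Vision-field thresholds (%s):\n", x$source))
  cat(sprintf("  foveal < %g px | parafoveal < %g px | perifoveal < %g px | near-peripheral < %g px\n",
              x$foveal_px, x$parafoveal_px, x$perifoveal_px, x$near_peripheral_px))
  invisible(x)
}

#' Default visual-field thresholds for a camera
#'
#' In `"table_defaults"` mode the published rounded thresholds
#' 20 / 90 / 180 / 640 px are returned; these are specific to the
#' reference camera (1280 x 960 px, 60 degree horizontal FOV) and
#' requesting them for any other camera is an error. In
#' `"derived_from_camera"` mode the exact (unrounded) conversion of the
#' 2 / 9 / 18 / 60 degree diameters is used, which works for any camera.
#'
#' @param camera A [camera_model()].
#' @param mode `"table_defaults"` or `"derived_from_camera"`.
#' @return A [vision_field_spec()].
#' @export
default_field_spec <- function(camera,
                               mode = c("table_defaults", "derived_from_camera")) {
  assert_camera(camera)
  mode <- match.arg(mode)
  if (mode == "table_defaults") {
    ref <- reference_camera()
    if (camera$width_px != ref$width_px || camera$height_px != ref$height_px ||
        camera$hfov_deg != ref$hfov_deg)
      stop("table_defaults thresholds (20/90/180/640 px) are defined only for the ",
           "1280x960 px / 60 deg reference camera; use mode = 'derived_from_camera'",
           call. = FALSE)
    vision_field_spec(20, 90, 180, 640, source = "table_defaults")
  } else {
    th <- deg_diameter_to_px(camera, c(2, 9, 18, 60))
    vision_field_spec(th[1], th[2], th[3], th[4], source = "derived_from_camera")
  }
}

#' Field-of-vision band names
#' @return Character vector of the six band labels in order of increasing
#'   eccentricity, ending with `"outside"` and `"undetected"`.
#' @export
vision_bands <- function() {
  c("foveal", "parafoveal", "perifoveal", "near_peripheral", "outside", "undetected")
}

#' Classify distances into fields of vision
#'
#' Assigns each OGD value to a concentric visual-field band around the gaze
#' point. Bands are half-open `[lo, hi)` intervals: a distance of 0 px (an
#' AOI Hit) is foveal; distances at or beyond the near-peripheral threshold
#' are `"outside"`. Records flagged as sentinel (the AOI was not detected in
#' the frame) are classified `"undetected"` regardless of their stored value.
#'
#' @param distance_px Numeric vector of distances in pixels (>= 0).
#' @param spec A [vision_field_spec()].
#' @param sentinel Logical vector (recycled) flagging undetected records.
#' @return A factor with levels [vision_bands()].
#' @export
classify_vision_field <- function(distance_px, spec, sentinel = FALSE) {
  if (!inherits(spec, "vision_field_spec"))
    stop("spec must be a 'vision_field_spec'", call. = FALSE)
  if (!is.numeric(distance_px) || any(!is.finite(distance_px)) || any(distance_px < 0))
    stop("classify_vision_field: distances must be finite and non-negative", call. = FALSE)
  sentinel <- rep_len(as.logical(sentinel), length(distance_px))
  cuts <- c(-Inf, spec$foveal_px, spec$parafoveal_px, spec$perifoveal_px,
            spec$near_peripheral_px, Inf)
  band <- cut(distance_px, breaks = cuts, right = FALSE,
              labels = vision_bands()[1:5])
  band <- factor(as.character(band), levels = vision_bands())
  band[sentinel] <- "undetected"
  band
}
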