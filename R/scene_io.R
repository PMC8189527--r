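## Readers and writers for fixation tables, mask streams and OGD output.
##
## Coordinate convention used throughout the package: 0-based pixel indices,
## origin at the top-left corner, x rightward, y downward. Gaze coordinates
## are continuous (sub-pixel) floats in the same units, with integer
## coordinates falling on pixel centers: gaze (0, 0) is the center of the
## top-left pixel. A mask is a logical matrix of dim (height_px, width_px),
## so pixel (x, y) is mask[y + 1, x + 1].

FIXATION_COLS <- c("fixation_id", "start_s", "duration_s", "gaze_x", "gaze_y")

#' Validate a fixation table
#'
#' Checks a data frame of fixation events (one row per fixation: id, start
#' time, duration, scene-camera gaze coordinates), sorts it by start time
#' (with a warning if the input was unsorted), and rejects temporally
#' overlapping fixations. Gaze points outside the frame bounds are kept and
#' flagged in an `in_frame` column, never clamped: clamping would fabricate
#' geometry.
#'
#' @param df Data frame with columns `fixation_id`, `start_s`, `duration_s`,
#'   `gaze_x`, `gaze_y`. Extra columns (e.g. `trial`) are preserved.
#' @param camera Optional [camera_model()]; when given, the `in_frame` flag
#'   is computed against its resolution.
#' @return The validated, time-sorted data frame.
#' @export
as_fixations <- function(df, camera = NULL) {
  df <- as.data.frame(df)
  missing <- setdiff(FIXATION_COLS, names(df))
  if (length(missing))
    stop("fixation table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  for (col in c("start_s", "duration_s", "gaze_x", "gaze_y"))
    if (!is.numeric(df[[col]]))
      stop("fixation column '", col, "' must be numeric", call. = FALSE)
  if (any(df$duration_s <= 0))
    stop("fixation durations must be positive", call. = FALSE)
  if (any(df$start_s < 0))
    stop("fixation start times must be non-negative", call. = FALSE)
  if (anyDuplicated(df$fixation_id))
    stop("duplicate fixation_id values", call. = FALSE)
  if (is.unsorted(df$start_s)) {
    warning("fixations were not sorted by start time; sorting", call. = FALSE)
    df <- df[order(df$start_s), , drop = FALSE]
  }
  ends <- df$start_s + df$duration_s
  n <- nrow(df)
  if (n > 1L) {
    bad <- which(df$start_s[-1] < ends[-n] - 1e-9)
    if (length(bad))
      stop("overlapping fixations: id ", df$fixation_id[bad[1]], " overlaps id ",
           df$fixation_id[bad[1] + 1L], call. = FALSE)
  }
  if (!is.null(camera)) {
    assert_camera(camera)
    df$in_frame <- df$gaze_x >= -0.5 & df$gaze_x < camera$width_px - 0.5 &
      df$gaze_y >= -0.5 & df$gaze_y < camera$height_px - 0.5
    if (any(!df$in_frame))
      warning(sum(!df$in_frame), " gaze point(s) outside the frame bounds; ",
              "kept and flagged in 'in_frame'", call. = FALSE)
  }
  rownames(df) <- NULL
  df
}

#' Read a fixation table from CSV
#'
#' @param path CSV file with a header row containing at least the columns
#'   `fixation_id`, `start_s`, `duration_s`, `gaze_x`, `gaze_y` (any order).
#' @inheritParams as_fixations
#' @return A validated fixation data frame (see [as_fixations()]).
#' @export
read_fixations <- function(path, camera = NULL) {
  if (!file.exists(path)) stop("fixation file not found: ", path, call. = FALSE)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  as_fixations(df, camera = camera)
}

#' Write a fixation table to CSV
#' @param fixations A fixation data frame.
#' @param path Output CSV path.
#' @export
write_fixations <- function(fixations, path) {
  data.table::fwrite(as.data.frame(fixations), path)
  invisible(path)
}

#' One frame's AOI segmentation
#'
#' @param frame_index 0-based video frame index.
#' @param masks Named list mapping AOI label to a list of binary instance
#'   masks (logical matrices of dim height x width). A label absent from
#'   the list means the AOI was not detected in this frame.
#' @return An object of class `frame_segmentation`.
#' @export
frame_segmentation <- function(frame_index, masks = list()) {
  if (length(masks)) {
    if (is.null(names(masks)) || any(!nzchar(names(masks))))
      stop("masks must be a named list keyed by AOI label", call. = FALSE)
    for (lab in names(masks)) {
      inst <- masks[[lab]]
      if (is.matrix(inst)) inst <- list(inst)
      ok <- vapply(inst, function(m) is.matrix(m) && is.logical(m), logical(1))
      if (!all(ok))
        stop("masks for AOI '", lab, "' must be logical matrices", call. = FALSE)
      masks[[lab]] <- inst
    }
  }
  structure(list(frame_index = as.integer(frame_index), masks = masks),
            class = "frame_segmentation")
}

mask_dims_ok <- function(frames, camera) {
  for (fr in frames)
    for (inst in fr$masks)
      for (m in inst)
        if (nrow(m) != camera$height_px || ncol(m) != camera$width_px)
          stop("mask dimensions ", nrow(m), "x", ncol(m), " do not match camera ",
               camera$height_px, "x", camera$width_px, " (frame ", fr$frame_index,
               ")", call. = FALSE)
  invisible(TRUE)
}

#' Bundle a trial's inputs
#'
#' Groups the camera, the fixation table and the per-frame segmentations of
#' one recording into a single object consumed by [compute_ogd_series()].
#'
#' @param camera A [camera_model()].
#' @param fixations A fixation table (validated via [as_fixations()]).
#' @param frames List of [frame_segmentation()] with contiguous indices
#'   starting at 0.
#' @param aoi_labels Character vector of AOI labels; defaults to the union
#'   of labels seen in `frames`.
#' @return An object of class `trial_bundle`.
#' @export
trial_bundle <- function(camera, fixations, frames, aoi_labels = NULL) {
  assert_camera(camera)
  fixations <- as_fixations(fixations, camera = camera)
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  if (length(idx) == 0L) stop("trial_bundle: no frames", call. = FALSE)
  if (!identical(idx, seq_along(idx) - 1L))
    stop("frame indices must be contiguous from 0", call. = FALSE)
  mask_dims_ok(frames, camera)
  seen <- unique(unlist(lapply(frames, function(f) names(f$masks))))
  if (is.null(aoi_labels)) aoi_labels <- sort(seen %||% character())
  aoi_labels <- as.character(aoi_labels)
  n_frames <- length(frames)
  spans <- lapply(seq_len(nrow(fixations)), function(i)
    fixation_frame(fixations[i, ], camera, policy = "all_frames",
                   n_frames = NULL))
  out_of_range <- vapply(spans, function(s) min(s) < 0 || max(s) >= n_frames,
                         logical(1))
  if (any(out_of_range))
    stop("fixation(s) outside the frame range: id ",
         paste(fixations$fixation_id[out_of_range], collapse = ", "),
         call. = FALSE)
  structure(list(camera = camera, fixations = fixations, frames = frames,
                 aoi_labels = aoi_labels),
            class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf("Trial bundle: %d fixations, %d frames, AOIs: %s\n",
              nrow(x$fixations), length(x$frames),
              paste(x$aoi_labels, collapse = ", ")))
  print(x$camera)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- label PNG masks ------------------------------------------------------

frame_png_name <- function(frame_index) sprintf("frame_%06d.png", frame_index)

#' Read per-frame AOI masks from 8-bit label PNGs
#'
#' Each frame is one single-channel PNG whose pixel values are integer
#' labels (0 = background); a JSON label map associates values with AOI
#' names. A value absent from a frame means the AOI was not detected in
#' that frame.
#'
#' @param dir Directory of `frame_NNNNNN.png` files (any name containing
#'   the 0-based frame index as its only integer works).
#' @param labelmap Path to a JSON object mapping pixel value to AOI label,
#'   e.g. `{"1": "screw", "2": "screwdriver"}`, or an equivalent named
#'   list / character vector.
#' @param camera A [camera_model()]; mask dimensions must match.
#' @return List of [frame_segmentation()] ordered by frame index.
#' @export
read_label_png_masks <- function(dir, labelmap, camera) {
  assert_camera(camera)
  if (!dir.exists(dir)) stop("mask directory not found: ", dir, call. = FALSE)
  lm <- read_labelmap(labelmap)
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (!length(files)) stop("no PNG files in ", dir, call. = FALSE)
  idx <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
  if (any(is.na(idx)))
    stop("cannot parse frame index from file name(s): ",
         paste(basename(files)[is.na(idx)], collapse = ", "), call. = FALSE)
  files <- files[order(idx)]
  idx <- sort(idx)
  lapply(seq_along(files), function(i) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    vals <- matrix(as.integer(round(img * 255)), nrow = nrow(img))
    if (nrow(vals) != camera$height_px || ncol(vals) != camera$width_px)
      stop("PNG ", basename(files[i]), " is ", nrow(vals), "x", ncol(vals),
           ", camera expects ", camera$height_px, "x", camera$width_px,
           call. = FALSE)
    present <- setdiff(unique(as.vector(vals)), 0L)
    unknown <- setdiff(present, as.integer(names(lm)))
    if (length(unknown))
      stop("PNG ", basename(files[i]), " contains pixel value(s) not in the ",
           "label map: ", paste(unknown, collapse = ", "), call. = FALSE)
    masks <- list()
    for (v in present) masks[[lm[[as.character(v)]]]] <- list(vals == v)
    frame_segmentation(idx[i], masks)
  })
}

read_labelmap <- function(labelmap) {
  if (is.character(labelmap) && length(labelmap) == 1L && file.exists(labelmap))
    labelmap <- jsonlite::read_json(labelmap, simplifyVector = TRUE)
  lm <- as.list(labelmap)
  if (is.null(names(lm)) || any(is.na(suppressWarnings(as.integer(names(lm))))))
    stop("label map must be keyed by integer pixel values", call. = FALSE)
  lapply(lm, as.character)
}

#' Write per-frame AOI masks as 8-bit label PNGs
#'
#' Inverse of [read_label_png_masks()]. Multiple instances of one label are
#' merged (a label PNG cannot encode instances separately); overlapping
#' AOIs are written in label-map order, later labels overwriting earlier
#' ones.
#'
#' @param frames List of [frame_segmentation()].
#' @param dir Output directory (created if absent).
#' @param labelmap Named list / vector mapping pixel value to AOI label; a
#'   `labelmap.json` is written alongside the frames.
#' @param camera Optional [camera_model()] supplying frame dimensions for
#'   all-background frames; otherwise dimensions are taken from any mask.
#' @return `dir`, invisibly.
#' @export
write_label_png_masks <- function(frames, dir, labelmap, camera = NULL) {
  lm <- read_labelmap(labelmap)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  label_of <- stats::setNames(names(lm), unlist(lm))
  default_dims <- if (!is.null(camera)) c(camera$height_px, camera$width_px)
  for (fr in frames) {
    dims <- default_dims
    for (inst in fr$masks) for (m in inst) dims <- dim(m)
    if (is.null(dims))
      stop("cannot write an all-background frame without knowing dimensions; ",
           "pass the camera", call. = FALSE)
    vals <- matrix(0L, dims[1], dims[2])
    for (lab in names(fr$masks)) {
      v <- label_of[[lab]]
      if (is.null(v)) stop("AOI '", lab, "' missing from label map", call. = FALSE)
      for (m in fr$masks[[lab]]) vals[m] <- as.integer(v)
    }
    png::writePNG(vals / 255, file.path(dir, frame_png_name(fr$frame_index)))
  }
  jsonlite::write_json(lm, file.path(dir, "labelmap.json"), auto_unbox = TRUE)
  invisible(dir)
}

## ---- COCO-style JSON ------------------------------------------------------

#' Read per-frame AOI masks from COCO-style JSON annotations
#'
#' Supports polygon segmentations (lists of flattened x,y rings, even-odd
#' fill rule, a pixel counted when its center lies inside) and uncompressed
#' run-length encodings (`counts` as an integer vector, column-major,
#' starting with the background run). Compressed (string) RLE is not
#' supported. The frame index of each image is taken from an optional
#' `frame_index` field, falling back to the image `id`.
#'
#' Multiple annotations sharing a category in one frame become multiple
#' instances under one AOI label.
#'
#' @param path JSON file with `images`, `annotations` and `categories`.
#' @param camera A [camera_model()]; masks are rasterized at its resolution.
#' @param n_frames Total number of frames; defaults to max frame index + 1.
#' @return List of [frame_segmentation()], one per frame index 0..n-1
#'   (frames without annotations get empty mask maps).
#' @export
read_coco_segmentations <- function(path, camera, n_frames = NULL) {
  assert_camera(camera)
  if (!file.exists(path)) stop("COCO file not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  images <- doc$images %||% list()
  anns <- doc$annotations %||% list()
  cats <- doc$categories %||% list()
  cat_name <- list()
  for (ct in cats) cat_name[[as.character(ct$id)]] <- ct$name
  img_frame <- list()
  for (im in images)
    img_frame[[as.character(im$id)]] <- as.integer(im$frame_index %||% im$id)
  max_idx <- max(c(-1L, unlist(img_frame)))
  if (is.null(n_frames)) n_frames <- max_idx + 1L
  frames <- lapply(seq_len(n_frames) - 1L, function(i) frame_segmentation(i))
  for (an in anns) {
    fi <- img_frame[[as.character(an$image_id)]] %||%
      as.integer(an$image_id)
    lab <- cat_name[[as.character(an$category_id)]] %||%
      as.character(an$category_id)
    m <- rasterize_segmentation(an$segmentation, camera)
    frames[[fi + 1L]]$masks[[lab]] <-
      c(frames[[fi + 1L]]$masks[[lab]], list(m))
  }
  frames
}

rasterize_segmentation <- function(seg, camera) {
  h <- camera$height_px; w <- camera$width_px
  if (is.list(seg) && !is.null(seg$counts)) {
    counts <- unlist(seg$counts)
    if (is.character(counts))
      stop("unsupported segmentation encoding: compressed (string) RLE; ",
           "use polygons or uncompressed integer counts", call. = FALSE)
    size <- unlist(seg$size)
    if (size[1] != h || size[2] != w)
      stop("RLE size ", size[1], "x", size[2], " does not match camera ",
           h, "x", w, call. = FALSE)
    vals <- rep(rep(c(FALSE, TRUE), length.out = length(counts)), counts)
    if (length(vals) != h * w)
      stop("RLE counts sum to ", length(vals), ", expected ", h * w, call. = FALSE)
    return(matrix(vals, nrow = h, ncol = w))  # COCO RLE is column-major
  }
  if (is.list(seg) || is.numeric(seg)) {
    rings <- if (is.numeric(seg)) list(seg) else lapply(seg, unlist)
    if (!all(vapply(rings, is.numeric, logical(1))))
      stop("unsupported segmentation encoding: expected polygon lists or ",
           "uncompressed RLE", call. = FALSE)
    return(rasterize_polygons(rings, w, h))
  }
  stop("unsupported segmentation encoding: ", class(seg)[1], call. = FALSE)
}

## Even-odd scanline fill over all rings. COCO polygons live in continuous
## image coordinates where pixel (col, row) spans [col, col+1) x [row, row+1);
## a pixel is set when its center (col + 0.5, row + 0.5) is inside an odd
## number of ring crossings.
rasterize_polygons <- function(rings, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  edges <- do.call(rbind, lapply(rings, function(ring) {
    if (length(ring) < 6 || length(ring) %% 2 != 0)
      stop("polygon ring must have >= 3 (x, y) vertex pairs", call. = FALSE)
    xs <- ring[seq(1, length(ring), 2)]
    ys <- ring[seq(2, length(ring), 2)]
    n <- length(xs)
    cbind(x0 = xs, y0 = ys, x1 = xs[c(2:n, 1)], y1 = ys[c(2:n, 1)])
  }))
  ymin <- max(0L, floor(min(edges[, c("y0", "y1")])))
  ymax <- min(height - 1L, ceiling(max(edges[, c("y0", "y1")])))
  if (ymax < ymin) return(mask)
  for (row in ymin:ymax) {
    yc <- row + 0.5
    sel <- (edges[, "y0"] <= yc & edges[, "y1"] > yc) |
           (edges[, "y1"] <= yc & edges[, "y0"] > yc)
    if (!any(sel)) next
    e <- edges[sel, , drop = FALSE]
    xcross <- e[, "x0"] + (yc - e[, "y0"]) / (e[, "y1"] - e[, "y0"]) *
      (e[, "x1"] - e[, "x0"])
    xcross <- sort(xcross)
    for (k in seq(1, length(xcross) - 1, by = 2)) {
      lo <- ceiling(xcross[k] - 0.5)       # first col with center > xcross[k]
      hi <- floor(xcross[k + 1] - 0.5 + 1e-12)
      lo <- max(lo, 0L); hi <- min(hi, width - 1L)
      if (hi >= lo) mask[row + 1L, (lo:hi) + 1L] <- TRUE
    }
  }
  mask
}

#' Write per-frame AOI masks as COCO-style JSON (uncompressed RLE)
#'
#' @param frames List of [frame_segmentation()].
#' @param path Output JSON path.
#' @param camera A [camera_model()].
#' @return `path`, invisibly.
#' @export
write_coco_segmentations <- function(frames, path, camera) {
  assert_camera(camera)
  labels <- sort(unique(unlist(lapply(frames, function(f) names(f$masks)))))
  cats <- lapply(seq_along(labels), function(i)
    list(id = i, name = labels[i]))
  images <- lapply(frames, function(f)
    list(id = f$frame_index, frame_index = f$frame_index,
         width = camera$width_px, height = camera$height_px))
  anns <- list(); aid <- 0L
  for (f in frames) {
    for (lab in names(f$masks)) {
      for (m in f$masks[[lab]]) {
        aid <- aid + 1L
        anns[[aid]] <- list(
          id = aid, image_id = f$frame_index,
          category_id = match(lab, labels),
          segmentation = list(counts = mask_to_rle_counts(m),
                              size = c(nrow(m), ncol(m))))
      }
    }
  }
  jsonlite::write_json(
    list(images = images, annotations = anns, categories = cats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

mask_to_rle_counts <- function(mask) {
  v <- as.vector(mask)  # column-major
  r <- rle(v)
  counts <- r$lengths
  if (length(v) && v[1]) counts <- c(0L, counts)  # RLE starts with a 0-run
  as.integer(counts)
}

## ---- camera / run config --------------------------------------------------

#' Read a camera configuration from YAML or JSON
#'
#' @param path File with keys `width_px`, `height_px`, `hfov_deg`,
#'   `vfov_deg`, `fps`.
#' @return A [camera_model()].
#' @export
read_camera_config <- function(path) {
  if (!file.exists(path)) stop("camera config not found: ", path, call. = FALSE)
  cfg <- read_config_file(path)
  need <- c("width_px", "height_px", "hfov_deg", "vfov_deg", "fps")
  missing <- setdiff(need, names(cfg))
  if (length(missing))
    stop("camera config ", path, " is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  camera_model(cfg$width_px, cfg$height_px, cfg$hfov_deg, cfg$vfov_deg, cfg$fps)
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

## ---- OGD series I/O -------------------------------------------------------

#' Write an OGD series to CSV
#'
#' Long-format table with one row per fixation x AOI:
#' `fixation_id, aoi_label, ogd_px, sentinel_flag, vision_band,
#' frame_index_used`. Numeric values round-trip losslessly through
#' [read_ogd_series()].
#'
#' @param series An `ogd_series` (see [compute_ogd_series()]).
#' @param path Output CSV path.
#' @param spec Optional [vision_field_spec()] used to fill the
#'   `vision_band` column; defaults to [default_field_spec()] of the
#'   series' camera in `derived_from_camera` mode.
#' @return `path`, invisibly.
#' @export
write_ogd_series <- function(series, path, spec = NULL) {
  stopifnot(inherits(series, "ogd_series"))
  if (is.null(spec))
    spec <- default_field_spec(attr(series, "camera"), "derived_from_camera")
  out <- data.frame(
    fixation_id = series$fixation_id,
    aoi_label = series$aoi_label,
    ogd_px = series$ogd_px,
    sentinel_flag = series$sentinel,
    vision_band = as.character(
      classify_vision_field(series$ogd_px, spec, series$sentinel)),
    frame_index_used = series$frame_index_used)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read an OGD series from CSV
#'
#' @param path CSV written by [write_ogd_series()].
#' @param camera The [camera_model()] the series was computed under.
#' @return An `ogd_series` data frame.
#' @export
read_ogd_series <- function(path, camera) {
  assert_camera(camera)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  need <- c("fixation_id", "aoi_label", "ogd_px", "sentinel_flag")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("OGD series file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  names(df)[names(df) == "sentinel_flag"] <- "sentinel"
  if (is.null(df$frame_index_used)) df$frame_index_used <- NA_integer_
  new_ogd_series(df[, c("fixation_id", "aoi_label", "ogd_px", "sentinel",
                        "frame_index_used")], camera)
}
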