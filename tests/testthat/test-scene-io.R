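test_that("fixation reader is header-driven, sorted, and conserves rows", {
  tf <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(fixation_id = 1:4, start_s = c(0, 0.5, 1.2, 2),
                   duration_s = c(0.4, 0.6, 0.7, 0.3),
                   gaze_x = c(10, 20, 30, 40), gaze_y = c(5, 6, 7, 8))
  write.csv(df, tf, row.names = FALSE)
  got <- read_fixations(tf)
  expect_equal(nrow(got), 4L)
  expect_equal(got$gaze_x, df$gaze_x)

  # shuffled columns give the same result
  tf2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, c("gaze_y", "start_s", "fixation_id", "duration_s", "gaze_x")],
            tf2, row.names = FALSE)
  expect_equal(read_fixations(tf2)[names(got)], got)

  # missing column named in the error
  tf3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[, -4], tf3, row.names = FALSE)
  expect_error(read_fixations(tf3), "gaze_x")
})

test_that("unsorted fixations are sorted with a warning; overlaps are fatal", {
  df <- data.frame(fixation_id = c(2L, 1L), start_s = c(1, 0),
                   duration_s = c(0.5, 0.5), gaze_x = 1, gaze_y = 1)
  expect_warning(got <- as_fixations(df), "sort")
  expect_equal(got$fixation_id, c(1L, 2L))

  ov <- data.frame(fixation_id = 1:3, start_s = c(0, 1, 1.3),
                   duration_s = c(0.5, 0.5, 0.5), gaze_x = 1, gaze_y = 1)
  ov$duration_s[2] <- 0.9  # row 2 runs into row 3
  expect_error(as_fixations(ov), "id 2 overlaps id 3")
})

test_that("out-of-frame gaze points are flagged, not clamped", {
  cam <- tiny_camera()
  df <- data.frame(fixation_id = 1:2, start_s = c(0, 1), duration_s = 0.5,
                   gaze_x = c(5, 40), gaze_y = c(5, 5))
  expect_warning(got <- as_fixations(df, camera = cam), "outside")
  expect_equal(got$in_frame, c(TRUE, FALSE))
  expect_equal(got$gaze_x[2], 40)  # untouched
})

test_that("label PNG masks round-trip and validate values and sizes", {
  cam <- tiny_camera()
  dir <- withr::local_tempdir()
  m1 <- matrix(FALSE, 15, 20); m1[3:5, 3:6] <- TRUE
  m2 <- matrix(FALSE, 15, 20); m2[10:12, 15:18] <- TRUE
  frames <- list(frame_segmentation(0L, list(screw = m1, screwdriver = m2)),
                 frame_segmentation(1L, list(screw = m1)))
  lm <- list(`1` = "screw", `2` = "screwdriver")
  write_label_png_masks(frames, dir, lm)
  got <- read_label_png_masks(dir, file.path(dir, "labelmap.json"), cam)
  expect_length(got, 2L)
  expect_equal(got[[1]]$masks$screw[[1]], m1)
  expect_equal(got[[1]]$masks$screwdriver[[1]], m2)
  expect_null(got[[2]]$masks$screwdriver)  # absent value => absent AOI

  # all-background frame reads as an empty mask map
  png::writePNG(matrix(0, 15, 20), file.path(dir, "frame_000001.png"))
  got2 <- read_label_png_masks(dir, file.path(dir, "labelmap.json"), cam)
  expect_length(got2[[2]]$masks, 0L)

  # unknown pixel value is listed in the error
  bad <- matrix(0, 15, 20); bad[1, 1] <- 7 / 255
  png::writePNG(bad, file.path(dir, "frame_000001.png"))
  expect_error(read_label_png_masks(dir, lm, cam), "7")

  # size mismatch with the camera is an error
  png::writePNG(matrix(0, 15, 20), file.path(dir, "frame_000001.png"))
  expect_error(read_label_png_masks(dir, lm, camera_model(30, 30, 60, 46, 10)),
               "camera expects")
})

test_that("COCO polygons rasterize by pixel-center containment", {
  cam <- tiny_camera()
  tf <- withr::local_tempfile(fileext = ".json")
  doc <- list(
    images = list(list(id = 0, frame_index = 0, width = 20, height = 15)),
    annotations = list(list(id = 1, image_id = 0, category_id = 1,
                            segmentation = list(c(0, 0, 10, 0, 10, 10, 0, 10)))),
    categories = list(list(id = 1, name = "screw")))
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  got <- read_coco_segmentations(tf, cam)
  m <- got[[1]]$masks$screw[[1]]
  expect_equal(sum(m), 100L)                     # 10 x 10 pixel centers inside
  expect_true(all(m[1:10, 1:10]))

  # empty annotation list -> empty mask maps for every frame
  doc$annotations <- list()
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  got <- read_coco_segmentations(tf, cam)
  expect_length(got[[1]]$masks, 0L)

  # two same-category polygons in one frame become two instances
  doc$annotations <- list(
    list(id = 1, image_id = 0, category_id = 1,
         segmentation = list(c(0, 0, 4, 0, 4, 4, 0, 4))),
    list(id = 2, image_id = 0, category_id = 1,
         segmentation = list(c(10, 10, 14, 10, 14, 14, 10, 14))))
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  got <- read_coco_segmentations(tf, cam)
  expect_length(got[[1]]$masks$screw, 2L)

  # compressed RLE is rejected by name
  doc$annotations <- list(list(id = 1, image_id = 0, category_id = 1,
                               segmentation = list(counts = "abc",
                                                   size = c(15, 20))))
  jsonlite::write_json(doc, tf, auto_unbox = TRUE)
  expect_error(read_coco_segmentations(tf, cam), "compressed")
})

test_that("PNG and COCO encodings of one scene read back identically", {
  spec <- two_object_spec(n_frames = 4, n_fixations = 6, dropout = 0.3, seed = 3)
  sc <- generate_scene(spec)
  cam <- spec$camera
  dir <- withr::local_tempdir()
  write_label_png_masks(sc$bundle$frames, dir,
                        list(`1` = "screw", `2` = "screwdriver"), camera = cam)
  from_png <- read_label_png_masks(dir, file.path(dir, "labelmap.json"), cam)
  tf <- withr::local_tempfile(fileext = ".json")
  write_coco_segmentations(sc$bundle$frames, tf, cam)
  from_coco <- read_coco_segmentations(tf, cam, n_frames = 4)
  for (k in 1:4) {
    labs <- sort(names(from_png[[k]]$masks))
    expect_equal(sort(names(from_coco[[k]]$masks)), labs)
    for (lab in labs)
      expect_equal(from_coco[[k]]$masks[[lab]][[1]],
                   from_png[[k]]$masks[[lab]][[1]])
  }
})

test_that("OGD series CSV holds the long-format schema and round-trips", {
  cam <- reference_camera()
  s <- make_series(c(0, 123.456789012345, 640, 1600),
                   aoi_label = rep(c("screw", "screwdriver"), 2),
                   sentinel = c(FALSE, FALSE, FALSE, TRUE),
                   fixation_id = c(1L, 1L, 2L, 2L), camera = cam)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_ogd_series(s, tf)
  txt <- read.csv(tf)
  expect_equal(nrow(txt), 4L)  # 2 fixations x 2 AOIs
  expect_true(all(c("fixation_id", "aoi_label", "ogd_px", "sentinel_flag",
                    "vision_band") %in% names(txt)))
  expect_equal(txt$sentinel_flag, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(txt$ogd_px[4], 1600)  # sentinel records sit at the diagonal
  back <- read_ogd_series(tf, cam)
  expect_identical(back$ogd_px, s$ogd_px)  # lossless numeric round-trip
  expect_identical(back$sentinel, s$sentinel)
})

test_that("trial bundle enforces contiguous frames and in-range fixations", {
  cam <- tiny_camera()
  m <- matrix(FALSE, 15, 20); m[5, 5] <- TRUE
  frames <- list(frame_segmentation(0L, list(a = m)),
                 frame_segmentation(1L, list(a = m)))
  fix <- data.frame(fixation_id = 1L, start_s = 0.01, duration_s = 0.05,
                    gaze_x = 5, gaze_y = 5)
  b <- trial_bundle(cam, fix, frames)
  expect_s3_class(b, "trial_bundle")
  expect_equal(b$aoi_labels, "a")

  late <- data.frame(fixation_id = 9L, start_s = 5, duration_s = 0.1,
                     gaze_x = 5, gaze_y = 5)
  expect_error(trial_bundle(cam, late, frames), "9")
  expect_error(trial_bundle(cam, fix, frames[2]), "contiguous")
})
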