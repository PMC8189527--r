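test_that("point-to-mask distance: containment, right triangles, validation", {
  m <- matrix(FALSE, 60, 60)
  m[51, 51] <- TRUE  # pixel (50, 50)
  expect_identical(min_distance_to_mask(50, 50, m), 0)

  m2 <- matrix(FALSE, 30, 30); m2[11, 11] <- TRUE  # pixel (10, 10)
  expect_identical(min_distance_to_mask(13, 14, m2), 5)  # 3-4-5 triangle

  expect_error(min_distance_to_mask(1, 1, matrix(FALSE, 5, 5)), "empty mask")
  expect_error(min_distance_to_mask(Inf, 1, m2), "finite")
})

test_that("fast distance equals the brute-force oracle on random masks", {
  set.seed(11)
  for (i in 1:60) {
    m <- rand_mask(sample(5:40, 1), sample(5:40, 1), runif(1, 0.02, 0.5))
    # integer gaze: exact agreement
    gi <- c(sample(0:(ncol(m) - 1), 1), sample(0:(nrow(m) - 1), 1))
    expect_identical(min_distance_to_mask(gi[1], gi[2], m),
                     brute_force_min_distance(gi[1], gi[2], m))
    # sub-pixel gaze (may fall outside the frame): within 1e-9
    gf <- c(runif(1, -5, ncol(m) + 5), runif(1, -5, nrow(m) + 5))
    expect_equal(min_distance_to_mask(gf[1], gf[2], m),
                 brute_force_min_distance(gf[1], gf[2], m), tolerance = 1e-9)
  }
})

test_that("distance is translation-equivariant and monotone under dilation", {
  set.seed(21)
  for (i in 1:20) {
    m <- matrix(FALSE, 40, 40)
    m[10:20, 12:22] <- rand_mask(11, 11, 0.3)
    g <- runif(2, 12, 25)
    d0 <- min_distance_to_mask(g[1], g[2], m)
    # integer translation of mask and gaze together
    dx <- sample(-5:5, 1); dy <- sample(-5:5, 1)
    mt <- matrix(FALSE, 40, 40)
    mt[(10:20) + dy, (12:22) + dx] <- m[10:20, 12:22]
    expect_equal(min_distance_to_mask(g[1] + dx, g[2] + dy, mt), d0)
    # 4-neighbourhood dilation never increases the distance
    md <- m
    md[-1, ] <- md[-1, ] | m[-nrow(m), ]
    md[-nrow(m), ] <- md[-nrow(m), ] | m[-1, ]
    md[, -1] <- md[, -1] | m[, -ncol(m)]
    md[, -ncol(m)] <- md[, -ncol(m)] | m[, -1]
    expect_lte(min_distance_to_mask(g[1], g[2], md), d0)
  }
})

test_that("fixations map to frames by midpoint or half-open span", {
  cam <- camera_model(100, 100, 60, 46, 60)
  fx <- list(fixation_id = 1L, start_s = 1.0, duration_s = 0.2)
  expect_identical(fixation_frame(fx, cam, "midpoint"), 66L)  # round(1.1 * 60)
  one <- list(fixation_id = 2L, start_s = 0, duration_s = 1 / 60)
  expect_identical(fixation_frame(one, cam, "all_frames"), 0L)
  span <- list(fixation_id = 3L, start_s = 0.5, duration_s = 0.1)
  expect_identical(fixation_frame(span, cam, "all_frames"), 30:35)
  expect_error(fixation_frame(fx, cam, "midpoint", n_frames = 10), "1")
})

test_that("per-fixation OGD: sentinel, hit, nearest instance, label check", {
  cam <- tiny_camera(fps = 10)
  m_far <- matrix(FALSE, 15, 20); m_far[11, 11] <- TRUE   # pixel (10, 10)
  m_near <- matrix(FALSE, 15, 20); m_near[3, 11] <- TRUE  # pixel (10, 2)
  frames <- list(
    frame_segmentation(0L, list(a = list(m_far, m_near), b = m_far)),
    frame_segmentation(1L, list(b = m_far)))

  fx0 <- data.frame(fixation_id = 1L, start_s = 0.01, duration_s = 0.04,
                    gaze_x = 10, gaze_y = 0)
  # two instances at distances 10 and 2: nearest instance wins
  rec <- ogd_for_fixation(fx0, frames, "a", cam)
  expect_equal(rec$ogd_px, 2)
  expect_false(rec$sentinel)

  # gaze inside the mask is a Hit
  hit <- ogd_for_fixation(data.frame(fixation_id = 2L, start_s = 0.01,
                                     duration_s = 0.04, gaze_x = 10, gaze_y = 10),
                          frames, "a", cam)
  expect_identical(hit$ogd_px, 0)

  # AOI absent in the midpoint frame -> sentinel at the frame diagonal (25)
  fx1 <- data.frame(fixation_id = 3L, start_s = 0.11, duration_s = 0.04,
                    gaze_x = 10, gaze_y = 0)
  sent <- ogd_for_fixation(fx1, frames, "a", cam)
  expect_identical(sent$ogd_px, 25)
  expect_true(sent$sentinel)

  expect_error(ogd_for_fixation(fx0, frames, "nope", cam), "known labels: a, b")
})

test_that("multi-frame aggregation mixes detected and sentinel frames", {
  cam <- tiny_camera(fps = 10)
  m <- matrix(FALSE, 15, 20); m[6, 6] <- TRUE  # pixel (5, 5)
  frames <- list(frame_segmentation(0L, list(a = m)),
                 frame_segmentation(1L),
                 frame_segmentation(2L, list(a = m)))
  fx <- data.frame(fixation_id = 1L, start_s = 0, duration_s = 0.3,
                   gaze_x = 5, gaze_y = 8)  # distance 3 when detected
  med <- ogd_for_fixation(fx, frames, "a", cam, policy = "all_frames",
                          aggregate = "median")
  expect_equal(med$ogd_px, 3)       # median of (3, 25, 3)
  expect_false(med$sentinel)        # detected in at least one frame
  mn <- ogd_for_fixation(fx, frames, "a", cam, policy = "all_frames",
                         aggregate = "mean")
  expect_equal(mn$ogd_px, (3 + 25 + 3) / 3)
  # absent everywhere -> sentinel
  empty <- list(frame_segmentation(0L), frame_segmentation(1L),
                frame_segmentation(2L))
  allgone <- ogd_for_fixation(fx, empty, "a", cam, policy = "all_frames",
                              known_labels = "a")
  expect_true(allgone$sentinel)
  expect_identical(allgone$ogd_px, 25)
})

test_that("series covers the full fixation x AOI grid with bounded values", {
  spec <- two_object_spec(n_frames = 5, n_fixations = 5, seed = 2)
  sc <- generate_scene(spec)
  s <- compute_ogd_series(sc$bundle)
  expect_equal(nrow(s), 5L * 2L)   # complete grid
  diag <- frame_diagonal_px(spec$camera)
  expect_true(all(s$ogd_px >= 0 & s$ogd_px <= diag))
  expect_true(all(s$ogd_px[s$sentinel] == diag))
  # ordered by fixation time then label
  expect_equal(s$fixation_id, rep(1:5, each = 2))
  expect_equal(unique(s$aoi_label), c("screw", "screwdriver"))
})

test_that("an all-dropout AOI is sentinel throughout, the other unaffected", {
  spec <- two_object_spec(n_frames = 5, n_fixations = 6, seed = 4,
                          dropout = c(screw = 1, screwdriver = 0))
  sc <- generate_scene(spec)
  s <- compute_ogd_series(sc$bundle)
  expect_true(all(s$sentinel[s$aoi_label == "screw"]))
  expect_false(any(s$sentinel[s$aoi_label == "screwdriver"]))
  base <- compute_ogd_series(generate_scene(
    two_object_spec(n_frames = 5, n_fixations = 6, seed = 4, dropout = 0))$bundle)
  expect_equal(s$ogd_px[s$aoi_label == "screwdriver"],
               base$ogd_px[base$aoi_label == "screwdriver"])
})
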