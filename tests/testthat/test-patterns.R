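params_default <- function() pattern_params()

test_that("glance: hit with opposite movement and a return", {
  p <- params_default()
  ev <- detect_glance(c(60, 0, 55), c(150, 210, 160), p)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$pattern, "glance")
  expect_equal(c(ev$start_idx, ev$end_idx), c(1L, 3L))
  expect_equal(ev$hit_aoi, "A")

  # flat series without zeros: nothing
  expect_equal(nrow(detect_glance(rep(60, 6), rep(150, 6), p)), 0L)
  # hit that never reverts is a sustained fixation, not a glance
  expect_equal(nrow(detect_glance(c(60, 0, 0), c(150, 210, 220), p)), 0L)
  # B barely moving (within tolerance) is not "opposite movement"
  expect_equal(nrow(detect_glance(c(60, 0, 55), c(150, 154, 150), p)), 0L)
  # misaligned series are rejected
  expect_error(detect_glance(c(1, 2), c(1, 2, 3), p), "aligned")
})

test_that("convergence: simultaneous decrease ending in exactly one hit", {
  p <- params_default()
  ev <- detect_convergence(c(120, 60, 10), c(200, 90, 0), p)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$hit_aoi, "B")
  expect_equal(c(ev$start_idx, ev$end_idx), c(1L, 3L))

  # both increasing: nothing
  expect_equal(nrow(detect_convergence(c(10, 60, 120), c(0, 90, 200), p)), 0L)
  # both end foveal but neither hits 0: the strict rule requires a Hit
  expect_equal(nrow(detect_convergence(c(120, 60, 10), c(200, 90, 5), p)), 0L)
  # simultaneous hits on both AOIs do not satisfy "exactly one"
  expect_equal(nrow(detect_convergence(c(120, 60, 0), c(200, 90, 0), p)), 0L)
})

test_that("joint excursion: both leave the perifoveal field and return", {
  p <- params_default()
  ev <- detect_joint_excursion(c(100, 250, 120), c(150, 300, 140), p)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start_idx, ev$end_idx), c(1L, 3L))

  # only one series rises: not a joint excursion
  expect_equal(nrow(detect_joint_excursion(c(100, 250, 120),
                                           c(150, 160, 140), p)), 0L)
  # rise without return before the series ends
  expect_equal(nrow(detect_joint_excursion(c(100, 250, 260),
                                           c(150, 300, 310), p)), 0L)
})

test_that("disappearance: one AOI beyond near-peripheral, the other close", {
  p <- params_default()
  ev <- detect_disappearance(c(100, 1600, 1600), c(90, 85, 80), p)
  expect_equal(nrow(ev), 1L)
  expect_equal(c(ev$start_idx, ev$end_idx), c(1L, 3L))
  expect_match(ev$notes, "A")

  # both gone: no "other stays close"
  expect_equal(nrow(detect_disappearance(c(100, 1600, 1600),
                                         c(90, 1600, 1600), p)), 0L)
  # the other AOI outside the perifoveal field: strict rule rejects
  expect_equal(nrow(detect_disappearance(c(100, 700, 700),
                                         c(300, 300, 300), p)), 0L)
})

test_that("each embedded pattern is recovered exactly once, no cross hits", {
  p <- params_default()
  detectors <- list(glance = detect_glance, convergence = detect_convergence,
                    joint_excursion = detect_joint_excursion,
                    disappearance = detect_disappearance)
  for (pat in names(detectors)) {
    for (len in c(6L, 9L, 14L)) {
      e <- embed_pattern_series(pat, p, length = len)
      own <- detectors[[pat]](e$a, e$b, p)
      expect_equal(nrow(own), 1L, info = paste(pat, len))
      expect_equal(c(own$start_idx, own$end_idx), e$span,
                   info = paste(pat, len))
      for (other in setdiff(names(detectors), pat)) {
        hits <- nrow(detectors[[other]](e$a, e$b, p)) +
          nrow(detectors[[other]](e$b, e$a, p))
        expect_equal(hits, 0L, info = paste(pat, "->", other, len))
      }
    }
  }
})

test_that("two concatenated embeds give two events; empty series give none", {
  p <- params_default()
  e <- embed_pattern_series("glance", p, length = 8)
  a2 <- c(e$a, e$a); b2 <- c(e$b, e$b)
  names(a2) <- names(b2) <- seq_along(a2)
  expect_equal(nrow(detect_glance(a2, b2, p)), 2L)
  res <- detect_all(list(A = a2, B = b2), p)
  expect_equal(res$summary$count[res$summary$pattern == "glance"], 2)
  expect_equal(res$summary$mean[res$summary$pattern == "glance"], 2)
  expect_equal(res$summary$sd[res$summary$pattern == "glance"], 0)
  expect_equal(nrow(detect_all(list(A = numeric(0), B = numeric(0)),
                               p)$events), 0L)
})

test_that("detect_all unions the four detectors over AOI pairs", {
  p <- params_default()
  offs <- c(glance = 0L, convergence = 10L, joint_excursion = 20L,
            disappearance = 30L)
  a <- rep(55, 40); b <- rep(135, 40)
  for (pat in names(offs)) {
    e <- embed_pattern_series(pat, p, length = 10)
    a[offs[[pat]] + 1:10] <- e$a
    b[offs[[pat]] + 1:10] <- e$b
  }
  names(a) <- names(b) <- seq_along(a)
  res <- detect_all(list(screw = a, screwdriver = b), p)
  expect_equal(sort(res$events$pattern),
               sort(c("glance", "convergence", "joint_excursion",
                      "disappearance")))
  expect_true(!is.unsorted(res$events$start_fix))
  expect_error(detect_all(list(A = a), p), "at least 2")
})

test_that("events of one detector never overlap for one AOI pair", {
  p <- params_default()
  set.seed(31)
  detectors <- list(detect_glance, detect_convergence,
                    detect_joint_excursion, detect_disappearance)
  for (i in 1:15) {
    n <- 60
    a <- runif(n, 0, 1600); b <- runif(n, 0, 1600)
    a[runif(n) < 0.15] <- 0
    for (det in detectors) {
      ev <- det(a, b, p)
      if (nrow(ev) > 1L) {
        ord <- ev[order(ev$start_idx), ]
        expect_true(all(ord$start_idx[-1] > ord$end_idx[-nrow(ord)]))
      }
      expect_true(all(ev$start_fix <= ev$end_fix))
    }
  }
})

test_that("detection is robust to sub-tolerance jitter on both series", {
  p <- params_default()
  set.seed(33)
  for (pat in c("glance", "convergence", "joint_excursion", "disappearance")) {
    e <- embed_pattern_series(pat, p, length = 12)
    for (rep_i in 1:5) {
      jit <- runif(1, 0, p$tolerance_px * 0.9)
      aj <- ifelse(e$a == 0, 0, e$a + jit)  # exact hits stay exact
      bj <- ifelse(e$b == 0, 0, e$b + jit)
      names(aj) <- names(bj) <- names(e$a)
      res <- detect_all(list(A = aj, B = bj), p)
      expect_equal(sum(res$events$pattern == pat), 1, info = pat)
    }
  }
})
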