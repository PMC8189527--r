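## Rule-based detection of multi-OGD gaze patterns. The four pattern shapes
## — glance, convergence, joint excursion, disappearance — are qualitative
## descriptions of how the paired distance curves of two AOIs move; the
## quantitative onset/offset rules below are this package's operational
## definitions, with every threshold exposed as a parameter. Pattern search
## runs on fixation-indexed series, not wall-clock time.

#' Parameters for multi-OGD pattern detection
#'
#' @param field_spec A [vision_field_spec()] supplying the foveal,
#'   perifoveal and near-peripheral thresholds the rules refer to.
#' @param min_len Minimum event length in fixations for the convergence
#'   rule (default 2).
#' @param tolerance_px Allowed counter-movement in pixels when a rule
#'   requires a monotone trend, and the minimum rise that counts as an
#'   increase (default 5; must stay below the foveal threshold).
#' @param return_window After a glance's AOI Hit, the number of fixations
#'   within which the gaze must revert (default 3).
#' @param return_tolerance_px How close (px) the reverted distance must be
#'   to its pre-Hit value to count as "a similar position as before"
#'   (default 30).
#' @return An object of class `pattern_params`.
#' @export
pattern_params <- function(field_spec = NULL, min_len = 2L, tolerance_px = 5,
                           return_window = 3L, return_tolerance_px = 30) {
  if (is.null(field_spec))
    field_spec <- default_field_spec(reference_camera(), "table_defaults")
  stopifnot(inherits(field_spec, "vision_field_spec"))
  if (min_len < 1 || tolerance_px <= 0 || return_window < 1 ||
      return_tolerance_px <= 0)
    stop("pattern parameters must be positive", call. = FALSE)
  if (tolerance_px >= field_spec$foveal_px)
    stop("tolerance_px must be smaller than the foveal threshold", call. = FALSE)
  structure(list(field_spec = field_spec, min_len = as.integer(min_len),
                 tolerance_px = tolerance_px,
                 return_window = as.integer(return_window),
                 return_tolerance_px = return_tolerance_px),
            class = "pattern_params")
}

## Internal: coerce a pattern series argument to a numeric vector with ids.
as_pattern_series <- function(x) {
  if (is.data.frame(x)) {
    ids <- x$fixation_id %||% seq_len(nrow(x))
    v <- x$ogd_px
  } else {
    v <- as.numeric(x)
    ids <- if (!is.null(names(x))) as.integer(names(x)) else seq_along(v)
  }
  list(v = v, ids = ids)
}

check_aligned <- function(a, b) {
  if (length(a$v) != length(b$v) || !identical(a$ids, b$ids))
    stop("series are not aligned: they must share the same fixation ids",
         call. = FALSE)
}

pattern_event <- function(pattern, a, start_idx, end_idx, aoi_a, aoi_b,
                          hit_aoi = NA_character_, notes = "") {
  df <- data.frame(pattern = pattern,
                   start_fix = unname(a$ids[start_idx]),
                   end_fix = unname(a$ids[end_idx]),
                   start_idx = unname(start_idx), end_idx = unname(end_idx),
                   aoi_a = aoi_a, aoi_b = aoi_b, hit_aoi = hit_aoi,
                   notes = notes, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

empty_events <- function() {
  data.frame(pattern = character(), start_fix = integer(), end_fix = integer(),
             start_idx = integer(), end_idx = integer(), aoi_a = character(),
             aoi_b = character(), hit_aoi = character(), notes = character(),
             stringsAsFactors = FALSE)
}

## Maximal runs of a logical vector, as a matrix of (start, end) indices.
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Detect glances (pattern: opposite movement with a brief Hit)
#'
#' A glance is a brief look at one object: the OGD of AOI A drops to 0 px
#' (an AOI Hit) for one or more fixations while the OGD of AOI B increases
#' by more than `tolerance_px` over the same fixations, and within
#' `return_window` fixations after the Hit the gaze reverts to within
#' `return_tolerance_px` of A's pre-Hit distance. A Hit that never reverts
#' (the gaze stays on the object) is a sustained fixation, not a glance.
#'
#' @param a,b Aligned OGD series of the two AOIs: numeric vectors, or data
#'   frames with `fixation_id` and `ogd_px`.
#' @param params A [pattern_params()].
#' @param aoi_a,aoi_b Labels used in the returned events.
#' @return A data frame of events (possibly empty): `pattern`, `start_fix`,
#'   `end_fix`, `start_idx`, `end_idx`, `aoi_a`, `aoi_b`, `hit_aoi`, `notes`.
#' @export
detect_glance <- function(a, b, params = pattern_params(),
                          aoi_a = "A", aoi_b = "B") {
  a <- as_pattern_series(a); b <- as_pattern_series(b)
  check_aligned(a, b)
  av <- a$v; bv <- b$v; n <- length(av)
  events <- empty_events()
  if (n < 3L || !any(av == 0)) return(events)
  runs <- logical_runs(av == 0)
  prev_end <- 0L
  for (r in seq_len(nrow(runs))) {
    r0 <- runs[r, "start"]; r1 <- runs[r, "end"]
    pre <- r0 - 1L
    if (pre < 1L || pre <= prev_end) next
    if (av[pre] == 0) next
    if (bv[r1] - bv[pre] <= params$tolerance_px) next       # B must move away
    post <- (r1 + 1L):min(n, r1 + params$return_window)
    if (r1 >= n) next                                        # never returns
    ok <- which(av[post] > 0 &
                  abs(av[post] - av[pre]) <= params$return_tolerance_px)
    if (!length(ok)) next
    j <- post[ok[1L]]
    events <- rbind(events,
                    pattern_event("glance", a, pre, j, aoi_a, aoi_b,
                                  hit_aoi = aoi_a))
    prev_end <- j
  }
  events
}

#' Detect convergences (pattern: simultaneous decrease to a Hit)
#'
#' Both OGDs decrease together (non-strict, allowing counter-movement up to
#' `tolerance_px` per step) over at least `min_len` fixations until both
#' lie inside the foveal field, with an AOI Hit (0 px) on exactly one of
#' the two AOIs at the end — the gaze has moved to the point of
#' interconnection between the objects.
#'
#' @inheritParams detect_glance
#' @return Event data frame; `hit_aoi` names the AOI that was hit.
#' @export
detect_convergence <- function(a, b, params = pattern_params(),
                               aoi_a = "A", aoi_b = "B") {
  a <- as_pattern_series(a); b <- as_pattern_series(b)
  check_aligned(a, b)
  av <- a$v; bv <- b$v; n <- length(av)
  fov <- params$field_spec$foveal_px; tol <- params$tolerance_px
  events <- empty_events()
  prev_end <- 0L
  k <- 2L
  while (k <= n) {
    one_hit <- xor(av[k] == 0, bv[k] == 0)
    both_foveal <- av[k] < fov && bv[k] < fov
    if (one_hit && both_foveal) {
      s <- k
      while (s - 1L > prev_end &&
             av[s] <= av[s - 1L] + tol && bv[s] <= bv[s - 1L] + tol)
        s <- s - 1L
      len <- k - s + 1L
      if (len >= params$min_len &&
          av[s] - av[k] > tol && bv[s] - bv[k] > tol) {
        hit <- if (av[k] == 0) aoi_a else aoi_b
        events <- rbind(events,
                        pattern_event("convergence", a, s, k, aoi_a, aoi_b,
                                      hit_aoi = hit))
        prev_end <- k
        k <- k + 1L
        ## skip the remainder of a sustained hit so one approach yields one event
        while (k <= n && (av[k] == 0 || bv[k] == 0)) k <- k + 1L
        next
      }
    }
    k <- k + 1L
  }
  events
}

#' Detect joint excursions (pattern: both OGDs leave and re-enter)
#'
#' Both OGDs start inside the perifoveal field, rise beyond it
#' simultaneously for one or more fixations, then both return inside it —
#' the gaze wanders away from both objects and comes back.
#'
#' @inheritParams detect_glance
#' @return Event data frame.
#' @export
detect_joint_excursion <- function(a, b, params = pattern_params(),
                                   aoi_a = "A", aoi_b = "B") {
  a <- as_pattern_series(a); b <- as_pattern_series(b)
  check_aligned(a, b)
  av <- a$v; bv <- b$v; n <- length(av)
  peri <- params$field_spec$perifoveal_px
  events <- empty_events()
  if (n < 3L) return(events)
  above <- av >= peri & bv >= peri
  if (!any(above)) return(events)
  runs <- logical_runs(above)
  prev_end <- 0L
  for (r in seq_len(nrow(runs))) {
    i <- runs[r, "start"]; j <- runs[r, "end"]
    if (i <= 1L || j >= n) next                    # needs start + return
    if (!(av[i - 1L] < peri && bv[i - 1L] < peri)) next
    if (!(av[j + 1L] < peri && bv[j + 1L] < peri)) next
    s <- max(i - 1L, prev_end + 1L)
    events <- rbind(events,
                    pattern_event("joint_excursion", a, s, j + 1L,
                                  aoi_a, aoi_b))
    prev_end <- j + 1L
  }
  events
}

#' Detect disappearances (pattern: one AOI leaves the field of view)
#'
#' One AOI's OGD rises to or beyond the near-peripheral threshold (which
#' includes the frame-diagonal sentinel of an undetected object) while the
#' other AOI stays inside the perifoveal field throughout — one object has
#' left the operator's field of view while the gaze remains close to the
#' other.
#'
#' @inheritParams detect_glance
#' @return Event data frame; `notes` names the disappearing AOI.
#' @export
detect_disappearance <- function(a, b, params = pattern_params(),
                                 aoi_a = "A", aoi_b = "B") {
  a <- as_pattern_series(a); b <- as_pattern_series(b)
  check_aligned(a, b)
  av <- a$v; bv <- b$v; n <- length(av)
  np <- params$field_spec$near_peripheral_px
  peri <- params$field_spec$perifoveal_px
  events <- empty_events()
  if (n < 2L) return(events)
  gone <- av >= np & bv < peri
  if (!any(gone)) return(events)
  runs <- logical_runs(gone)
  prev_end <- 0L
  for (r in seq_len(nrow(runs))) {
    i <- runs[r, "start"]; j <- runs[r, "end"]
    if (i <= 1L) next                              # needs a visible onset
    if (!(av[i - 1L] < np && bv[i - 1L] < peri)) next
    s <- max(i - 1L, prev_end + 1L)
    events <- rbind(events,
                    pattern_event("disappearance", a, s, j, aoi_a, aoi_b,
                                  notes = paste0("disappeared: ", aoi_a)))
    prev_end <- j
  }
  events
}

#' Run all four pattern detectors over every AOI pair
#'
#' Applies the glance, convergence, joint-excursion and disappearance
#' detectors to every unordered pair of AOIs (direction-sensitive rules are
#' run in both directions), deduplicates identical events, and returns the
#' time-sorted union together with a per-pattern count summary. Overlapping
#' events of different types are all reported; consumers can filter.
#'
#' @param series_map Named list of aligned numeric OGD vectors (one per
#'   AOI), or an `ogd_series` from [compute_ogd_series()] (split by AOI).
#' @param params A [pattern_params()].
#' @return A list with `events` (data frame) and `summary` (per-pattern
#'   `count`, and `mean`/`sd` of per-trial counts; a single trial has
#'   `mean = count` and `sd = 0`).
#' @export
detect_all <- function(series_map, params = pattern_params()) {
  if (inherits(series_map, "ogd_series") ||
      (is.data.frame(series_map) && !is.null(series_map$aoi_label))) {
    df <- series_map
    labs <- sort(unique(df$aoi_label))
    series_map <- lapply(labs, function(lab) {
      s <- df[df$aoi_label == lab, ]
      stats::setNames(s$ogd_px, s$fixation_id)
    })
    names(series_map) <- labs
  }
  labs <- names(series_map)
  if (length(series_map) < 2L)
    stop("pattern detection needs at least 2 AOIs", call. = FALSE)
  events <- empty_events()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i == j) next
    A <- series_map[[i]]; B <- series_map[[j]]
    la <- labs[i]; lb <- labs[j]
    events <- rbind(events, detect_glance(A, B, params, la, lb))
    events <- rbind(events, detect_disappearance(A, B, params, la, lb))
    if (i < j) {  # symmetric rules: one direction suffices
      events <- rbind(events, detect_convergence(A, B, params, la, lb))
      events <- rbind(events, detect_joint_excursion(A, B, params, la, lb))
    }
  }
  if (nrow(events)) {
    pair_key <- ifelse(events$aoi_a < events$aoi_b,
                       paste(events$aoi_a, events$aoi_b),
                       paste(events$aoi_b, events$aoi_a))
    key <- paste(events$pattern, events$start_fix, events$end_fix, pair_key,
                 events$hit_aoi, events$notes)
    events <- events[!duplicated(key), , drop = FALSE]
    events <- events[order(events$start_fix, events$pattern), , drop = FALSE]
    rownames(events) <- NULL
  }
  list(events = events, summary = summarize_patterns(list(events)))
}

#' Summarize pattern counts over trials
#'
#' @param event_list List of event data frames, one per trial.
#' @return Data frame with per-pattern total `count` and the `mean` and
#'   `sd` of per-trial counts.
#' @export
summarize_patterns <- function(event_list) {
  patterns <- c("glance", "convergence", "joint_excursion", "disappearance")
  per_trial <- sapply(event_list, function(ev)
    vapply(patterns, function(p) sum(ev$pattern == p), numeric(1)))
  per_trial <- matrix(per_trial, nrow = length(patterns),
                      dimnames = list(patterns, NULL))
  data.frame(pattern = patterns,
             count = rowSums(per_trial),
             mean = rowMeans(per_trial),
             sd = apply(per_trial, 1, function(x)
               if (length(x) > 1L) stats::sd(x) else 0),
             row.names = NULL)
}
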