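#' Parameters of the trajectory post-processing pipeline
#'
#' Defaults mirror a standard 25-fps worm-tracking workflow: individual tracks
#' of at least 30 s are kept, holes shorter than 5 s are linearly
#' interpolated (longer holes split the track), positions are smoothed with a
#' 50-frame centered rolling mean to remove the sinusoidal body wave, and
#' supra-threshold curvature episodes (threshold 0.25 radians/frame on the
#' smoothed path) are called reorientations.
#'
#' @param min_track_s Minimum track duration kept, seconds.
#' @param max_gap_s Holes at or above this duration split a track; shorter
#'   holes are interpolated. Seconds.
#' @param smooth_window_frames Rolling-mean window, frames.
#' @param curvature_threshold Reorientation threshold, radians/frame.
#' @param min_event_separation_s Supra-threshold runs closer than this merge
#'   into one event. Seconds.
#' @param fps Frame rate, frames/second.
#' @param stillness_floor_mm Centered per-frame displacements below this value
#'   (mm) are treated as stationary and given zero curvature, since heading is
#'   undefined at near-zero speed. The default (0.2 um) is deliberately far
#'   below the displacement scale of a smoothed sharp turn: on a rolling-mean
#'   path, per-frame curvature kappa and centered displacement delta obey
#'   kappa * delta^2 <= step^2 / window, so a supra-threshold turn necessarily
#'   passes through sub-micron displacements and a larger floor would veto
#'   every real reorientation.
#' @return An object of class `pipeline_params`.
#' @export
pipeline_params <- function(min_track_s = 30,
                            max_gap_s = 5,
                            smooth_window_frames = 50,
                            curvature_threshold = 0.25,
                            min_event_separation_s = 1,
                            fps = 25,
                            stillness_floor_mm = 0.0001) {
  check_positive(min_track_s, "min_track_s")
  check_positive(max_gap_s, "max_gap_s")
  check_positive(smooth_window_frames, "smooth_window_frames")
  check_positive(curvature_threshold, "curvature_threshold")
  check_positive(min_event_separation_s, "min_event_separation_s")
  check_positive(fps, "fps")
  check_nonneg(stillness_floor_mm, "stillness_floor_mm")
  if (max_gap_s * fps < 1) stop_input("max_gap_s * fps must be >= 1 frame")
  structure(
    list(min_track_s = min_track_s, max_gap_s = max_gap_s,
         smooth_window_frames = as.integer(smooth_window_frames),
         curvature_threshold = curvature_threshold,
         min_event_separation_s = min_event_separation_s, fps = fps,
         stillness_floor_mm = stillness_floor_mm),
    class = "pipeline_params"
  )
}

new_track_segment <- function(worm_id, frame, x, y, observed, fps) {
  structure(
    data.frame(frame = as.integer(frame), x_mm = x, y_mm = y,
               observed = observed),
    worm_id = worm_id, fps = fps,
    class = c("track_segment", "data.frame")
  )
}

#' Split trajectories into contiguous track segments and apply the duration filter
#'
#' Per worm, the frame sequence is split wherever a hole of at least
#' `max_gap_s` occurs; the resulting contiguous pieces shorter than
#' `min_track_s` are discarded. Holes shorter than `max_gap_s` are kept inside
#' a segment as unobserved frames (coordinates `NA`) for later interpolation.
#' Row order of the input is irrelevant.
#'
#' @param table A [trajectory_table()].
#' @param params A [pipeline_params()]; its `fps` is used unless the table
#'   carries its own `fps` attribute.
#' @return List of `track_segment` objects (possibly empty).
#' @export
filter_and_segment <- function(table, params) {
  fps <- attr(table, "fps")
  if (is.null(fps)) fps <- params$fps
  if (is.null(fps) || !is.finite(fps) || fps <= 0) {
    stop_input("frame rate (fps) missing")
  }
  if (nrow(table) == 0L) return(list())
  split_gap <- params$max_gap_s * fps   # holes with >= this many missing frames split
  min_frames <- params$min_track_s * fps
  out <- list()
  for (w in sort(unique(table$worm_id))) {
    sub <- table[table$worm_id == w, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    if (anyDuplicated(sub$frame)) {
      stop_input("duplicate frames for worm ", w)
    }
    holes <- diff(sub$frame) - 1L
    brk <- which(holes >= split_gap)
    starts <- c(1L, brk + 1L)
    ends <- c(brk, nrow(sub))
    for (k in seq_along(starts)) {
      piece <- sub[starts[k]:ends[k], , drop = FALSE]
      f0 <- piece$frame[1L]
      f1 <- piece$frame[nrow(piece)]
      if ((f1 - f0 + 1L) < min_frames) next
      grid <- f0:f1
      idx <- match(grid, piece$frame)
      obs <- !is.na(idx)
      out[[length(out) + 1L]] <- new_track_segment(
        worm_id = w, frame = grid,
        x = piece$x_mm[idx], y = piece$y_mm[idx],
        observed = obs, fps = fps
      )
    }
  }
  out
}

#' Linearly interpolate short holes inside a track segment
#'
#' Fills every unobserved frame with the point on the straight line between
#' the flanking observed frames. Holes of `max_gap_s` or longer must not reach
#' this stage (they split the track upstream).
#'
#' @param segment A `track_segment` from [filter_and_segment()].
#' @param params A [pipeline_params()].
#' @return The segment with all coordinates filled; `observed` flags preserved.
#' @export
interpolate_gaps <- function(segment, params) {
  fps <- attr(segment, "fps")
  miss <- !segment$observed
  if (!any(miss)) return(segment)
  runs <- rle(miss)
  if (max(runs$lengths[runs$values]) >= params$max_gap_s * fps) {
    stop("hole >= max_gap_s reached interpolation stage (contract violation)")
  }
  obs <- which(segment$observed)
  segment$x_mm <- stats::approx(segment$frame[obs], segment$x_mm[obs],
                                xout = segment$frame)$y
  segment$y_mm <- stats::approx(segment$frame[obs], segment$y_mm[obs],
                                xout = segment$frame)$y
  segment
}

# Centered rolling mean with window shrink at the edges, O(n) via cumsum.
# An even window cannot be centered on a frame, so interior frames use the
# classical centered even-order average: full weight on the w - 1 nearest
# neighbours and half weight on the two outermost samples. This keeps straight
# lines exactly unchanged and retains the zero of the plain w-term average at
# periods dividing w. Within half a window of an edge the largest centered
# odd window that fits is used instead (no padding).
rolling_mean <- function(x, w) {
  n <- length(x)
  i <- seq_len(n)
  h <- w %/% 2
  cs <- c(0, cumsum(x))
  win_mean <- function(lo, hi) (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  out <- numeric(n)
  interior <- i - h >= 1L & i + h <= n
  ii <- i[interior]
  out[interior] <- (win_mean(ii - h, ii + h - 1L) +
                      win_mean(ii - h + 1L, ii + h)) / 2
  if (any(!interior)) {
    ie <- i[!interior]
    k <- pmin(ie - 1L, n - ie)
    out[!interior] <- win_mean(ie - k, ie + k)
  }
  out
}

#' Smooth a segment with a centered rolling mean
#'
#' Replaces each coordinate by the mean over `smooth_window_frames`
#' consecutive frames, centered on the frame; near the segment edges the
#' window shrinks symmetrically (no padding, no fabricated positions). With
#' the default 50-frame window at 25 fps this removes a 1-s sinusoidal body
#' wobble exactly (the window spans two full periods) while leaving the
#' underlying path intact.
#'
#' @param segment An interpolated `track_segment`.
#' @param params A [pipeline_params()].
#' @return The smoothed segment (same length).
#' @export
rolling_mean_smooth <- function(segment, params) {
  w <- params$smooth_window_frames
  if (nrow(segment) < w) {
    warning("segment shorter than smoothing window; returned unsmoothed")
    return(segment)
  }
  if (anyNA(segment$x_mm) || anyNA(segment$y_mm)) {
    stop_input("segment must be interpolated before smoothing")
  }
  segment$x_mm <- rolling_mean(segment$x_mm, w)
  segment$y_mm <- rolling_mean(segment$y_mm, w)
  attr(segment, "smooth_window") <- w
  segment
}

#' Per-frame path curvature of a smoothed segment
#'
#' Heading at frame t is the direction of the centered displacement
#' `atan2(y[t+1] - y[t-1], x[t+1] - x[t-1])`; curvature is the absolute
#' per-frame heading change, with angle differences wrapped to (-pi, pi].
#' Frames whose centered displacement is below the stillness floor get zero
#' curvature (heading is undefined when stationary). Units: radians/frame.
#' The first and last interior frames are consumed by differencing, so the
#' series covers frames `2 .. n-2` of an n-frame segment. For a segment that
#' went through [rolling_mean_smooth()], the half-window margins at either
#' end are excluded as well: there the shrunken window no longer spans whole
#' wobble periods, so the body wave is not attenuated and its residual
#' curvature would masquerade as turning.
#'
#' @param segment A smoothed `track_segment`.
#' @param params A [pipeline_params()] (stillness floor).
#' @return A `curvature_series`: data frame (`frame`, `kappa`) with `worm_id`
#'   and `fps` attributes.
#' @export
compute_curvature <- function(segment, params = pipeline_params()) {
  n <- nrow(segment)
  if (n < 4L) stop_input("segment too short for curvature (need >= 4 frames)")
  x <- segment$x_mm; y <- segment$y_mm
  dx <- x[3:n] - x[1:(n - 2)]
  dy <- y[3:n] - y[1:(n - 2)]
  heading <- atan2(dy, dx)                       # frames 2 .. n-1
  disp <- sqrt(dx^2 + dy^2) / 2                  # per-frame centered displacement
  still <- disp < params$stillness_floor_mm
  kappa <- abs(wrap_angle(diff(heading)))        # frames 2 .. n-2
  kappa[still[-length(still)] | still[-1L]] <- 0
  frame <- segment$frame[2:(n - 2)]
  w <- attr(segment, "smooth_window")
  if (!is.null(w)) {
    # a kappa value reads positions up to 2 frames away, so the margin must
    # cover the partial-window frames plus the differencing stencil
    m <- floor(w / 2) + 3L
    keep <- seq_along(kappa) > (m - 1L) & seq_along(kappa) <= (n - m - 1L)
    kappa <- kappa[keep]
    frame <- frame[keep]
  }
  structure(
    data.frame(frame = frame, kappa = kappa),
    worm_id = attr(segment, "worm_id"), fps = attr(segment, "fps"),
    class = c("curvature_series", "data.frame")
  )
}

#' Detect reorientation events from a curvature series
#'
#' Maximal runs of consecutive frames with curvature above
#' `curvature_threshold` become one event each; runs separated by less than
#' `min_event_separation_s` are merged (one omega turn should not be counted
#' twice). The peak curvature within each merged event is recorded.
#'
#' @param curv A `curvature_series` from [compute_curvature()].
#' @param params A [pipeline_params()].
#' @return Data frame (`worm_id`, `start_frame`, `end_frame`,
#'   `peak_curvature`), zero rows when nothing crosses the threshold.
#' @export
detect_reorientations <- function(curv, params) {
  fps <- attr(curv, "fps")
  worm <- attr(curv, "worm_id")
  empty <- data.frame(worm_id = if (is.null(worm)) integer(0) else worm[0],
                      start_frame = integer(0), end_frame = integer(0),
                      peak_curvature = numeric(0))
  above <- curv$kappa > params$curvature_threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  # merge runs whose frame gap is below the separation window
  sep <- params$min_event_separation_s * fps
  merged <- list(runs[1L, ])
  if (nrow(runs) > 1L) {
    for (k in 2:nrow(runs)) {
      last <- merged[[length(merged)]]
      gap <- curv$frame[runs[k, 1L]] - curv$frame[last[2L]] - 1L
      if (gap < sep) {
        merged[[length(merged)]] <- c(last[1L], runs[k, 2L])
      } else {
        merged[[length(merged) + 1L]] <- runs[k, ]
      }
    }
  }
  do.call(rbind, lapply(merged, function(m) {
    data.frame(worm_id = if (is.null(worm)) NA else worm,
               start_frame = curv$frame[m[1L]],
               end_frame = curv$frame[m[2L]],
               peak_curvature = max(curv$kappa[m[1L]:m[2L]]))
  }))
}

#' Reorientation rate of a track segment
#'
#' Events per minute of track time: `count / (segment duration in minutes)`.
#'
#' @param events Event data frame from [detect_reorientations()] for this
#'   segment.
#' @param segment The `track_segment` the events belong to.
#' @return One-row data frame: `worm_id`, `n_events`, `track_minutes`,
#'   `reorientations_per_minute`.
#' @export
reorientation_rate <- function(events, segment) {
  fps <- attr(segment, "fps")
  minutes <- nrow(segment) / fps / 60
  if (minutes <= 0) stop("zero-duration segment (contract violation)")
  data.frame(
    worm_id = attr(segment, "worm_id"),
    n_events = nrow(events),
    track_minutes = minutes,
    reorientations_per_minute = nrow(events) / minutes
  )
}

#' Speed percentiles and motion-mode fractions of a segment
#'
#' Per-frame speed is the forward displacement times the frame rate;
#' `speed_10th`/`speed_50th` are its 10th/50th percentiles (mm/s). When a
#' per-frame body orientation is supplied, each frame is classified forward /
#' backward / paused by the sign of the velocity projected on the orientation,
#' with a dead-band around zero speed; the fractions are time fractions. With
#' centroid-only data (no orientation) the forward/backward fractions are
#' `NA` and only the paused fraction is reported.
#'
#' @param segment A smoothed `track_segment`.
#' @param heading_reference Optional per-frame body orientation, radians
#'   (length `nrow(segment)` or one less).
#' @param dead_band_mm_s Speeds below this magnitude count as paused (mm/s).
#' @return One-row data frame with `worm_id`, `speed_10th`, `speed_50th`,
#'   `forward_fraction`, `backward_fraction`, `paused_fraction`.
#' @export
locomotion_features <- function(segment, heading_reference = NULL,
                                dead_band_mm_s = 0.02) {
  fps <- attr(segment, "fps")
  n <- nrow(segment)
  vx <- diff(segment$x_mm) * fps
  vy <- diff(segment$y_mm) * fps
  speed <- sqrt(vx^2 + vy^2)
  qs <- unname(quantile(speed, c(0.1, 0.5), names = FALSE))
  fwd <- bwd <- NA_real_
  paused <- mean(speed < dead_band_mm_s)
  if (!is.null(heading_reference)) {
    h <- heading_reference
    if (length(h) == n) h <- h[-n]
    if (length(h) != n - 1L) {
      stop_input("heading_reference must have one value per frame")
    }
    proj <- vx * cos(h) + vy * sin(h)
    mode <- ifelse(abs(proj) < dead_band_mm_s, 0, sign(proj))
    fwd <- mean(mode > 0)
    bwd <- mean(mode < 0)
    paused <- mean(mode == 0)
  }
  data.frame(
    worm_id = attr(segment, "worm_id"),
    speed_10th = qs[1L], speed_50th = qs[2L],
    forward_fraction = fwd, backward_fraction = bwd,
    paused_fraction = paused
  )
}

#' Run the full trajectory pipeline on a table
#'
#' Filter/segment, interpolate, smooth, curvature, event detection and
#' per-segment summaries, in order.
#'
#' @param table A [trajectory_table()].
#' @param params A [pipeline_params()].
#' @return List with `segments` (smoothed), `events` (one data frame across
#'   worms), and `summary` (per-segment rates and speed features).
#' @export
analyze_trajectories <- function(table, params = pipeline_params()) {
  segs <- filter_and_segment(table, params)
  events <- list()
  summaries <- list()
  smoothed <- vector("list", length(segs))
  for (k in seq_along(segs)) {
    seg <- rolling_mean_smooth(interpolate_gaps(segs[[k]], params), params)
    smoothed[[k]] <- seg
    curv <- compute_curvature(seg, params)
    ev <- detect_reorientations(curv, params)
    events[[k]] <- ev
    summaries[[k]] <- cbind(
      reorientation_rate(ev, seg),
      locomotion_features(seg)[, -1L, drop = FALSE]
    )
  }
  empty_ev <- data.frame(worm_id = integer(0), start_frame = integer(0),
                         end_frame = integer(0), peak_curvature = numeric(0))
  list(
    segments = smoothed,
    events = if (length(events)) do.call(rbind, events) else empty_ev,
    summary = if (length(summaries)) do.call(rbind, summaries) else NULL
  )
}

#' Score detected events against a planted ground truth
#'
#' Interval matching with a tolerance window: a planted event is recovered if
#' any detected event overlaps it once both are dilated by `tolerance_s`; a
#' detected event is correct if it overlaps any planted event. Matching is
#' many-to-one by design: the rolling-mean smoothing smears each sharp turn
#' over about two seconds, so one detection may legitimately cover two planted
#' turns that occurred back to back.
#'
#' @param planted Data frame `worm_id`, `start_frame`, `end_frame`.
#' @param detected Data frame of the same shape from
#'   [detect_reorientations()].
#' @param fps Frame rate.
#' @param tolerance_s Dilation half-width, seconds (default 2).
#' @return List with `sensitivity`, `precision`, `n_planted`, `n_detected`.
#' @export
event_match_stats <- function(planted, detected, fps, tolerance_s = 2) {
  tol <- tolerance_s * fps
  overlaps <- function(a, b) {
    # any row of b overlapping interval a (after dilation)?
    any(b$start_frame - tol <= a[2L] & b$end_frame + tol >= a[1L])
  }
  hit_planted <- vapply(seq_len(nrow(planted)), function(i) {
    d <- detected[detected$worm_id == planted$worm_id[i], , drop = FALSE]
    if (!nrow(d)) return(FALSE)
    overlaps(c(planted$start_frame[i], planted$end_frame[i]), d)
  }, TRUE)
  hit_detected <- vapply(seq_len(nrow(detected)), function(i) {
    p <- planted[planted$worm_id == detected$worm_id[i], , drop = FALSE]
    if (!nrow(p)) return(FALSE)
    overlaps(c(detected$start_frame[i], detected$end_frame[i]), p)
  }, TRUE)
  list(
    sensitivity = if (nrow(planted)) mean(hit_planted) else NA_real_,
    precision = if (nrow(detected)) mean(hit_detected) else NA_real_,
    n_planted = nrow(planted), n_detected = nrow(detected)
  )
}
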