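#' Configuration for the two-state foraging trajectory simulator
#'
#' Bundles the generative parameters of a run-and-reorient random walk used to
#' emulate off-food search behavior recorded at a fixed frame rate. Worms move
#' as persistent runs with Gaussian heading noise and a sinusoidal "wobble"
#' (the body-wave signature a centroid tracker sees), interrupted by Poisson
#' reorientation events during which the heading swings by about
#' `turn_magnitude` over `turn_duration_frames` frames. Tracking dropouts are
#' planted as Poisson gaps of fixed length.
#'
#' The two behavioral states differ only in their reorientation rate:
#' `"local"` search is turn-rich (default 4 events/min) and `"global"` search
#' is run-dominated (default 1 event/min). These per-state defaults are
#' placeholders chosen to separate the two regimes cleanly; override
#' `reorientation_rate` to set the rate directly.
#'
#' @param n_worms Number of worms to simulate.
#' @param duration_s Recording duration in seconds.
#' @param fps Frame rate (frames/second), default 25.
#' @param state Behavioral state label, `"local"` or `"global"`; sets the
#'   default reorientation rate (4/min resp. 1/min) when
#'   `reorientation_rate` is `NULL`.
#' @param reorientation_rate Poisson event rate, events per minute.
#' @param run_speed Crawl speed during runs, mm/s (default 0.1, an off-food crawl; slow enough that a 5-min video cannot reach the wall of an 8-cm plate from a central start).
#' @param wobble_amplitude Amplitude of the sinusoidal lateral wobble, mm.
#' @param wobble_period_s Wobble period in seconds (default 1 s, i.e. 25
#'   frames at 25 fps, so a 50-frame rolling mean cancels it exactly).
#' @param heading_noise Per-frame Gaussian heading noise SD, radians/frame.
#' @param turn_magnitude Mean total heading change per reorientation, radians.
#'   The default 3.05 (~175 degrees) mimics omega-turn-like near-reversals,
#'   the sharp maneuvers the curvature detector is built for.
#' @param turn_duration_frames Frames over which the turn is executed.
#' @param gap_rate Tracking-gap rate, gaps per minute.
#' @param gap_length_s Length of each planted gap, seconds (values below and
#'   at/above 5 s are both legal; the analysis treats them differently).
#' @param arena_radius Radius of the circular arena, mm (default 40, an
#'   8-cm assay plate). Tracks reflect off the boundary.
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#'
#' @return An object of class `foraging_config` (a named list).
#' @seealso [simulate_foraging_tracks()]
#' @export
foraging_config <- function(n_worms = 20,
                            duration_s = 300,
                            fps = 25,
                            state = c("global", "local"),
                            reorientation_rate = NULL,
                            run_speed = 0.1,
                            wobble_amplitude = 0.15,
                            wobble_period_s = 1,
                            heading_noise = 0.03,
                            turn_magnitude = 3.05,
                            turn_duration_frames = 8,
                            gap_rate = 0.5,
                            gap_length_s = 2,
                            arena_radius = 40,
                            seed = 1) {
  state <- match.arg(state)
  if (is.null(reorientation_rate)) {
    reorientation_rate <- switch(state, local = 4, global = 1)
  }
  check_positive(n_worms, "n_worms")
  check_positive(duration_s, "duration_s")
  check_positive(fps, "fps")
  check_nonneg(reorientation_rate, "reorientation_rate")
  check_nonneg(run_speed, "run_speed")
  check_nonneg(wobble_amplitude, "wobble_amplitude")
  check_positive(wobble_period_s, "wobble_period_s")
  check_nonneg(heading_noise, "heading_noise")
  check_nonneg(gap_rate, "gap_rate")
  check_positive(gap_length_s, "gap_length_s")
  check_positive(arena_radius, "arena_radius")
  if (turn_duration_frames < 1) stop_input("`turn_duration_frames` must be >= 1")
  structure(
    list(
      n_worms = as.integer(n_worms), duration_s = duration_s, fps = fps,
      state = state, reorientation_rate = reorientation_rate,
      run_speed = run_speed, wobble_amplitude = wobble_amplitude,
      wobble_period_s = wobble_period_s, heading_noise = heading_noise,
      turn_magnitude = turn_magnitude,
      turn_duration_frames = as.integer(turn_duration_frames),
      gap_rate = gap_rate, gap_length_s = gap_length_s,
      arena_radius = arena_radius, seed = as.integer(seed)
    ),
    class = "foraging_config"
  )
}

#' Construct a trajectory table
#'
#' A per-worm, per-frame centroid table: columns `worm_id`, `frame`
#' (0-based integer), `x_mm`, `y_mm`, with the frame rate attached as an
#' attribute. This is the interchange format consumed by the trajectory
#' pipeline.
#'
#' @param df Data frame with columns `worm_id`, `frame`, `x_mm`, `y_mm`.
#' @param fps Frame rate in frames/second.
#' @return A `trajectory_table` (data frame with `fps` attribute).
#' @export
trajectory_table <- function(df, fps) {
  need <- c("worm_id", "frame", "x_mm", "y_mm")
  if (!all(need %in% names(df))) {
    stop_input("trajectory table needs columns: ", paste(need, collapse = ", "))
  }
  check_positive(fps, "fps")
  if (any(!is.finite(df$x_mm)) || any(!is.finite(df$y_mm))) {
    stop_input("trajectory coordinates must be finite")
  }
  out <- as.data.frame(df)[need]
  out$frame <- as.integer(out$frame)
  attr(out, "fps") <- fps
  class(out) <- c("trajectory_table", "data.frame")
  out
}

# Poisson process of fixed-length, non-overlapping intervals on a frame grid.
# Returns a matrix with columns start, end (1-based, inclusive); intervals are
# fully contained in [1, n_frames].
sample_intervals <- function(n_frames, rate_per_min, len_frames, fps) {
  out <- matrix(integer(0), ncol = 2L)
  if (rate_per_min <= 0) return(out)
  rate_per_frame <- rate_per_min / (60 * fps)
  t <- 0
  starts <- integer(0)
  repeat {
    t <- t + rexp(1L, rate_per_frame)
    s <- floor(t) + 1L
    if (s + len_frames - 1L > n_frames) break
    starts <- c(starts, s)
    t <- s + len_frames - 1L
  }
  if (length(starts)) out <- cbind(starts, starts + len_frames - 1L)
  out
}

#' Simulate two-state foraging trajectories with known ground truth
#'
#' Generates centroid tracks for `n_worms` worms under the run-and-reorient
#' model described in [foraging_config()]. Worms start near the arena center
#' (as in a plate assay where animals are deposited centrally), run at
#' constant speed with heading noise, execute planted reorientations at
#' Poisson times, reflect specularly off the arena wall, and carry a
#' sinusoidal lateral wobble. Frames falling inside planted tracking gaps are
#' absent from the returned table.
#'
#' @param config A [foraging_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{tracks}{a [trajectory_table()]}
#'     \item{truth}{a ground-truth log: `planted_events` and `planted_gaps`
#'       data frames (`worm_id`, `start_frame`, `end_frame`, 0-based,
#'       inclusive) and `true_rate` (events/minute)}
#'   }
#' @export
simulate_foraging_tracks <- function(config) {
  if (!inherits(config, "foraging_config")) {
    stop_input("`config` must be a foraging_config")
  }
  n_frames <- as.integer(round(config$duration_s * config$fps))
  if (n_frames < 1L) stop_input("duration too short for one frame")
  step <- config$run_speed / config$fps
  gap_len <- max(1L, as.integer(round(config$gap_length_s * config$fps)))
  omega <- 2 * pi / (config$wobble_period_s * config$fps)

  with_seed(config$seed, {
    rows <- vector("list", config$n_worms)
    ev_list <- vector("list", config$n_worms)
    gp_list <- vector("list", config$n_worms)
    for (w in seq_len(config$n_worms)) {
      # start within 2 mm of plate center, random heading
      r0 <- min(2, config$arena_radius / 2) * sqrt(runif(1L))
      a0 <- runif(1L, -pi, pi)
      p0 <- c(r0 * cos(a0), r0 * sin(a0))
      heading0 <- runif(1L, -pi, pi)

      ev <- sample_intervals(n_frames, config$reorientation_rate,
                             config$turn_duration_frames, config$fps)
      dtheta <- rnorm(n_frames, 0, config$heading_noise)
      if (nrow(ev)) {
        signs <- sample(c(-1, 1), nrow(ev), replace = TRUE)
        per_frame <- config$turn_magnitude / config$turn_duration_frames
        for (k in seq_len(nrow(ev))) {
          idx <- ev[k, 1L]:ev[k, 2L]
          dtheta[idx] <- dtheta[idx] + signs[k] * per_frame
        }
      }
      phase <- runif(1L, 0, 2 * pi)
      gp <- sample_intervals(n_frames, config$gap_rate, gap_len, config$fps)

      heading <- heading0 + cumsum(dtheta)
      x <- p0[1] + cumsum(step * cos(heading))
      y <- p0[2] + cumsum(step * sin(heading))

      if (any(x * x + y * y > config$arena_radius^2)) {
        # redo sequentially with specular reflection at the wall
        th <- heading0
        px <- p0[1]; py <- p0[2]
        R <- config$arena_radius
        for (i in seq_len(n_frames)) {
          th <- th + dtheta[i]
          px2 <- px + step * cos(th)
          py2 <- py + step * sin(th)
          r2 <- sqrt(px2 * px2 + py2 * py2)
          if (r2 > R) {
            nx <- px2 / r2; ny <- py2 / r2
            px2 <- px2 - 2 * (r2 - R) * nx
            py2 <- py2 - 2 * (r2 - R) * ny
            dx <- cos(th); dy <- sin(th)
            dot <- dx * nx + dy * ny
            th <- atan2(dy - 2 * dot * ny, dx - 2 * dot * nx)
          }
          px <- px2; py <- py2
          x[i] <- px; y[i] <- py
          heading[i] <- th
        }
      }

      if (config$wobble_amplitude > 0) {
        wob <- config$wobble_amplitude * sin(omega * seq_len(n_frames) + phase)
        x <- x - wob * sin(heading)
        y <- y + wob * cos(heading)
      }

      keep <- rep(TRUE, n_frames)
      if (nrow(gp)) {
        for (k in seq_len(nrow(gp))) keep[gp[k, 1L]:gp[k, 2L]] <- FALSE
      }
      rows[[w]] <- data.frame(
        worm_id = w,
        frame = which(keep) - 1L,
        x_mm = x[keep], y_mm = y[keep]
      )
      ev_list[[w]] <- if (nrow(ev)) {
        data.frame(worm_id = w, start_frame = ev[, 1L] - 1L,
                   end_frame = ev[, 2L] - 1L)
      }
      gp_list[[w]] <- if (nrow(gp)) {
        data.frame(worm_id = w, start_frame = gp[, 1L] - 1L,
                   end_frame = gp[, 2L] - 1L)
      }
    }
    empty <- data.frame(worm_id = integer(0), start_frame = integer(0),
                        end_frame = integer(0))
    tracks <- trajectory_table(do.call(rbind, rows), config$fps)
    attr(tracks, "arena_radius") <- config$arena_radius
    list(
      tracks = tracks,
      truth = list(
        planted_events = if (any(!vapply(ev_list, is.null, TRUE))) {
          do.call(rbind, ev_list[!vapply(ev_list, is.null, TRUE)])
        } else empty,
        planted_gaps = if (any(!vapply(gp_list, is.null, TRUE))) {
          do.call(rbind, gp_list[!vapply(gp_list, is.null, TRUE)])
        } else empty,
        true_rate = config$reorientation_rate
      )
    )
  })
}
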