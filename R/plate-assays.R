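#' Dispersal zone density ratio of a thresholded plate image
#'
#' Background is removed by thresholding (Otsu by default, as a reproducible
#' stand-in for interactive image thresholding; pass a number for a fixed
#' threshold), then the integrated density (IntDen, the sum of remaining
#' intensities) is computed inside the central zone and over the whole plate
#' disk. The statistic is
#' `ratio = (IntDen_zone / zone_area) / (IntDen_plate / plate_area)`:
#' values near 1 mean worms spread homogeneously; values of
#' `plate_area / zone_area` mean all signal stayed central (no dispersal).
#' Pixels outside the plate disk are ignored throughout, including for the
#' threshold.
#'
#' @param image A [plate_image()].
#' @param threshold_method `"otsu"` or a fixed numeric threshold; intensities
#'   at or below the threshold are zeroed.
#' @return A `dispersal_result` list: `intden_zone`, `intden_plate`,
#'   `zone_area`, `plate_area` (pixel counts) and `zone_density_ratio`.
#'   The ratio is `NA` (with a warning) when the plate carries no
#'   supra-threshold signal.
#' @export
zone_density_ratio <- function(image, threshold_method = "otsu") {
  if (!inherits(image, "plate_image")) stop_input("need a plate_image")
  img <- image$img
  plate <- disk_mask(dim(img), image$center, image$plate_radius)
  zone <- disk_mask(dim(img), image$center, image$zone_radius)
  vals <- img[plate]
  thr <- if (is.numeric(threshold_method)) {
    threshold_method
  } else if (identical(threshold_method, "otsu")) {
    otsu_threshold(vals)
  } else {
    stop_input("`threshold_method` must be \"otsu\" or a number")
  }
  fg <- img
  fg[fg <= thr] <- 0
  intden_plate <- sum(fg[plate])
  intden_zone <- sum(fg[zone & plate])
  zone_area <- sum(zone & plate)
  plate_area <- sum(plate)
  ratio <- if (intden_plate > 0) {
    (intden_zone / zone_area) / (intden_plate / plate_area)
  } else {
    warning("no supra-threshold signal on plate; ratio undefined")
    NA_real_
  }
  structure(
    list(intden_zone = intden_zone, intden_plate = intden_plate,
         zone_area = zone_area, plate_area = plate_area,
         zone_density_ratio = ratio, threshold = thr),
    class = "dispersal_result"
  )
}

# Otsu threshold of the in-plate intensities. Constant images get a threshold
# below the minimum so everything is kept (thresholding a blank field should
# not delete it).
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1L] - 1)
  x <- EBImage::Image(matrix((vals - rng[1L]) / diff(rng), nrow = 1L))
  thr01 <- EBImage::otsu(x, range = c(0, 1), levels = 256L)
  rng[1L] + thr01 * diff(rng)
}

#' Geometry of a food patch
#'
#' @param center Patch center `(x, y)`, mm.
#' @param radius Patch radius, mm.
#' @param body_length Worm body length, mm (default 1.0); a leaving event
#'   requires the full body to clear the patch, approximated at centroid
#'   resolution as the centroid passing `radius + body_length / 2`.
#' @return An object of class `patch_geometry`.
#' @export
patch_geometry <- function(center = c(0, 0), radius, body_length = 1.0) {
  check_positive(radius, "radius")
  check_positive(body_length, "body_length")
  structure(list(center = center, radius = radius, body_length = body_length),
            class = "patch_geometry")
}

#' Food-leaving probability from centroid trajectories
#'
#' A leaving event fires when a worm's centroid first moves beyond
#' `radius + body_length / 2` from the patch center (the centroid-level proxy
#' for the whole body having left the patch). The detector then disarms until
#' the worm returns fully inside the patch radius, so one excursion cannot be
#' counted twice. The probability is the assay's standard normalization:
#' `events / worms on the patch at video start / video minutes`.
#'
#' @param table A [trajectory_table()] (positions in mm, patch coordinates).
#' @param patch A [patch_geometry()].
#' @param n_worms_at_start Worms on the patch when the video starts (> 0).
#' @param video_minutes Video length, minutes (> 0).
#' @return List with `probability` (events/worm/min), `n_events`, and
#'   `events` (data frame `worm_id`, `frame` of each crossing).
#' @export
food_leaving_probability <- function(table, patch, n_worms_at_start,
                                     video_minutes) {
  check_positive(n_worms_at_start, "n_worms_at_start")
  check_positive(video_minutes, "video_minutes")
  if (!inherits(patch, "patch_geometry")) stop_input("need a patch_geometry")
  out_r <- patch$radius + patch$body_length / 2
  events <- data.frame(worm_id = integer(0), frame = integer(0))
  if (nrow(table)) {
    for (w in unique(table$worm_id)) {
      sub <- table[table$worm_id == w, , drop = FALSE]
      sub <- sub[order(sub$frame), , drop = FALSE]
      d <- sqrt((sub$x_mm - patch$center[1L])^2 +
                (sub$y_mm - patch$center[2L])^2)
      armed <- d[1L] < out_r
      for (i in seq_along(d)) {
        if (armed && d[i] > out_r) {
          events <- rbind(events,
                          data.frame(worm_id = w, frame = sub$frame[i]))
          armed <- FALSE
        } else if (!armed && d[i] < patch$radius) {
          armed <- TRUE
        }
      }
    }
  }
  list(
    probability = nrow(events) / n_worms_at_start / video_minutes,
    n_events = nrow(events),
    events = events
  )
}

#' Quadrant chemotaxis index
#'
#' `CI = ((test1 + test2) - (ctrl1 + ctrl2)) / total counted`, in `[-1, 1]`.
#' Worms stranded at the plate center are excluded from the total. Note the
#' numerator contrasts test against control quadrants; assay write-ups
#' sometimes misprint the formula with the test terms repeated, which would be
#' identically zero. Plates with fewer than `min_total` counted worms are
#' flagged invalid (but still scored).
#'
#' @param test1,test2,ctrl1,ctrl2 Worm counts per quadrant (non-negative
#'   integers).
#' @param n_center_excluded Worms that never left the center (not counted).
#' @param min_total Minimum counted worms for a valid plate (default 50).
#' @return List with `index`, `total`, and `valid` (logical). `index` is `NA`
#'   with a warning when no worms were counted.
#' @export
chemotaxis_index <- function(test1, test2, ctrl1, ctrl2,
                             n_center_excluded = 0, min_total = 50) {
  counts <- c(test1, test2, ctrl1, ctrl2)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_input("quadrant counts must be non-negative integers")
  }
  total <- sum(counts)
  if (total == 0) {
    warning("no worms counted; chemotaxis index undefined")
    return(list(index = NA_real_, total = 0L, valid = FALSE))
  }
  list(
    index = ((test1 + test2) - (ctrl1 + ctrl2)) / total,
    total = as.integer(total),
    valid = total >= min_total
  )
}

#' Patch-occupancy time course
#'
#' Percentage of worms remaining on the food patch at each scored minute,
#' relative to the number on the patch before the repellent was added.
#'
#' @param counts_over_time Data frame with columns `minute` (non-decreasing)
#'   and `n_on_patch`.
#' @param n_total Worms on the patch before treatment (> 0).
#' @return Data frame (`minute`, `percent_remaining`).
#' @export
occupancy_timecourse <- function(counts_over_time, n_total) {
  check_positive(n_total, "n_total")
  need <- c("minute", "n_on_patch")
  if (!all(need %in% names(counts_over_time))) {
    stop_input("need columns: ", paste(need, collapse = ", "))
  }
  if (is.unsorted(counts_over_time$minute)) {
    stop_input("minutes must be non-decreasing")
  }
  if (any(counts_over_time$n_on_patch > n_total) ||
      any(counts_over_time$n_on_patch < 0)) {
    stop_input("n_on_patch must lie in [0, n_total]")
  }
  data.frame(
    minute = counts_over_time$minute,
    percent_remaining = 100 * counts_over_time$n_on_patch / n_total
  )
}
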