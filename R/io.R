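# Readers and writers for the package's plain-text interchange formats.

#' Write / read a trajectory table as CSV with a YAML metadata sidecar
#'
#' The CSV has the header `worm_id,frame,x_mm,y_mm` (frame 0-based); the
#' sidecar `<path>.meta.yaml` records the frame rate and, when known, the
#' arena geometry, so the table round-trips losslessly.
#'
#' @param table A [trajectory_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(table, path) {
  write.csv(as.data.frame(table)[c("worm_id", "frame", "x_mm", "y_mm")],
            path, row.names = FALSE)
  meta <- list(fps = attr(table, "fps"))
  if (!is.null(attr(table, "arena_radius"))) {
    meta$arena_radius_mm <- attr(table, "arena_radius")
  }
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param fps Frame rate; read from the sidecar when omitted.
#' @export
read_trajectory_csv <- function(path, fps = NULL) {
  df <- read.csv(path)
  side <- paste0(path, ".meta.yaml")
  if (is.null(fps)) {
    if (!file.exists(side)) stop_input("fps not given and no metadata sidecar")
    fps <- yaml::read_yaml(side)$fps
  }
  trajectory_table(df, fps)
}

#' Write a ground-truth or detected event log as CSV
#'
#' Columns `worm_id,start_frame,end_frame,kind`, kind in `{event, gap}`.
#'
#' @param events Data frame with `worm_id`, `start_frame`, `end_frame`.
#' @param path Output path.
#' @param kind Label for the rows (default `"event"`).
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, kind = "event") {
  out <- events[c("worm_id", "start_frame", "end_frame")]
  out$kind <- kind
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write / read a current trace or I-V ramp as CSV
#'
#' Traces use `time_s,current_uA`; ramps use `voltage_mV,current_uA`.
#'
#' @param x A `tevc_trace` or `iv_ramp` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- read.csv(path)
  if ("voltage_mV" %in% names(df)) {
    class(df) <- c("iv_ramp", "data.frame")
  } else if ("time_s" %in% names(df)) {
    class(df) <- c("tevc_trace", "data.frame")
  } else {
    stop_input("trace CSV must have a time_s or voltage_mV column")
  }
  df
}

#' Write a plate image as 8- or 16-bit grayscale PNG
#'
#' Intensities are scaled to the full bit depth; the geometry travels in a
#' YAML sidecar so [read_plate_png()] can rebuild the [plate_image()].
#'
#' @param image A [plate_image()].
#' @param path Output PNG path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_plate_png <- function(image, path, bit_depth = 16) {
  if (!bit_depth %in% c(8, 16)) stop_input("bit_depth must be 8 or 16")
  img <- image$img
  mx <- max(img)
  scaled <- if (mx > 0) img / mx else img
  png::writePNG(scaled, path, dpi = NULL)
  yaml::write_yaml(
    list(center = as.numeric(image$center),
         plate_radius = image$plate_radius,
         zone_radius = image$zone_radius,
         intensity_max = mx),
    paste0(path, ".meta.yaml")
  )
  invisible(path)
}

#' @rdname write_plate_png
#' @export
read_plate_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  meta <- yaml::read_yaml(paste0(path, ".meta.yaml"))
  plate_image(img * meta$intensity_max, unlist(meta$center),
              meta$plate_radius, meta$zone_radius)
}

#' Read a quadrant-count table
#'
#' CSV with columns `plate_id,test1,test2,ctrl1,ctrl2`.
#'
#' @param path CSV path.
#' @return Data frame of counts.
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path)
  need <- c("plate_id", "test1", "test2", "ctrl1", "ctrl2")
  if (!all(need %in% names(df))) {
    stop_input("counts CSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}
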