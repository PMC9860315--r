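#' Construct a plate-image object
#'
#' A grayscale intensity grid with the plate/zone geometry needed by the
#' dispersal statistic: plate center and radius, and the radius of the
#' central scoring zone (all in pixels).
#'
#' @param img Numeric matrix of non-negative intensities (rows = y).
#' @param center Plate center `(x, y)` in pixels.
#' @param plate_radius Plate disk radius, pixels.
#' @param zone_radius Central zone radius, pixels (must be smaller than the
#'   plate radius).
#' @param pixel_size Optional pixel size, mm/px.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(img, center, plate_radius, zone_radius,
                        pixel_size = NULL) {
  if (!is.matrix(img) || !is.numeric(img) || any(!is.finite(img))) {
    stop_input("`img` must be a finite numeric matrix")
  }
  if (any(img < 0)) stop_input("intensities must be non-negative")
  check_positive(plate_radius, "plate_radius")
  check_positive(zone_radius, "zone_radius")
  if (zone_radius >= plate_radius) {
    stop_input("zone_radius must be smaller than plate_radius")
  }
  structure(
    list(img = img, center = center, plate_radius = plate_radius,
         zone_radius = zone_radius, pixel_size = pixel_size),
    class = "plate_image"
  )
}

disk_mask <- function(dim, center, radius) {
  xs <- matrix(seq_len(dim[2L]), nrow = dim[1L], ncol = dim[2L], byrow = TRUE)
  ys <- matrix(seq_len(dim[1L]), nrow = dim[1L], ncol = dim[2L])
  (xs - center[1L])^2 + (ys - center[2L])^2 <= radius^2
}

#' Simulate a dispersal-assay plate photograph
#'
#' Paints worm-like bright blobs (small Gaussian spots) on a dark background:
#' `n_blobs_center` inside the central zone and `n_blobs_outside` in the
#' annulus between zone and plate edge. The analytically known zone density
#' ratio of the painted signal (central-zone signal density over whole-plate
#' signal density, by direct pixel summation of the clean image) is returned
#' alongside, so the image analysis can be checked against ground truth.
#'
#' @param n_blobs_center,n_blobs_outside Blob counts (>= 0).
#' @param blob_intensity Peak intensity per blob, arbitrary units.
#' @param image_size_px Side of the square image, pixels.
#' @param zone_radius_px Central zone radius, pixels; must be below half the
#'   image size.
#' @param seed Integer seed.
#' @param blob_sigma_px Gaussian blob SD, pixels.
#' @return List with `image` (a [plate_image()]) and `true_ratio`.
#' @export
simulate_plate_image <- function(n_blobs_center, n_blobs_outside,
                                 blob_intensity = 1, image_size_px = 512,
                                 zone_radius_px = 80, seed = 1,
                                 blob_sigma_px = 2) {
  check_nonneg(n_blobs_center, "n_blobs_center")
  check_nonneg(n_blobs_outside, "n_blobs_outside")
  if (zone_radius_px >= image_size_px / 2) {
    stop_input("zone larger than plate")
  }
  size <- as.integer(image_size_px)
  center <- c((size + 1) / 2, (size + 1) / 2)
  plate_radius <- 0.46 * size
  stamp_r <- ceiling(4 * blob_sigma_px)
  # blobs are square stamps; the corner diagonal sets the containment margin
  margin <- ceiling(stamp_r * sqrt(2)) + 1
  ks <- -stamp_r:stamp_r
  stamp <- blob_intensity *
    exp(-outer(ks^2, ks^2, "+") / (2 * blob_sigma_px^2))

  img <- matrix(0, size, size)
  paint <- function(img, n, r_lo, r_hi) {
    if (n == 0) return(img)
    r <- sqrt(runif(n, r_lo^2, r_hi^2))
    a <- runif(n, 0, 2 * pi)
    cx <- round(center[1L] + r * cos(a))
    cy <- round(center[2L] + r * sin(a))
    for (b in seq_len(n)) {
      rows <- (cy[b] - stamp_r):(cy[b] + stamp_r)
      cols <- (cx[b] - stamp_r):(cx[b] + stamp_r)
      img[rows, cols] <- img[rows, cols] + stamp
    }
    img
  }
  img <- with_seed(seed, {
    img <- paint(img, n_blobs_center, 0, max(zone_radius_px - margin, 0))
    paint(img, n_blobs_outside, zone_radius_px + margin, plate_radius - margin)
  })

  zone <- disk_mask(dim(img), center, zone_radius_px)
  plate <- disk_mask(dim(img), center, plate_radius)
  dens_zone <- sum(img[zone]) / sum(zone)
  dens_plate <- sum(img[plate]) / sum(plate)
  true_ratio <- if (dens_plate > 0) dens_zone / dens_plate else NA_real_

  list(
    image = plate_image(img, center, plate_radius, zone_radius_px),
    true_ratio = true_ratio
  )
}
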