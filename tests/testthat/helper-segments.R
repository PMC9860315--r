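# Builders for hand-crafted pipeline inputs.

# A trajectory table for one worm from explicit frame/position vectors.
toy_table <- function(frame, x, y, fps = 25, worm_id = 1L) {
  trajectory_table(
    data.frame(worm_id = worm_id, frame = frame, x_mm = x, y_mm = y),
    fps = fps
  )
}

# A bare track segment (as filter_and_segment would emit), fully observed.
toy_segment <- function(x, y, fps = 25, worm_id = 1L) {
  structure(
    data.frame(frame = seq_along(x) - 1L, x_mm = x, y_mm = y,
               observed = TRUE),
    worm_id = worm_id, fps = fps,
    class = c("track_segment", "data.frame")
  )
}

# Seeded normal draws for coverage checks.
with_seed_draw <- function(seed, n, mean = 5, sd = 1) {
  set.seed(seed)
  rnorm(n, mean, sd)
}

# Independent pixel-center disk mask (oracle for zone/plate areas).
disk_area_px <- function(size, center, radius) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
}

# A fixed permutation of 1..n for order-invariance checks.
with_seed_shuffle <- function(n, seed = 1) {
  set.seed(seed)
  sample.int(n)
}

# A curvature series from explicit values (frames contiguous from 2).
toy_curvature <- function(kappa, fps = 25, worm_id = 1L) {
  structure(
    data.frame(frame = seq_along(kappa) + 1L, kappa = kappa),
    worm_id = worm_id, fps = fps,
    class = c("curvature_series", "data.frame")
  )
}
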