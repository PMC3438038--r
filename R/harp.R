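# Harmonic-phase (HARP) analysis: isolate the first spectral harmonic of a
# line-tag pattern and track material points by phase invariance.

#' Isolate the first tag harmonic of a frame
#'
#' Computes the 2D DFT of the frame, retains the first harmonic with a
#' circularly symmetric raised-cosine band-pass centred at `+1/tag_spacing`
#' along the tag direction, and inverse-transforms to a complex harmonic
#' image whose phase is (to first order) `2*pi * e . X / tag_spacing` at
#' material reference position X.
#'
#' @param frame Real image matrix (rows x cols).
#' @param tag_direction Unit 2-vector (x, y components).
#' @param tag_spacing Tag period, mm.
#' @param pixel_spacing Pixel size, mm.
#' @param filter_radius Band-pass radius in cycles/mm; default
#'   `0.7 / tag_spacing`. The raised-cosine window falls to zero at this
#'   radius, so the DC and conjugate peaks (at distance `1/tag_spacing` and
#'   `2/tag_spacing` from the centre) remain fully excluded; the wide
#'   default minimises edge-induced phase bias on phantom calibration (see
#'   the methods vignette).
#' @return A `harmonic_image`: list with complex matrix `values`,
#'   `tag_direction`, `tag_frequency` (cycles/mm), `filter` descriptor and
#'   `pixel_spacing`.
#' @export
isolate_harmonic <- function(frame, tag_direction, tag_spacing,
                             pixel_spacing = 1,
                             filter_radius = 0.7 / tag_spacing) {
  f0 <- 1 / tag_spacing
  if (filter_radius >= f0) stop("filter overlaps DC")
  centre <- f0 * tag_direction
  fy <- fft_freq(nrow(frame), pixel_spacing)   # rows <-> y
  fx <- fft_freq(ncol(frame), pixel_spacing)   # cols <-> x
  dist2 <- outer((fy - centre[2])^2, (fx - centre[1])^2, `+`)
  d <- sqrt(dist2)
  H <- matrix(0, nrow(frame), ncol(frame))
  inb <- d < filter_radius
  H[inb] <- 0.5 * (1 + cos(pi * d[inb] / filter_radius))
  harm <- stats::fft(stats::fft(frame) * H, inverse = TRUE) / length(frame)
  structure(list(values = harm,
                 tag_direction = tag_direction,
                 tag_frequency = f0,
                 filter = list(center = centre, radius = filter_radius),
                 pixel_spacing = pixel_spacing),
            class = "harmonic_image")
}

#' Phase and magnitude of a harmonic image
#'
#' @param h A `harmonic_image` from [isolate_harmonic()].
#' @return Matrix of wrapped phase in `(-pi, pi]`, or magnitude (>= 0).
#' @export
harmonic_phase <- function(h) {
  wrap_phase(Arg(h$values))
}

#' @rdname harmonic_phase
#' @export
harmonic_magnitude <- function(h) Mod(h$values)

# Wrapped phase at continuous pixel positions, by bilinear interpolation of
# the complex harmonic (interpolating wrapped phase directly is invalid).
phase_at <- function(h, x_px, y_px) {
  wrap_phase(Arg(bilinear_interp(h$values, y_px, x_px)))
}

magnitude_at <- function(h, x_px, y_px) {
  Mod(bilinear_interp(h$values, y_px, x_px))
}

# Wrapped central-difference phase gradient (rad/px) of harmonic h at
# continuous positions; delta in pixels.
phase_gradient <- function(h, x_px, y_px, delta = 0.5) {
  gx <- wrap_phase(phase_at(h, x_px + delta, y_px) -
                     phase_at(h, x_px - delta, y_px)) / (2 * delta)
  gy <- wrap_phase(phase_at(h, x_px, y_px + delta) -
                     phase_at(h, x_px, y_px - delta)) / (2 * delta)
  list(gx = gx, gy = gy)
}

#' Track material points between two frames by harmonic phase invariance
#'
#' Given the pair of harmonic images (one per tag direction) at frame f and
#' at frame f+1, finds for each point the frame-f+1 position whose wrapped
#' phase pair matches the frame-f target, by Newton iteration on the
#' 2-vector of wrapped phase differences with wrapped finite-difference
#' gradients. Convergence when the Newton step falls below 0.01 pixel;
#' at most 20 iterations.
#'
#' @param h1a,h1b `harmonic_image`s at frame f for tag directions a and b.
#' @param h2a,h2b `harmonic_image`s at frame f+1.
#' @param points n x 2 matrix of positions in continuous 1-based pixel
#'   coordinates (x = column, y = row).
#' @param magnitude_floor Points whose harmonic magnitude at frame f+1 falls
#'   below this fraction of the slice maximum fail with status
#'   `"signal void"` (default 0.05).
#' @param max_step_px Steps larger than this (default: one tag period in
#'   pixels) indicate phase jumping; status `"tracking diverged"`.
#' @param start Optional n x 2 matrix of initial iterates in frame f+1
#'   (defaults to `points`); used when a better starting guess than the
#'   frame-f position is available.
#' @return List with `points` (n x 2 matrix of tracked positions) and
#'   `status` (character: `"ok"`, `"signal void"`, `"tracking diverged"`,
#'   `"no convergence"`). Failed points carry their starting position.
#' @export
track_points <- function(h1a, h1b, h2a, h2b, points,
                         magnitude_floor = 0.05,
                         max_step_px = NULL,
                         start = NULL) {
  points <- matrix(points, ncol = 2)
  n <- nrow(points)
  if (is.null(start)) start <- points
  start <- matrix(start, ncol = 2)
  sp <- h1a$pixel_spacing
  if (is.null(max_step_px)) {
    max_step_px <- (1 / h1a$tag_frequency) / sp
  }
  status <- rep("ok", n)
  t1 <- phase_at(h1a, points[, 1], points[, 2])
  t2 <- phase_at(h1b, points[, 1], points[, 2])
  floor_a <- magnitude_floor * max(harmonic_magnitude(h2a))
  floor_b <- magnitude_floor * max(harmonic_magnitude(h2b))
  void <- magnitude_at(h2a, start[, 1], start[, 2]) < floor_a |
    magnitude_at(h2b, start[, 1], start[, 2]) < floor_b
  status[void] <- "signal void"
  active <- !void
  out <- start
  for (it in seq_len(20)) {
    if (!any(active)) break
    ax <- out[active, 1]
    ay <- out[active, 2]
    r1 <- wrap_phase(phase_at(h2a, ax, ay) - t1[active])
    r2 <- wrap_phase(phase_at(h2b, ax, ay) - t2[active])
    g1 <- phase_gradient(h2a, ax, ay)
    g2 <- phase_gradient(h2b, ax, ay)
    det <- g1$gx * g2$gy - g1$gy * g2$gx
    det[abs(det) < 1e-12] <- NA
    sx <- (g2$gy * r1 - g1$gy * r2) / det
    sy <- (-g2$gx * r1 + g1$gx * r2) / det
    bad <- !is.finite(sx) | !is.finite(sy) |
      sqrt(sx^2 + sy^2) > max_step_px
    idx <- which(active)
    if (any(bad)) {
      status[idx[bad]] <- "tracking diverged"
      sx[bad] <- 0
      sy[bad] <- 0
    }
    out[idx, 1] <- out[idx, 1] - sx
    out[idx, 2] <- out[idx, 2] - sy
    conv <- sqrt(sx^2 + sy^2) < 0.01
    active[idx[bad | conv]] <- FALSE
  }
  status[active] <- "no convergence"
  out[status != "ok", ] <- start[status != "ok", , drop = FALSE]
  list(points = out, status = status)
}

#' Track a single point, raising an error on failure
#'
#' Scalar wrapper around [track_points()]: returns the tracked position or
#' stops with the failure status (`"signal void"`, `"tracking diverged"`,
#' `"no convergence"`).
#'
#' @inheritParams track_points
#' @param point Length-2 position in continuous pixel coordinates (x, y).
#' @return Length-2 tracked position.
#' @export
track_point <- function(h1a, h1b, h2a, h2b, point,
                        magnitude_floor = 0.05, max_step_px = NULL) {
  res <- track_points(h1a, h1b, h2a, h2b, matrix(point, 1, 2),
                      magnitude_floor = magnitude_floor,
                      max_step_px = max_step_px)
  if (res$status[1] != "ok") stop(res$status[1])
  drop(res$points)
}
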