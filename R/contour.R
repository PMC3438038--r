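# Midwall contour initialisation and tracking. A contour is an ordered,
# closed ring of landmarks at a fixed angular step (default 5 degrees, 72
# points) on the mid-myocardial line; landmark positions are stored in mm
# relative to the image centre.

# Centre of the image grid in 1-based pixel coordinates (x = col, y = row).
grid_centre_px <- function(mask) {
  c((ncol(mask) + 1) / 2, (nrow(mask) + 1) / 2)
}

mm_to_px <- function(xy_mm, mask, pixel_spacing) {
  ctr <- grid_centre_px(mask)
  cbind(xy_mm[, 1] / pixel_spacing + ctr[1],
        xy_mm[, 2] / pixel_spacing + ctr[2])
}

px_to_mm <- function(xy_px, mask, pixel_spacing) {
  ctr <- grid_centre_px(mask)
  cbind((xy_px[, 1] - ctr[1]) * pixel_spacing,
        (xy_px[, 2] - ctr[2]) * pixel_spacing)
}

# Cast a ray from centre_px at `angle_deg` and return the endo/epi crossing
# radii (mm) of the first contiguous myocardial run, or NULL if the ray
# never crosses the wall.
ray_crossings <- function(mask, centre_px, angle_deg, pixel_spacing,
                          step_px = 0.25) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  rmax <- max(nr, nc) * 0.75
  radii <- seq(step_px, rmax, by = step_px)
  ca <- cos(angle_deg * pi / 180)
  sa <- sin(angle_deg * pi / 180)
  col <- round(centre_px[1] + radii * ca)
  row <- round(centre_px[2] + radii * sa)
  keep <- row >= 1 & row <= nr & col >= 1 & col <= nc
  radii <- radii[keep]
  vals <- mask[cbind(row[keep], col[keep])]
  idx <- which(vals)
  if (!length(idx)) return(NULL)
  gaps <- which(diff(idx) > 1)
  last <- if (length(gaps)) idx[gaps[1]] else idx[length(idx)]
  c(endo = radii[idx[1]] * pixel_spacing,
    epi = radii[last] * pixel_spacing)
}

#' Initialise a midwall contour from an annular mask
#'
#' For each angle (default every 5 degrees, 72 landmarks), casts a ray from
#' the myocardial centroid and places the landmark midway between the endo-
#' and epicardial boundary crossings. The result is a closed, clockwise-
#' ordered ring anchored at frame 1 (end-diastole).
#'
#' @param mask Logical annular myocardium matrix (rows x cols).
#' @param angular_step Angular landmark spacing, degrees.
#' @param pixel_spacing Pixel size, mm.
#' @return A `contour_track`: list with `angles_deg`, `positions`
#'   (n_points x 2 x n_frames array, mm relative to image centre; one frame
#'   here), `frame_times` (NULL until tracked), `flags`, `pixel_spacing`,
#'   `reference_frame = 1`.
#' @export
init_midwall_contour <- function(mask, angular_step = 5, pixel_spacing = 1) {
  if (!any(mask)) stop("open myocardium")
  ij <- which(mask, arr.ind = TRUE)
  centre_px <- c(mean(ij[, 2]), mean(ij[, 1]))
  angles <- seq(0, 360 - angular_step, by = angular_step)
  pos <- matrix(NA_real_, length(angles), 2)
  for (k in seq_along(angles)) {
    cr <- ray_crossings(mask, centre_px, angles[k], pixel_spacing)
    if (is.null(cr)) stop("open myocardium")
    rmid_px <- mean(cr) / pixel_spacing
    pos[k, ] <- c(centre_px[1] + rmid_px * cos(angles[k] * pi / 180),
                  centre_px[2] + rmid_px * sin(angles[k] * pi / 180))
  }
  pos_mm <- px_to_mm(pos, mask, pixel_spacing)
  positions <- array(pos_mm, c(length(angles), 2, 1))
  structure(list(angles_deg = angles,
                 positions = positions,
                 frame_times = NULL,
                 flags = matrix(FALSE, length(angles), 1),
                 pixel_spacing = pixel_spacing,
                 reference_frame = 1L),
            class = "contour_track")
}

# Circular interpolation of failed landmark positions from their nearest
# valid angular neighbours.
interp_failed <- function(pos, ok) {
  n <- nrow(pos)
  if (all(ok)) return(pos)
  if (!any(ok)) stop("track quality")
  idx_ok <- which(ok)
  for (j in which(!ok)) {
    before <- idx_ok[(j - idx_ok) %% n == min((j - idx_ok) %% n)][1]
    after <- idx_ok[(idx_ok - j) %% n == min((idx_ok - j) %% n)][1]
    db <- (j - before) %% n
    da <- (after - j) %% n
    w <- if (db + da == 0) 0.5 else da / (db + da)
    pos[j, ] <- w * pos[before, ] + (1 - w) * pos[after, ]
  }
  pos
}

#' Track a midwall contour through all frames
#'
#' Sequential frame-to-frame HARP tracking of every landmark using the two
#' orthogonal tag-direction series. Landmarks whose tracking fails in a
#' frame are interpolated circularly from their angular neighbours and
#' flagged; if more than `max_fail_frac` of landmarks fail in any single
#' frame the track is rejected.
#'
#' @param series_a,series_b `tagged_series` for the two tag directions,
#'   covering identical frames.
#' @param contour A `contour_track` from [init_midwall_contour()].
#' @param filter_radius Band-pass radius passed to [isolate_harmonic()].
#' @param magnitude_floor Passed to [track_points()].
#' @param max_fail_frac Maximum tolerated fraction of failed landmarks per
#'   frame (default 0.25); exceeding it raises `"track quality"`.
#' @return The `contour_track` with `positions` extended to all frames,
#'   per-landmark-per-frame `flags`, `frame_times`, and `n_flagged`.
#' @export
track_contour <- function(series_a, series_b, contour,
                          filter_radius = 0.7 / series_a$tag_spacing,
                          magnitude_floor = 0.05,
                          max_fail_frac = 0.25) {
  if (!isTRUE(all.equal(series_a$frame_times, series_b$frame_times))) {
    stop("tag-direction series must cover identical frames")
  }
  n_frames <- dim(series_a$images)[3]
  n_pts <- nrow(contour$positions[, , 1, drop = FALSE])
  sp <- series_a$pixel_spacing
  harm <- function(series, f) {
    isolate_harmonic(series$images[, , f], series$tag_direction,
                     series$tag_spacing, sp, filter_radius)
  }
  ha <- lapply(seq_len(n_frames), function(f) harm(series_a, f))
  hb <- lapply(seq_len(n_frames), function(f) harm(series_b, f))
  mask_dummy <- series_a$images[, , 1]
  positions <- array(NA_real_, c(n_pts, 2, n_frames))
  positions[, , 1] <- contour$positions[, , 1]
  flags <- matrix(FALSE, n_pts, n_frames)
  ref_px <- mm_to_px(positions[, , 1], mask_dummy, sp)
  cur_px <- ref_px
  for (f in seq_len(n_frames - 1)) {
    # frame-to-frame step keeps the motion below half a tag period ...
    res <- track_points(ha[[f]], hb[[f]], ha[[f + 1]], hb[[f + 1]],
                        cur_px, magnitude_floor = magnitude_floor)
    ok <- res$status == "ok"
    if (mean(!ok) > max_fail_frac) stop("track quality")
    new_px <- interp_failed(res$points, ok)
    # ... then the position is refined against the end-diastolic reference
    # phase, so interpolation bias does not accumulate across frames
    ref <- track_points(ha[[1]], hb[[1]], ha[[f + 1]], hb[[f + 1]],
                        ref_px, magnitude_floor = magnitude_floor,
                        start = new_px)
    keep <- ok & ref$status == "ok"
    new_px[keep, ] <- ref$points[keep, , drop = FALSE]
    flags[!ok, f + 1] <- TRUE
    positions[, , f + 1] <- px_to_mm(new_px, mask_dummy, sp)
    cur_px <- new_px
  }
  contour$positions <- positions
  contour$flags <- flags
  contour$frame_times <- series_a$frame_times
  contour$n_flagged <- sum(flags)
  contour
}

#' @export
print.contour_track <- function(x, ...) {
  cat(sprintf("Midwall contour: %d landmarks (%g deg step), %d frame(s), %d flagged\n",
              length(x$angles_deg), diff(x$angles_deg[1:2]),
              dim(x$positions)[3], sum(x$flags)))
  invisible(x)
}

#' Export a tracked contour as a data frame
#'
#' One row per landmark per frame: `slice`, `frame`, `time_ms`,
#' `angle_deg`, `x_mm`, `y_mm`, `flag`.
#'
#' @param track A tracked `contour_track`.
#' @param slice Slice index recorded in the output.
#' @return A data frame.
#' @export
contour_to_df <- function(track, slice = 1L) {
  n_f <- dim(track$positions)[3]
  times <- if (is.null(track$frame_times)) rep(NA_real_, n_f) else
    track$frame_times
  do.call(rbind, lapply(seq_len(n_f), function(f) {
    data.frame(slice = slice, frame = f, time_ms = times[f],
               angle_deg = track$angles_deg,
               x_mm = track$positions[, 1, f],
               y_mm = track$positions[, 2, f],
               flag = track$flags[, f])
  }))
}
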