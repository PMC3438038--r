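# Phantom configuration: a full generative description of one synthetic
# subject (geometry, motion, tissue contrast, noise).

#' Configure a synthetic left-ventricular phantom
#'
#' Describes one synthetic subject: a cylindrical LV annulus on a square
#' pixel grid, an analytic contraction pattern prescribing per-sector
#' circumferential shortening (csh) with per-sector timing delays, line-tag
#' parameters for two orthogonal tag directions, and the tissue layout
#' (transmural edema arc on T2-weighted slices with a nested necrosis arc on
#' LGE slices) plus signal and noise levels.
#'
#' Angles are in degrees, increasing clockwise as viewed from the apex with
#' 0 deg at the anterior junction of the right and left ventricle; sector
#' `s` covers `[(s-1)*60, s*60)` degrees, sectors S1..S6. Frames are
#' 1-based; frame 1 is end-diastole (the undeformed reference) and
#' `avc_frame` is the frame of aortic valve closure (end-systole).
#'
#' @param grid_size Pixels per side of the square image grid.
#' @param pixel_spacing In-plane pixel size, mm.
#' @param n_slices Number of short-axis slices (8--11 typical).
#' @param slice_thickness Slice thickness, mm.
#' @param endo_radius,epi_radius Endo- and epicardial radii at end-diastole, mm.
#' @param n_frames Number of cine frames.
#' @param frame_interval Temporal resolution, ms.
#' @param avc_frame 1-based frame index of aortic valve closure.
#' @param tag_spacing Tag line period, mm.
#' @param tag_directions List of two orthonormal 2-vectors (x, y components).
#' @param sector_amplitudes Peak csh per sector S1..S6, percent.
#' @param sector_delays Activation delay per sector, ms (>= 0).
#' @param post_systolic_fraction Fraction of the peak amplitude added as a
#'   post-systolic shortening bump in sectors whose centre lies inside
#'   `necrosis_arc` (0 disables).
#' @param edema_arc `c(start, end)` degrees of the transmural edema arc.
#' @param necrosis_arc `c(start, end)` degrees; must be nested in `edema_arc`.
#' @param signal_levels List with `remote_mean`, `remote_sd`, `edema_mean`,
#'   `necrosis_mean` (arbitrary intensity units).
#' @param noise_sd Gaussian noise SD added to rendered images, intensity units.
#' @param center_offset In-plane rigid offset of the whole phantom, mm `c(x, y)`.
#' @param seed Integer seed; all rendering noise derives from it.
#' @return An object of class `phantom_config` (a validated list).
#' @export
#' @examples
#' cfg <- phantom_config(noise_sd = 0)
#' cfg$epi_radius
phantom_config <- function(grid_size = 108,
                           pixel_spacing = 1,
                           n_slices = 9,
                           slice_thickness = 8,
                           endo_radius = 20,
                           epi_radius = 30,
                           n_frames = 20,
                           frame_interval = 45,
                           avc_frame = 9,
                           tag_spacing = 6,
                           tag_directions = list(c(1, 0), c(0, 1)),
                           sector_amplitudes = rep(15, 6),
                           sector_delays = rep(0, 6),
                           post_systolic_fraction = 0,
                           edema_arc = c(0, 207),
                           necrosis_arc = c(0, 108),
                           signal_levels = list(remote_mean = 100,
                                                remote_sd = 10,
                                                edema_mean = 160,
                                                necrosis_mean = 200),
                           noise_sd = 0,
                           center_offset = c(0, 0),
                           seed = 1L) {
  cfg <- structure(
    list(grid_size = as.integer(grid_size),
         pixel_spacing = pixel_spacing,
         n_slices = as.integer(n_slices),
         slice_thickness = slice_thickness,
         endo_radius = endo_radius,
         epi_radius = epi_radius,
         n_frames = as.integer(n_frames),
         frame_interval = frame_interval,
         avc_frame = as.integer(avc_frame),
         tag_spacing = tag_spacing,
         tag_directions = lapply(tag_directions, as.numeric),
         sector_amplitudes = as.numeric(sector_amplitudes),
         sector_delays = as.numeric(sector_delays),
         post_systolic_fraction = post_systolic_fraction,
         edema_arc = as.numeric(edema_arc),
         necrosis_arc = as.numeric(necrosis_arc),
         signal_levels = signal_levels,
         noise_sd = noise_sd,
         center_offset = as.numeric(center_offset),
         seed = as.integer(seed)),
    class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

#' Validate a phantom configuration
#'
#' Checks the structural invariants of a [phantom_config()]: positive
#' geometry with `endo_radius < epi_radius`, `avc_frame` within the frame
#' range, non-negative sector amplitudes and delays, orthonormal tag
#' directions, and `necrosis_arc` nested inside `edema_arc`.
#'
#' @param cfg A `phantom_config`.
#' @return `cfg`, invisibly, if valid; otherwise an error of class
#'   `tagsync_validation_error`.
#' @export
validate_phantom_config <- function(cfg) {
  fail <- function(msg) {
    stop(structure(class = c("tagsync_validation_error", "error", "condition"),
                   list(message = msg, call = NULL)))
  }
  if (cfg$grid_size < 16) fail("grid_size too small")
  if (cfg$pixel_spacing <= 0) fail("pixel_spacing must be positive")
  if (cfg$endo_radius <= 0 || cfg$endo_radius >= cfg$epi_radius) {
    fail("requires 0 < endo_radius < epi_radius")
  }
  if (cfg$n_frames < 2) fail("need at least 2 frames")
  if (cfg$avc_frame < 1 || cfg$avc_frame > cfg$n_frames) {
    fail("avc_frame outside 1..n_frames")
  }
  if (cfg$frame_interval <= 0) fail("frame_interval must be positive")
  if (length(cfg$sector_amplitudes) != 6 || any(cfg$sector_amplitudes < 0)) {
    fail("sector_amplitudes must be 6 non-negative values")
  }
  if (length(cfg$sector_delays) != 6 || any(cfg$sector_delays < 0)) {
    fail("sector_delays must be 6 non-negative values (frame 1 is the reference)")
  }
  if (any(cfg$sector_amplitudes >= 100)) fail("sector amplitudes must be < 100%")
  if (length(cfg$tag_directions) != 2) fail("exactly two tag directions required")
  e1 <- cfg$tag_directions[[1]]
  e2 <- cfg$tag_directions[[2]]
  if (abs(sum(e1^2) - 1) > 1e-8 || abs(sum(e2^2) - 1) > 1e-8 ||
      abs(sum(e1 * e2)) > 1e-8) {
    fail("tag_directions must be orthonormal unit 2-vectors")
  }
  for (arc in list(cfg$edema_arc, cfg$necrosis_arc)) {
    if (arc_width(arc) < 0 || arc_width(arc) > 360) {
      fail("tissue arcs must have width in [0, 360] degrees")
    }
  }
  if (!arc_contains(cfg$edema_arc, cfg$necrosis_arc)) {
    fail("necrosis_arc must be nested within edema_arc")
  }
  if (cfg$noise_sd < 0) fail("noise_sd must be non-negative")
  if (cfg$post_systolic_fraction < 0 || cfg$post_systolic_fraction > 1) {
    fail("post_systolic_fraction must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Phantom preset emulating an acute anterior infarct
#'
#' Convenience wrapper around [phantom_config()]: hypokinetic, delayed
#' sectors under the necrosis arc (S1--S2), intermediate shortening in the
#' edematous-but-viable sector (S3--S4 portion of the edema arc), normal
#' shortening elsewhere, and a post-systolic component in infarcted sectors.
#'
#' @param ... Overrides passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
infarct_phantom <- function(...) {
  phantom_config(
    sector_amplitudes = c(5, 5, 10, 12, 15, 15),
    sector_delays = c(90, 90, 45, 0, 0, 0),
    post_systolic_fraction = 0.25,
    edema_arc = c(0, 207),
    necrosis_arc = c(0, 108),
    ...)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("Synthetic LV phantom configuration\n")
  cat(sprintf("  grid: %d x %d px @ %.2f mm, %d slices x %.1f mm\n",
              x$grid_size, x$grid_size, x$pixel_spacing, x$n_slices,
              x$slice_thickness))
  cat(sprintf("  annulus: endo %.1f / epi %.1f mm; tags every %.1f mm\n",
              x$endo_radius, x$epi_radius, x$tag_spacing))
  cat(sprintf("  %d frames @ %.0f ms, AVC at frame %d (%.0f ms)\n",
              x$n_frames, x$frame_interval, x$avc_frame,
              (x$avc_frame - 1) * x$frame_interval))
  cat(sprintf("  peak csh per sector [%%]: %s\n",
              paste(format(x$sector_amplitudes), collapse = " ")))
  cat(sprintf("  delays [ms]: %s\n",
              paste(format(x$sector_delays), collapse = " ")))
  cat(sprintf("  edema arc %g..%g deg; necrosis arc %g..%g deg; noise sd %g\n",
              x$edema_arc[1], x$edema_arc[2], x$necrosis_arc[1],
              x$necrosis_arc[2], x$noise_sd))
  invisible(x)
}
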