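# Renderers: tagged cine series, deforming cine masks, and the T2w/LGE
# tissue study. All images are matrices indexed [row, col]; the physical x
# axis runs along columns and y along rows, with the origin at the grid
# centre. Intensities are arbitrary units; noise is Gaussian on magnitude
# images (a simplification of Rician noise, adequate at the SNRs used).

# mm coordinates of every pixel centre relative to the phantom centre
# (grid centre plus the configured rigid offset).
pixel_grid_mm <- function(cfg) {
  ax <- pixel_axis_mm(cfg$grid_size, cfg$pixel_spacing)
  list(x = matrix(ax, cfg$grid_size, cfg$grid_size, byrow = TRUE) -
         cfg$center_offset[1],
       y = matrix(ax, cfg$grid_size, cfg$grid_size) - cfg$center_offset[2])
}

#' Render a tagged cine series for one slice and tag direction
#'
#' Simulates a 1-1 SPAMM line-tag pattern imprinted at end-diastole and
#' carried by the phantom motion: the intensity at image position y in
#' frame f is `baseline * (1 + cos(2*pi * e . X(y, f) / tag_spacing)) / 2`
#' inside the deformed myocardium, where `X(y, f)` is the reference-frame
#' position obtained through the analytic inverse of the motion model, and
#' near zero outside. Gaussian noise with SD `noise_sd` is added.
#' Reproducible given the configuration seed.
#'
#' @param cfg A [phantom_config()].
#' @param slice 1-based slice index (slices share in-plane geometry).
#' @param tag_direction One of `cfg$tag_directions`.
#' @return A `tagged_series`: list with `images` (rows x cols x frames),
#'   `pixel_spacing`, `frame_times` (ms), `tag_direction`, `tag_spacing`.
#' @export
render_tagged_series <- function(cfg, slice = 1,
                                 tag_direction = cfg$tag_directions[[1]]) {
  if (cfg$tag_spacing <= 2 * cfg$pixel_spacing) stop("tags unresolvable")
  dir_idx <- which(vapply(cfg$tag_directions, function(e) {
    sum(abs(e - tag_direction)) < 1e-9
  }, logical(1)))
  if (length(dir_idx) != 1) {
    stop("tag_direction must be one of cfg$tag_directions")
  }
  if (slice < 1 || slice > cfg$n_slices) stop("slice outside 1..n_slices")
  g <- pixel_grid_mm(cfg)
  rho <- sqrt(g$x^2 + g$y^2)
  phi <- atan2(g$y, g$x) %% (2 * pi)
  e <- tag_direction
  base <- cfg$signal_levels$remote_mean
  imgs <- array(0, c(cfg$grid_size, cfg$grid_size, cfg$n_frames))
  for (f in seq_len(cfg$n_frames)) {
    ref <- invert_motion(cfg, rho, phi, f)
    inside <- ref$r >= cfg$endo_radius & ref$r <= cfg$epi_radius
    X1 <- ref$r * cos(ref$theta)
    X2 <- ref$r * sin(ref$theta)
    tag <- base * (1 + cos(2 * pi * (e[1] * X1 + e[2] * X2) /
                             cfg$tag_spacing)) / 2
    frame <- matrix(0, cfg$grid_size, cfg$grid_size)
    frame[inside] <- tag[inside]
    imgs[, , f] <- frame
  }
  if (cfg$noise_sd > 0) {
    imgs <- imgs + with_seed(
      derive_seed(cfg$seed, 7919 * slice + dir_idx),
      array(stats::rnorm(length(imgs), sd = cfg$noise_sd), dim(imgs)))
  }
  structure(list(images = imgs,
                 pixel_spacing = cfg$pixel_spacing,
                 frame_times = (seq_len(cfg$n_frames) - 1) * cfg$frame_interval,
                 tag_direction = tag_direction,
                 tag_spacing = cfg$tag_spacing),
            class = "tagged_series")
}

#' Render deforming endo- and epicardial masks for all frames and slices
#'
#' Binary masks of the deforming annulus, the programmatic stand-in for
#' manually delineated endo- and epicardial borders. `endo` is the cavity
#' disc, `epi` the full epicardial disc; the myocardium is `epi & !endo`.
#'
#' @param cfg A [phantom_config()].
#' @return List with logical arrays `endo` and `epi` of dimension
#'   rows x cols x n_slices x n_frames, plus spacing metadata.
#' @export
render_cine_masks <- function(cfg) {
  g <- pixel_grid_mm(cfg)
  rho <- sqrt(g$x^2 + g$y^2)
  phi <- atan2(g$y, g$x) %% (2 * pi)
  n <- cfg$grid_size
  endo <- array(FALSE, c(n, n, cfg$n_slices, cfg$n_frames))
  epi <- array(FALSE, c(n, n, cfg$n_slices, cfg$n_frames))
  for (f in seq_len(cfg$n_frames)) {
    ref <- invert_motion(cfg, rho, phi, f)
    cav <- ref$r < cfg$endo_radius
    disc <- ref$r <= cfg$epi_radius
    for (s in seq_len(cfg$n_slices)) {
      endo[, , s, f] <- cav
      epi[, , s, f] <- disc
    }
  }
  list(endo = endo, epi = epi,
       pixel_spacing = cfg$pixel_spacing,
       slice_thickness = cfg$slice_thickness,
       frame_times = (seq_len(cfg$n_frames) - 1) * cfg$frame_interval)
}

#' Render the T2-weighted and LGE tissue study
#'
#' Produces end-diastolic T2w slices (basal, midventricular, apical) in
#' which the transmural edema arc is hyperintense, an LGE stack covering
#' every slice in which the nested necrosis arc is hyperenhanced, the
#' annular myocardial masks, and a remote-tissue ROI placed at the centre
#' of the unaffected circumference.
#'
#' @param cfg A [phantom_config()].
#' @return A `tissue_study`: list with `t2w_slices` (rows x cols x 3),
#'   `lge_slices` (rows x cols x n_slices), `myocardial_mask` (logical
#'   matrix, identical across slices), `remote_roi` (logical matrix),
#'   `t2w_slice_index`, `slice_positions` (mm), `pixel_spacing`.
#' @export
render_tissue_maps <- function(cfg) {
  sl <- cfg$signal_levels
  if (sl$edema_mean <= sl$remote_mean + 2 * sl$remote_sd) {
    stop("edema signal must exceed remote mean + 2 SD")
  }
  if (sl$necrosis_mean <= sl$remote_mean + 2 * sl$remote_sd) {
    stop("necrosis signal must exceed remote mean + 2 SD")
  }
  g <- pixel_grid_mm(cfg)
  r <- sqrt(g$x^2 + g$y^2)
  ang <- angle_deg(g$x, g$y)
  myo <- r >= cfg$endo_radius & r <= cfg$epi_radius
  edema <- myo & in_arc(ang, cfg$edema_arc)
  necro <- myo & in_arc(ang, cfg$necrosis_arc)

  t2w_base <- matrix(0, cfg$grid_size, cfg$grid_size)
  t2w_base[myo] <- sl$remote_mean
  t2w_base[edema] <- sl$edema_mean
  lge_base <- matrix(0, cfg$grid_size, cfg$grid_size)
  lge_base[myo] <- sl$remote_mean
  lge_base[necro] <- sl$necrosis_mean

  # Remote ROI: middle 60 degrees of the circumference not covered by edema.
  free <- 360 - arc_width(cfg$edema_arc)
  if (free < 60) stop("no remote circumference left for the reference ROI")
  roi_start <- (cfg$edema_arc[2] %% 360) + free / 2 - 30
  remote_roi <- myo & in_arc(ang, c(roi_start, roi_start + 60))

  t2w_idx <- unique(c(1L, as.integer(ceiling(cfg$n_slices / 2)), cfg$n_slices))
  t2w <- array(0, c(cfg$grid_size, cfg$grid_size, length(t2w_idx)))
  lge <- array(0, c(cfg$grid_size, cfg$grid_size, cfg$n_slices))
  for (k in seq_along(t2w_idx)) t2w[, , k] <- t2w_base
  for (s in seq_len(cfg$n_slices)) lge[, , s] <- lge_base
  if (cfg$noise_sd > 0) {
    t2w <- t2w + with_seed(derive_seed(cfg$seed, 31L),
      array(stats::rnorm(length(t2w), sd = cfg$noise_sd), dim(t2w)))
    lge <- lge + with_seed(derive_seed(cfg$seed, 37L),
      array(stats::rnorm(length(lge), sd = cfg$noise_sd), dim(lge)))
  }
  structure(list(t2w_slices = t2w,
                 lge_slices = lge,
                 myocardial_mask = myo,
                 remote_roi = remote_roi,
                 t2w_slice_index = t2w_idx,
                 slice_positions = (seq_len(cfg$n_slices) - 1) *
                   cfg$slice_thickness,
                 pixel_spacing = cfg$pixel_spacing),
            class = "tissue_study")
}
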