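# Analytic motion model of the phantom.
#
# The deformation is prescribed in polar coordinates about the LV axis. Each
# 60-degree sector s carries a circumferential stretch
#   lambda_s(t) = 1 - csh_s(t)/100,
# where csh_s(t) is a raised-cosine activation reaching its peak amplitude
# at the time of aortic valve closure plus the sector's delay. A material
# point at reference angle theta and radius r maps to
#   phi(theta, t)  = (1/lbar) * integral_0^theta lambda(u, t) du
#   rho(r, theta, t)^2 = (R_m lbar)^2 + (lbar/lambda) (r^2 - R_m^2)
# with R_m the midwall radius and lbar the circumferential mean of lambda.
# The map conserves local area exactly (d(rho^2)/d(r^2) * dphi/dtheta = 1),
# so contraction is accompanied by wall thickening, and the arc length of a
# material sector at the midwall is exactly lambda_s(t) times its reference
# length -- the ground-truth csh is known in closed form.

sector_of_angle <- function(angle_deg) {
  (floor((angle_deg %% 360) / 60) %% 6) + 1
}

# Base activation time course g0(tau) in [0, 1]: raised-cosine rise from 0
# at tau = 0 to 1 at tau = t_peak, then raised-cosine fall back to 0 at
# tau = t_peak + t_fall. Delayed sectors follow g0(t - delay), i.e. an exact
# time shift of the base curve.
activation_base <- function(tau, t_peak, t_fall) {
  g <- numeric(length(tau))
  rise <- tau > 0 & tau <= t_peak
  g[rise] <- 0.5 * (1 - cos(pi * tau[rise] / t_peak))
  if (t_fall > 0) {
    fall <- tau > t_peak & tau < t_peak + t_fall
    g[fall] <- 0.5 * (1 + cos(pi * (tau[fall] - t_peak) / t_fall))
  } else {
    g[tau >= t_peak] <- 1
  }
  g
}

# Post-systolic bump: raised-cosine lobe peaking at t_peak + 0.35 * t_fall.
post_systolic_bump <- function(tau, t_peak, t_fall) {
  if (t_fall <= 0) return(numeric(length(tau)))
  centre <- t_peak + 0.35 * t_fall
  half <- 0.35 * t_fall
  b <- numeric(length(tau))
  inside <- abs(tau - centre) < half
  b[inside] <- 0.5 * (1 + cos(pi * (tau[inside] - centre) / half))
  b
}

# Which sectors receive the post-systolic component: those whose centre
# angle falls in the necrosis arc.
infarct_sectors <- function(cfg) {
  centres <- (0:5) * 60 + 30
  which(vapply(centres, in_arc, logical(1), arc = cfg$necrosis_arc))
}

#' Prescribed circumferential shortening of each sector
#'
#' Evaluates the phantom's analytic ground-truth csh (percent) for every
#' sector at time `t_ms` after end-diastole.
#'
#' @param cfg A [phantom_config()].
#' @param t_ms Time after end-diastole, ms (scalar).
#' @return Numeric vector of 6 csh values in percent.
#' @export
prescribed_csh <- function(cfg, t_ms) {
  t_peak <- (cfg$avc_frame - 1) * cfg$frame_interval
  t_end <- (cfg$n_frames - 1) * cfg$frame_interval
  t_fall <- t_end - t_peak
  tau <- t_ms - cfg$sector_delays
  g <- activation_base(tau, t_peak, t_fall)
  csh <- cfg$sector_amplitudes * g
  if (cfg$post_systolic_fraction > 0) {
    inf <- infarct_sectors(cfg)
    if (length(inf)) {
      b <- post_systolic_bump(tau[inf], t_peak, t_fall)
      csh[inf] <- csh[inf] +
        cfg$post_systolic_fraction * cfg$sector_amplitudes[inf] * b
    }
  }
  csh
}

# Per-sector circumferential stretch at time t (6-vector).
sector_stretch <- function(cfg, t_ms) {
  1 - prescribed_csh(cfg, t_ms) / 100
}

midwall_radius <- function(cfg) (cfg$endo_radius + cfg$epi_radius) / 2

# Deformed angle phi (rad) of reference angle theta (rad) given the sector
# stretches; piecewise-linear in theta, hence exactly invertible.
deformed_angle <- function(theta, lambda) {
  lbar <- mean(lambda)
  cum <- c(0, cumsum(lambda) * pi / 3)
  th <- theta %% (2 * pi)
  s <- pmin(floor(th / (pi / 3)), 5) + 1
  (cum[s] + lambda[s] * (th - (s - 1) * pi / 3)) / lbar
}

# Inverse of deformed_angle: reference theta (rad) of image angle phi (rad).
reference_angle <- function(phi, lambda) {
  lbar <- mean(lambda)
  cum <- c(0, cumsum(lambda) * pi / 3)
  bounds <- cum / lbar
  ph <- phi %% (2 * pi)
  s <- findInterval(ph, bounds, rightmost.closed = TRUE)
  s <- pmin(pmax(s, 1), 6)
  (s - 1) * pi / 3 + (ph * lbar - cum[s]) / lambda[s]
}

#' Displacement of a material point under the phantom motion model
#'
#' Forward map: given reference polar coordinates (angle, radius) of a
#' material point, returns its in-plane displacement at a given frame.
#' Deterministic in the configuration; frame 1 returns zero everywhere.
#' Angles outside [0, 360) are wrapped.
#'
#' @param cfg A [phantom_config()].
#' @param angle_deg Reference angle(s), degrees.
#' @param radius_mm Reference radius(-i), mm.
#' @param frame 1-based frame index (`<= n_frames`).
#' @return An n x 2 matrix of (dx, dy) displacements in mm.
#' @export
#' @examples
#' cfg <- phantom_config()
#' motion_displacement(cfg, 45, 25, 1)   # end-diastole: zero
motion_displacement <- function(cfg, angle_deg, radius_mm, frame) {
  if (frame < 1 || frame > cfg$n_frames) stop("frame outside 1..n_frames")
  n <- max(length(angle_deg), length(radius_mm))
  angle_deg <- rep_len(angle_deg, n)
  radius_mm <- rep_len(radius_mm, n)
  t_ms <- (frame - 1) * cfg$frame_interval
  lambda <- sector_stretch(cfg, t_ms)
  lbar <- mean(lambda)
  theta <- (angle_deg %% 360) * pi / 180
  s <- sector_of_angle(angle_deg)
  phi <- deformed_angle(theta, lambda)
  rm <- midwall_radius(cfg)
  rho2 <- (rm * lbar)^2 + (lbar / lambda[s]) * (radius_mm^2 - rm^2)
  rho <- sqrt(pmax(rho2, 0))
  cbind(dx = rho * cos(phi) - radius_mm * cos(theta),
        dy = rho * sin(phi) - radius_mm * sin(theta))
}

# Inverse map: image-space polar (rho, phi in rad) -> reference (r, theta).
# Used by the renderers to paint tag patterns and masks without iteration.
invert_motion <- function(cfg, rho, phi, frame) {
  t_ms <- (frame - 1) * cfg$frame_interval
  lambda <- sector_stretch(cfg, t_ms)
  lbar <- mean(lambda)
  theta <- reference_angle(phi, lambda)
  s <- sector_of_angle(theta * 180 / pi)
  rm <- midwall_radius(cfg)
  r2 <- rm^2 + (lambda[s] / lbar) * (rho^2 - (rm * lbar)^2)
  list(r = sqrt(pmax(r2, 0)), theta = theta)
}

#' Ground-truth csh of every sector at every frame
#'
#' Convenience wrapper returning the analytic csh (percent) as a 6 x
#' `n_frames` matrix, for comparison with HARP-tracked values.
#'
#' @param cfg A [phantom_config()].
#' @return 6 x n_frames matrix of csh in percent; column 1 is zero.
#' @export
ground_truth_csh <- function(cfg) {
  t <- (seq_len(cfg$n_frames) - 1) * cfg$frame_interval
  vapply(t, function(tt) prescribed_csh(cfg, tt), numeric(6))
}
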