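# Shared fixtures: compact phantoms that keep unit tests fast, plus an
# independent numeric arc-length oracle for the motion model.

small_phantom <- function(...) {
  args <- list(grid_size = 72, endo_radius = 16, epi_radius = 26,
               n_frames = 10, avc_frame = 6, tag_spacing = 6, noise_sd = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(phantom_config, args)
}

# Numeric arc-length csh oracle: deform a densely sampled midwall arc with
# motion_displacement() and integrate its polyline length, independently of
# the closed-form stretch used inside the model.
numeric_sector_csh <- function(cfg, sector, frame, n = 4001,
                               radius = (cfg$endo_radius + cfg$epi_radius) / 2) {
  th <- seq((sector - 1) * 60, sector * 60, length.out = n)
  p0 <- cbind(radius * cos(th * pi / 180), radius * sin(th * pi / 180))
  p <- p0 + motion_displacement(cfg, th, radius, frame)
  len <- function(q) sum(sqrt(rowSums(diff(q)^2)))
  100 * (len(p0) - len(p)) / len(p0)
}

# Uniform synchronous strain field: every segment follows the same
# raised-cosine time course peaking at `peak` percent at the AVC frame.
uniform_field <- function(n_slices = 9, n_frames = 10, avc = 8, peak = 15) {
  tt <- seq_len(n_frames) - 1
  course <- peak * 0.5 * (1 - cos(pi * pmin(tt / (avc - 1), 1)))
  csh <- array(rep(course, each = n_slices * 6), c(n_slices, 6, n_frames))
  strain_field(csh, tt * 45, avc)
}

# Pure first-spatial-harmonic field with zero spatial mean at every frame.
harmonic_field <- function(n_slices = 9, n_frames = 10, avc = 8, amp = 10) {
  tt <- seq_len(n_frames) - 1
  a <- amp * 0.5 * (1 - cos(pi * pmin(tt / (avc - 1), 1)))
  csh <- array(0, c(n_slices, 6, n_frames))
  pattern <- cos(2 * pi * (0:5) / 6)
  for (f in seq_len(n_frames)) {
    for (s in seq_len(n_slices)) csh[s, , f] <- a[f] * pattern
  }
  strain_field(csh, tt * 45, avc)
}

# Random strain field (frame 1 zero) for property tests.
random_field <- function(n_slices = 9, n_frames = 10, avc = 8) {
  csh <- array(stats::rnorm(n_slices * 6 * n_frames, 8, 4),
               c(n_slices, 6, n_frames))
  csh[, , 1] <- 0
  strain_field(csh, (seq_len(n_frames) - 1) * 45, avc)
}

# Direct-DFT brute-force CURE oracle, written independently of cure_index.
cure_oracle <- function(field, frames = seq(2, field$avc_frame)) {
  d <- dim(field$csh)
  a0 <- 0; a1 <- 0
  for (sl in seq_len(d[1])) {
    for (f in frames) {
      x <- field$csh[sl, , f]
      j <- 0:(length(x) - 1)
      c0 <- sum(x * exp(-2i * pi * 0 * j / length(x))) / length(x)
      c1 <- sum(x * exp(-2i * pi * 1 * j / length(x))) / length(x)
      a0 <- a0 + Mod(c0)^2
      a1 <- a1 + Mod(c1)^2
    }
  }
  sqrt(a0 / (a0 + a1))
}
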