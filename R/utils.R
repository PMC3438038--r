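# Shared numeric helpers. All phase arithmetic in the package is routed
# through wrap_phase() so that wrapped differences are handled in one place.

#' Wrap an angle in radians to (-pi, pi]
#'
#' All HARP phase arithmetic goes through this single utility, so that
#' `wrap_phase(a - b)` is invariant to adding multiples of 2*pi to either
#' argument.
#'
#' @param x Numeric vector of angles in radians.
#' @return Numeric vector with every element in `(-pi, pi]`.
#' @export
#' @examples
#' wrap_phase(3 * pi / 2)   # -pi/2
#' wrap_phase(pi)           # pi (boundary maps to +pi)
wrap_phase <- function(x) {
  pi - ((pi - x) %% (2 * pi))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 (R integers).
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 104729) %% 2147483647)
}

# Physical mm coordinate of each pixel centre along one axis, with the image
# origin at the grid centre.
pixel_axis_mm <- function(n, spacing) {
  (seq_len(n) - (n + 1) / 2) * spacing
}

# Angle of (x, y) in degrees in [0, 360).
angle_deg <- function(x, y) {
  (atan2(y, x) * 180 / pi) %% 360
}

# Is `angle` (deg) inside the arc c(start, end)? `end` may exceed 360 to
# express wrap-around; width must be in [0, 360].
in_arc <- function(angle, arc) {
  width <- arc[2] - arc[1]
  if (width < 0 || width > 360) {
    stop("arc width must lie in [0, 360] degrees", call. = FALSE)
  }
  ((angle - arc[1]) %% 360) < width
}

arc_width <- function(arc) arc[2] - arc[1]

# Is arc `inner` contained in arc `outer` (both c(start, end) deg)?
arc_contains <- function(outer, inner) {
  wi <- arc_width(inner)
  if (wi == 0) return(TRUE)
  off <- (inner[1] - outer[1]) %% 360
  off + wi <= arc_width(outer) + 1e-9
}

# Vectorised bilinear interpolation of a (possibly complex) matrix at
# continuous 1-based (row, col) positions. Positions outside the grid are
# clamped to the border.
bilinear_interp <- function(img, row, col) {
  nr <- nrow(img)
  nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1)
  c0 <- pmin(floor(col), nc - 1)
  fr <- row - r0
  fc <- col - c0
  i00 <- img[cbind(r0, c0)]
  i10 <- img[cbind(r0 + 1, c0)]
  i01 <- img[cbind(r0, c0 + 1)]
  i11 <- img[cbind(r0 + 1, c0 + 1)]
  # incremental form: exact (no weight round-off) on constant fields
  i00 + fr * (i10 - i00) + fc * (i01 - i00) +
    fr * fc * (i00 + i11 - i10 - i01)
}

# DFT sample frequencies (cycles per unit) for n samples spaced d apart,
# in standard FFT order.
fft_freq <- function(n, d = 1) {
  k <- 0:(n - 1)
  (k - n * (k >= ceiling(n / 2))) / (n * d)
}
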