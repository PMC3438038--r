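# Segmental circumferential shortening and the dyssynchrony indices:
# csh per 60-degree sector, time to peak shortening (T_max), the
# coefficient of variation of csh at end-systole (CV_csh) and the
# circumferential uniformity ratio estimate (CURE).

#' Construct a strain field
#'
#' The central exchange object: csh (percent shortening, positive =
#' shortening) indexed by slice x sector x frame.
#'
#' @param csh Numeric array `n_slices x 6 x n_frames`, or a `6 x n_frames`
#'   matrix for a single slice. Frame 1 must be (numerically) zero.
#' @param frame_times Frame times in ms, length `n_frames`, strictly
#'   increasing, starting at 0 (end-diastole).
#' @param avc_frame 1-based frame index of aortic valve closure.
#' @return A `strain_field`.
#' @export
strain_field <- function(csh, frame_times, avc_frame) {
  if (is.matrix(csh)) csh <- array(csh, c(1, dim(csh)))
  stopifnot(length(dim(csh)) == 3)
  if (dim(csh)[2] < 2) stop("need at least 2 sectors per slice")
  if (dim(csh)[3] != length(frame_times)) {
    stop("frame_times length must match the frame dimension")
  }
  if (any(diff(frame_times) <= 0)) stop("frame_times must be strictly increasing")
  if (avc_frame < 1 || avc_frame > dim(csh)[3]) stop("avc_frame out of range")
  if (max(abs(csh[, , 1])) > 1e-6) {
    warning("csh at frame 1 (end-diastole) is not zero")
  }
  structure(list(csh = csh, frame_times = frame_times,
                 avc_frame = as.integer(avc_frame)),
            class = "strain_field")
}

#' Segmental csh of one tracked contour
#'
#' csh of sector s at frame f is `100 * (L_s(1) - L_s(f)) / L_s(1)`, where
#' `L_s` is the polyline arc length of the contour segments inside the
#' sector; sectors are 60 degrees wide with boundaries at 0, 60, ..., 300
#' degrees and each polyline segment is assigned by the reference angle of
#' its midpoint. Shortening is positive.
#'
#' @param track A tracked `contour_track` covering all frames.
#' @param avc_frame 1-based frame index of aortic valve closure.
#' @return A single-slice `strain_field`.
#' @export
sector_csh <- function(track, avc_frame) {
  n_f <- dim(track$positions)[3]
  if (n_f < 2) stop("track must cover more than one frame")
  ang <- track$angles_deg
  n <- length(ang)
  step <- 360 / n
  seg_sector <- sector_of_angle(ang + step / 2)
  if (any(tabulate(seg_sector, 6) < 3)) stop("sector under-sampled")
  nxt <- c(2:n, 1)
  lengths_sf <- vapply(seq_len(n_f), function(f) {
    p <- track$positions[, , f]
    seg <- sqrt(rowSums((p[nxt, ] - p)^2))
    vapply(1:6, function(s) sum(seg[seg_sector == s]), numeric(1))
  }, numeric(6))
  l0 <- lengths_sf[, 1]
  csh <- 100 * sweep(-sweep(lengths_sf, 1, l0), 1, l0, `/`)
  times <- if (is.null(track$frame_times)) (seq_len(n_f) - 1) else
    track$frame_times
  strain_field(csh, times, avc_frame)
}

#' Stack single-slice strain fields into a multi-slice field
#'
#' @param fields List of `strain_field`s sharing frame times and AVC frame.
#' @return A `strain_field` with one slice per input.
#' @export
stack_strain_fields <- function(fields) {
  stopifnot(length(fields) >= 1)
  f1 <- fields[[1]]
  csh <- array(NA_real_, c(length(fields), dim(f1$csh)[2], dim(f1$csh)[3]))
  for (i in seq_along(fields)) {
    stopifnot(isTRUE(all.equal(fields[[i]]$frame_times, f1$frame_times)))
    csh[i, , ] <- fields[[i]]$csh[1, , ]
  }
  strain_field(csh, f1$frame_times, f1$avc_frame)
}

#' Time to peak shortening per segment
#'
#' `T_max` of a segment is the frame time of its maximum csh over all
#' frames (earliest frame on ties). Segments whose maximum falls in the
#' first three or in the last frame are flagged (the automated stand-in for
#' observer inspection of implausible peaks); segments with an all-zero csh
#' curve are flagged `"no peak"` with `T_max = NA`.
#'
#' @param field A `strain_field` with at least 5 frames.
#' @return Data frame with `slice`, `sector`, `t_max_ms`, `flag`
#'   (`"ok"`, `"edge"`, `"no peak"`).
#' @export
time_to_peak <- function(field) {
  d <- dim(field$csh)
  if (d[3] < 5) stop("need at least 5 frames")
  out <- expand.grid(sector = seq_len(d[2]), slice = seq_len(d[1]))[, 2:1]
  out$t_max_ms <- NA_real_
  out$flag <- "ok"
  k <- 0
  for (sl in seq_len(d[1])) {
    for (se in seq_len(d[2])) {
      k <- k + 1
      curve <- field$csh[sl, se, ]
      if (all(curve == 0)) {
        out$flag[k] <- "no peak"
        next
      }
      i <- which.max(curve)
      out$t_max_ms[k] <- field$frame_times[i]
      if (i <= 3 || i == d[3]) out$flag[k] <- "edge"
    }
  }
  out
}

#' Coefficient of variation of csh at end-systole
#'
#' `100 * sd(csh at AVC over all segments) / |mean(csh at AVC)|`, the
#' dispersion-based dyssynchrony measure.
#'
#' @param field A `strain_field` with at least 2 segments.
#' @param mean_floor Smallest admissible `|mean csh|` (percent); below it
#'   the ratio is meaningless and an error is raised.
#' @return CV_csh in percent.
#' @export
cv_csh <- function(field, mean_floor = 0.1) {
  vals <- as.vector(field$csh[, , field$avc_frame])
  if (length(vals) < 2) stop("need at least 2 segments")
  m <- mean(vals)
  if (abs(m) < mean_floor) stop("degenerate mean shortening")
  100 * stats::sd(vals) / abs(m)
}

#' Circumferential uniformity ratio estimate (CURE)
#'
#' For each slice and frame the six sector csh values are taken in circular
#' order and their discrete spatial Fourier coefficients computed:
#' `c_k = (1/6) * sum_j x_j exp(-i 2 pi k j / 6)`. With zeroth- and
#' first-harmonic powers `A0 = |c_0|^2` and `A1 = |c_1|^2`,
#' `CURE = sqrt( sum A0 / sum (A0 + A1) )`, the sums running over all
#' slices and the selected frames. CURE is 1 for a spatially uniform field
#' (complete synchrony) and 0 for a zero-mean pure first-harmonic pattern
#' (pure dyssynchrony).
#'
#' @param field A `strain_field` with at least 3 sectors.
#' @param frames Frame indices to sum over; default frames 2 through
#'   `avc_frame` (systole). Use `seq_len(dim(field$csh)[3])` for all frames.
#' @param harmonics `"one"` (default) counts `|c_1|^2` once; `"two"` counts
#'   both conjugate first harmonics (`2 |c_1|^2`). The 0/1 extremes and all
#'   invariances hold under either convention.
#' @return CURE in \[0, 1\].
#' @export
cure_index <- function(field, frames = NULL, harmonics = c("one", "two")) {
  harmonics <- match.arg(harmonics)
  d <- dim(field$csh)
  if (d[2] < 3) stop("need at least 3 sectors per slice")
  if (is.null(frames)) {
    frames <- seq(2, max(2, field$avc_frame))
  }
  stopifnot(all(frames >= 1 & frames <= d[3]))
  a0 <- 0
  a1 <- 0
  for (sl in seq_len(d[1])) {
    for (f in frames) {
      x <- field$csh[sl, , f]
      ck <- stats::fft(x) / length(x)
      a0 <- a0 + Mod(ck[1])^2
      a1 <- a1 + Mod(ck[2])^2 * if (harmonics == "two") 2 else 1
    }
  }
  if (a0 + a1 == 0) stop("degenerate strain field")
  sqrt(a0 / (a0 + a1))
}

#' Aggregate dyssynchrony report
#'
#' Combines [cure_index()], [cv_csh()] and [time_to_peak()] into one
#' report: CURE, CV_csh, per-segment T_max with flags, T_max mean and SD
#' over unflagged segments, and mean csh at aortic valve closure over all
#' segments.
#'
#' @param field A `strain_field`.
#' @param cure_frames Passed to [cure_index()] as `frames`.
#' @return A `dyssynchrony_report`: list with `cure`, `cv_csh`,
#'   `t_max` (data frame), `t_max_mean_ms`, `t_max_sd_ms`,
#'   `mean_csh_avc_pct`, `flagged_segments`, `avc_frame`.
#' @export
dyssynchrony_report <- function(field, cure_frames = NULL) {
  tp <- time_to_peak(field)
  unflagged <- tp$flag == "ok"
  flagged <- tp[tp$flag != "ok", c("slice", "sector", "flag")]
  structure(list(
    cure = cure_index(field, frames = cure_frames),
    cv_csh = cv_csh(field),
    t_max = tp,
    t_max_mean_ms = if (any(unflagged)) mean(tp$t_max_ms[unflagged]) else NA_real_,
    t_max_sd_ms = if (sum(unflagged) > 1) stats::sd(tp$t_max_ms[unflagged]) else 0,
    mean_csh_avc_pct = mean(field$csh[, , field$avc_frame]),
    flagged_segments = flagged,
    avc_frame = field$avc_frame),
    class = "dyssynchrony_report")
}

#' @export
print.dyssynchrony_report <- function(x, ...) {
  cat("LV dyssynchrony report\n")
  cat(sprintf("  CURE              %.4f  (1 = synchronous)\n", x$cure))
  cat(sprintf("  CV_csh            %.1f %%\n", x$cv_csh))
  cat(sprintf("  T_max mean (SD)   %.1f (%.1f) ms over unflagged segments\n",
              x$t_max_mean_ms, x$t_max_sd_ms))
  cat(sprintf("  mean csh at AVC   %.2f %%\n", x$mean_csh_avc_pct))
  cat(sprintf("  flagged segments  %d\n", nrow(x$flagged_segments)))
  invisible(x)
}

#' Export a strain field as a long data frame
#'
#' One row per slice, sector and frame: `slice`, `sector`, `frame`,
#' `time_ms`, `csh_pct`.
#'
#' @param field A `strain_field`.
#' @return A data frame.
#' @export
strain_to_df <- function(field) {
  d <- dim(field$csh)
  df <- expand.grid(slice = seq_len(d[1]), sector = seq_len(d[2]),
                    frame = seq_len(d[3]))
  df$time_ms <- field$frame_times[df$frame]
  df$csh_pct <- field$csh[cbind(df$slice, df$sector, df$frame)]
  df[order(df$slice, df$sector, df$frame), ]
}
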