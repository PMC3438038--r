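# Strain metrics: sector csh, T_max, CV_csh, CURE and the aggregate report.

test_that("sector csh is definitional on a synthetic shrinking contour", {
  # 36 landmarks on a circle; frame 2 shrinks the radius by 10%
  ang <- seq(0, 350, by = 10)
  p1 <- cbind(cos(ang * pi / 180), sin(ang * pi / 180)) * 100
  pos <- array(NA_real_, c(36, 2, 2))
  pos[, , 1] <- p1
  pos[, , 2] <- 0.9 * p1
  track <- structure(list(angles_deg = ang, positions = pos,
                          frame_times = c(0, 45),
                          flags = matrix(FALSE, 36, 2),
                          pixel_spacing = 1, reference_frame = 1L),
                     class = "contour_track")
  f <- sector_csh(track, avc_frame = 2)
  expect_equal(as.vector(f$csh[1, , 1]), rep(0, 6))
  expect_equal(as.vector(f$csh[1, , 2]), rep(10, 6), tolerance = 1e-12)
})

test_that("under-sampled sectors are refused", {
  ang <- seq(0, 350, by = 45)   # 8 landmarks, some sectors get < 3 segments
  pos <- array(rep(cbind(cos(ang * pi / 180), sin(ang * pi / 180)), 2),
               c(8, 2, 2))
  track <- structure(list(angles_deg = ang, positions = pos,
                          frame_times = c(0, 45),
                          flags = matrix(FALSE, 8, 2)),
                     class = "contour_track")
  expect_error(sector_csh(track, 2), "under-sampled")
})

test_that("phantom sector csh is recovered close to its configured values", {
  cfg <- phantom_config(sector_amplitudes = c(15, 15, 15, 5, 5, 15),
                        noise_sd = 0)
  sa <- render_tagged_series(cfg, 1, c(1, 0))
  sb <- render_tagged_series(cfg, 1, c(0, 1))
  masks <- render_cine_masks(cfg)
  myo <- masks$epi[, , 1, 1] & !masks$endo[, , 1, 1]
  tr <- track_contour(sa, sb, init_midwall_contour(myo, 5, cfg$pixel_spacing))
  f <- sector_csh(tr, cfg$avc_frame)
  err <- f$csh[1, , ] - ground_truth_csh(cfg)
  expect_lt(sqrt(mean(err^2)), 1)     # < 1 point RMS over sectors x frames
  # per-sector values at AVC: within 1 point away from amplitude steps,
  # up to 1.5 points in sectors abutting a step, where the band-limited
  # harmonic smooths the discontinuity over roughly one tag period
  err_avc <- abs(f$csh[1, , cfg$avc_frame] - cfg$sector_amplitudes)
  expect_lt(err_avc[2], 1)            # interior of the normokinetic span
  expect_lt(err_avc[4], 1)
  expect_true(all(err_avc <= 1.5))
})

test_that("T_max takes the earliest peak frame and flags edge peaks", {
  n <- 25
  tt <- (0:(n - 1)) * 45
  curve <- exp(-((tt - 315) / 150)^2)
  curve[1] <- 0
  csh <- array(0, c(1, 6, n))
  for (s in 1:6) csh[1, s, ] <- curve
  csh[1, 2, ] <- seq(0, 10, length.out = n)          # monotone -> last frame
  csh[1, 3, ] <- 0                                   # all-zero -> no peak
  f <- strain_field(csh, tt, avc_frame = 8)
  tp <- time_to_peak(f)
  expect_equal(tp$t_max_ms[tp$sector == 1], 315)
  expect_equal(tp$flag[tp$sector == 1], "ok")
  expect_equal(tp$flag[tp$sector == 2], "edge")
  expect_equal(tp$flag[tp$sector == 3], "no peak")
  expect_true(is.na(tp$t_max_ms[tp$sector == 3]))
  # ties resolve to the earliest frame
  csh[1, 3, ] <- c(0, 5, 10, 10, rep(2, n - 4))
  tp2 <- time_to_peak(strain_field(csh, tt, 8))
  expect_equal(tp2$t_max_ms[tp2$sector == 3], 2 * 45)
})

test_that("a delayed phantom sector shifts T_max by the configured delay", {
  cfg <- phantom_config(sector_delays = c(0, 0, 0, 90, 0, 0))
  f <- strain_field(array(ground_truth_csh(cfg), c(1, 6, cfg$n_frames)),
                    (seq_len(cfg$n_frames) - 1) * cfg$frame_interval,
                    cfg$avc_frame)
  tp <- time_to_peak(f)
  dt <- tp$t_max_ms[tp$sector == 4] - tp$t_max_ms[tp$sector == 1]
  expect_lte(abs(dt - 90), cfg$frame_interval / 2)
})

test_that("CV_csh matches hand calculation and is scale invariant", {
  mk <- function(vals) {
    csh <- array(0, c(1, length(vals), 2))
    csh[1, , 2] <- vals
    strain_field(csh, c(0, 45), 2)
  }
  expect_equal(cv_csh(mk(c(10, 10, 10, 10, 10, 10))), 0)
  expect_equal(cv_csh(mk(c(8, 12))), 100 * sd(c(8, 12)) / 10,
               tolerance = 1e-12)
  expect_equal(cv_csh(mk(c(8, 12))), 28.28, tolerance = 1e-3)
  set.seed(3)
  v <- runif(6, 5, 15)
  expect_equal(cv_csh(mk(v)), cv_csh(mk(2 * v)), tolerance = 1e-12)
  expect_error(cv_csh(mk(c(0.01, -0.01))), "degenerate mean")
})

test_that("CURE hits its analytic extremes", {
  expect_equal(cure_index(uniform_field()), 1, tolerance = 1e-12)
  expect_equal(cure_index(harmonic_field()), 0, tolerance = 1e-12)
  expect_equal(cure_index(uniform_field(), harmonics = "two"), 1,
               tolerance = 1e-12)
  expect_equal(cure_index(harmonic_field(), harmonics = "two"), 0,
               tolerance = 1e-12)
})

test_that("CURE equals the direct-DFT oracle on random fields", {
  set.seed(7)
  for (i in 1:100) {
    f <- random_field()
    expect_equal(cure_index(f), cure_oracle(f), tolerance = 1e-12)
  }
})

test_that("CURE is invariant to sector rotation, scaling and slice duplication", {
  set.seed(11)
  for (i in 1:20) {
    f <- random_field(n_slices = 3)
    base <- cure_index(f)
    expect_true(base >= 0 && base <= 1)
    # circular relabelling of sectors
    rot <- f
    rot$csh <- f$csh[, c(4:6, 1:3), , drop = FALSE]
    expect_equal(cure_index(rot), base, tolerance = 1e-12)
    # global positive scaling
    sc <- f
    sc$csh <- 3.7 * f$csh
    expect_equal(cure_index(sc), base, tolerance = 1e-12)
    # appending identical slices
    dup <- f
    dup$csh <- array(f$csh[rep(1:3, 2), , ], c(6, 6, dim(f$csh)[3]))
    expect_equal(cure_index(dup), base, tolerance = 1e-12)
  }
})

test_that("CURE decreases monotonically with first-harmonic amplitude", {
  amps <- seq(0, 8, by = 1)
  cures <- vapply(amps, function(a) {
    csh <- array(0, c(1, 6, 5))
    for (f in 2:5) csh[1, , f] <- 10 + a * cos(2 * pi * (0:5) / 6)
    cure_index(strain_field(csh, (0:4) * 45, 5))
  }, numeric(1))
  expect_equal(cures[1], 1, tolerance = 1e-12)
  expect_true(all(diff(cures) < 0))
})

test_that("degenerate strain fields are refused by CURE", {
  csh <- array(0, c(1, 6, 5))
  f <- strain_field(csh, (0:4) * 45, 5)
  expect_error(cure_index(f), "degenerate")
})

test_that("the dyssynchrony report aggregates and round-trips through JSON", {
  f <- uniform_field(n_slices = 2, n_frames = 25, avc = 8)
  rep1 <- dyssynchrony_report(f)
  expect_equal(rep1$cure, 1, tolerance = 1e-9)
  expect_equal(rep1$t_max_sd_ms, 0)
  expect_equal(rep1$mean_csh_avc_pct, 15, tolerance = 1e-9)

  # one delayed hypokinetic sector strictly lowers CURE
  cfg_sync <- small_phantom()
  cfg_dys <- small_phantom(sector_amplitudes = c(5, 15, 15, 15, 15, 15),
                           sector_delays = c(90, 0, 0, 0, 0, 0))
  f_sync <- strain_field(array(ground_truth_csh(cfg_sync),
                               c(1, 6, cfg_sync$n_frames)),
                         (0:9) * 45, cfg_sync$avc_frame)
  f_dys <- strain_field(array(ground_truth_csh(cfg_dys),
                              c(1, 6, cfg_dys$n_frames)),
                        (0:9) * 45, cfg_dys$avc_frame)
  expect_lt(dyssynchrony_report(f_dys)$cure,
            dyssynchrony_report(f_sync)$cure)

  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep1, path)
  back <- read_report_json(path)
  expect_equal(back$cure, rep1$cure)
  expect_equal(back$cv_csh, rep1$cv_csh)
  expect_equal(back$t_max_mean_ms, rep1$t_max_mean_ms)
  expect_equal(back$mean_csh_avc_pct, rep1$mean_csh_avc_pct)
})
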