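# Synthetic phantom: motion model, renderers, masks, cohort generator.

test_that("configuration invariants are enforced before any computation", {
  expect_error(phantom_config(endo_radius = 30, epi_radius = 20),
               "endo_radius")
  expect_error(phantom_config(necrosis_arc = c(180, 300),
                              edema_arc = c(0, 207)), "nested")
  expect_error(phantom_config(avc_frame = 99), "avc_frame")
  expect_error(phantom_config(tag_directions = list(c(1, 0), c(1, 0))),
               "orthonormal")
  expect_error(phantom_config(sector_amplitudes = c(-1, rep(15, 5))),
               "non-negative")
  expect_error(phantom_config(edema_arc = c(0, 400)), "arc")
})

test_that("end-diastole (frame 1) is the undeformed reference everywhere", {
  cfg <- small_phantom(sector_delays = c(0, 30, 60, 90, 120, 150))
  d <- motion_displacement(cfg, runif(50, 0, 360), runif(50, 16, 26), 1)
  expect_equal(max(abs(d)), 0)
})

test_that("midwall arc-length integration recovers the configured peak csh", {
  cfg <- small_phantom()
  for (s in c(1, 4)) {
    expect_equal(numeric_sector_csh(cfg, s, cfg$avc_frame), 15,
                 tolerance = 1e-6)
  }
  cfg2 <- small_phantom(sector_amplitudes = c(15, 15, 15, 5, 5, 15))
  expect_equal(numeric_sector_csh(cfg2, 1, cfg2$avc_frame), 15,
               tolerance = 1e-6)
  expect_equal(numeric_sector_csh(cfg2, 4, cfg2$avc_frame), 5,
               tolerance = 1e-6)
})

test_that("a delayed sector's csh curve is a pure time shift", {
  d_ms <- 90
  cfg <- phantom_config(sector_delays = c(0, 0, 0, d_ms, 0, 0))
  gt <- ground_truth_csh(cfg)
  shift <- d_ms / cfg$frame_interval   # exactly 2 frames
  expect_equal(gt[4, (shift + 1):cfg$n_frames],
               gt[1, 1:(cfg$n_frames - shift)], tolerance = 1e-12)
  # best-aligning lag via cross-correlation of the two curves
  lags <- 0:5
  score <- vapply(lags, function(L) {
    sum(gt[4, (L + 1):cfg$n_frames] * gt[1, 1:(cfg$n_frames - L)])
  }, numeric(1))
  expect_equal(lags[which.max(score)], shift)
})

test_that("motion wraps out-of-range angles instead of failing", {
  cfg <- small_phantom()
  expect_equal(motion_displacement(cfg, 400, 20, 4),
               motion_displacement(cfg, 40, 20, 4))
  expect_equal(motion_displacement(cfg, -20, 20, 4),
               motion_displacement(cfg, 340, 20, 4))
})

test_that("undeformed tagged frame is a cosine with the configured period", {
  cfg <- small_phantom()
  sa <- render_tagged_series(cfg, 1, c(1, 0))
  F <- Mod(stats::fft(sa$images[, , 1]))
  fx <- fft_freq(cfg$grid_size, cfg$pixel_spacing)
  fy <- fft_freq(cfg$grid_size, cfg$pixel_spacing)
  D <- sqrt(outer(fy^2, fx^2, `+`))
  F[D < 0.5 / cfg$tag_spacing] <- 0   # exclude the shape (near-DC) energy
  pk <- which(F == max(F), arr.ind = TRUE)[1, ]
  expect_equal(abs(fx[pk[2]]), 1 / cfg$tag_spacing, tolerance = 1e-9)
  expect_equal(fy[pk[1]], 0)
})

test_that("rigid phantom translation shifts the tag phase by 2 pi e.t / spacing", {
  t_mm <- c(2.25, 0)
  cfg0 <- small_phantom()
  cfg1 <- small_phantom(center_offset = t_mm)
  h0 <- isolate_harmonic(render_tagged_series(cfg0)$images[, , 1], c(1, 0), 6)
  h1 <- isolate_harmonic(render_tagged_series(cfg1)$images[, , 1], c(1, 0), 6)
  # compare at interior pixels of the translated myocardium
  ctr <- (cfg0$grid_size + 1) / 2
  px <- cbind(ctr + c(20, 21, -20, -21) + t_mm[1], ctr + c(1, -1, 2, -2))
  dphi <- wrap_phase(tagsync:::phase_at(h1, px[, 1], px[, 2]) -
                       tagsync:::phase_at(h0, px[, 1] - t_mm[1], px[, 2]))
  # same material point seen at shifted location keeps its phase; a fixed
  # image location sees the phase change by -2 pi (e . t) / spacing
  expect_lt(max(abs(dphi)), 0.05)
  dfix <- wrap_phase(tagsync:::phase_at(h1, px[, 1], px[, 2]) -
                       tagsync:::phase_at(h0, px[, 1], px[, 2]))
  expect_equal(mean(dfix), -2 * pi * t_mm[1] / 6, tolerance = 0.05)
})

test_that("rendering is bit-identical for the same seed and errors on coarse tags", {
  cfg <- small_phantom(noise_sd = 4, seed = 11)
  a <- render_tagged_series(cfg, 1, c(1, 0))
  b <- render_tagged_series(cfg, 1, c(1, 0))
  expect_identical(a$images, b$images)
  other <- render_tagged_series(small_phantom(noise_sd = 4, seed = 12))
  expect_false(identical(a$images, other$images))
  expect_error(render_tagged_series(small_phantom(tag_spacing = 1.5)),
               "unresolvable")
  expect_error(render_tagged_series(cfg, 1, c(sqrt(0.5), sqrt(0.5))),
               "tag_direction")
})

test_that("cine masks match the configured geometry and analytic volumes", {
  cfg <- phantom_config(endo_radius = 25, epi_radius = 33, n_slices = 10,
                        noise_sd = 0)
  m <- render_cine_masks(cfg)
  # epicardial disc area at ED within 2% of pi r^2
  expect_equal(sum(m$epi[, , 1, 1]) * cfg$pixel_spacing^2, pi * 33^2,
               tolerance = 0.02)
  # disc-summation EDV within 3% of the analytic cylinder volume
  v <- lv_volumes(m$endo[, , , 1], m$epi[, , , 1],
                  m$endo[, , , cfg$avc_frame],
                  cfg$pixel_spacing, cfg$slice_thickness)
  expect_equal(v$lvedv_ml, pi * 2.5^2 * 0.8 * 10, tolerance = 0.03)
  # cavity area monotone decreasing from ED to AVC for positive amplitudes
  areas <- vapply(seq_len(cfg$avc_frame), function(f) sum(m$endo[, , 1, f]),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
  expect_lt(areas[cfg$avc_frame], areas[1])
})

test_that("tissue maps place arcs, masks and remote ROI consistently", {
  cfg <- small_phantom(edema_arc = c(0, 90), necrosis_arc = c(0, 0))
  ts <- render_tissue_maps(cfg)
  expect_gte(sum(ts$remote_roi), 20)
  expect_true(all(ts$myocardial_mask[ts$remote_roi]))
  # remote ROI disjoint from the edema arc
  g <- tagsync:::pixel_grid_mm(cfg)
  ang <- tagsync:::angle_deg(g$x, g$y)
  expect_false(any(ts$remote_roi & tagsync:::in_arc(ang, cfg$edema_arc)))
  # necrosis_arc empty: LGE myocardium all at remote level
  expect_equal(max(ts$lge_slices[, , 1][ts$myocardial_mask]), 100)
  # 90 deg edema at noise 0 -> 25 %circ downstream
  ext <- quantify_tissue(ts)
  expect_lt(abs(ext$edema_extent - 25.0), 1)
  expect_equal(ext$necrosis_extent, 0)
  expect_equal(ext$salvage, ext$edema_extent)
  expect_error(render_tissue_maps(small_phantom(
    signal_levels = list(remote_mean = 100, remote_sd = 10,
                         edema_mean = 110, necrosis_mean = 200))),
    "edema signal")
})

test_that("cohort generator reproduces its configured structure", {
  tab <- generate_cohort_measures(5000, seed = 42)
  expect_s3_class(tab, "cohort_table")
  # law of large numbers at n = 5000
  expect_lt(abs(mean(tab$edema_extent) - 57.5), 1)
  # salvage is definitionally edema - necrosis
  expect_equal(tab$salvage, tab$edema_extent - tab$necrosis_extent)
  expect_true(all(tab$salvage >= 0))
  expect_true(all(tab$CURE_acute >= 0 & tab$CURE_acute <= 1))
  expect_true(all(tab$edema_extent >= 0 & tab$edema_extent <= 100))
  # determinism
  expect_identical(tab, generate_cohort_measures(5000, seed = 42))
  expect_error(generate_cohort_measures(1), "at least 2")
  expect_error(generate_cohort_measures(10, cohort_params(edema_sd = -1)),
               "variance")
  # degenerate link: constant CURE flagged by warning
  expect_warning(
    generate_cohort_measures(10, cohort_params(cure_slope = 0,
                                               cure_noise_sd = 0)),
    "constant")
})
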