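# tagsync

Quantifying left-ventricular (LV) mechanical dyssynchrony and infarct
burden from cardiovascular MR — and validating every step of that analysis
against a synthetic phantom with exact ground truth.

After an acute myocardial infarction the ventricle contracts non-uniformly:
necrotic and edematous segments shorten less and later than remote
myocardium. Tagged MR measures this directly. A SPAMM sequence imprints a
sinusoidal tag pattern on the tissue at end-diastole; the pattern deforms
with the myocardium; harmonic-phase (HARP) analysis recovers material
motion from the phase of the pattern's first spectral harmonic. From
tracked midwall contours the package computes, per 60° sector:

- **csh** — midwall circumferential shortening,
  `csh_s(f) = 100 · (L_s(ED) − L_s(f)) / L_s(ED)`, the arc-length change of
  the sector's contour relative to end-diastole (shortening positive);
- **T_max** — time to peak csh, with automated flagging of implausible
  (first-three-frames / last-frame) peaks;
- **CV_csh** — coefficient of variation of csh at end-systole (aortic
  valve closure, AVC);
- **CURE** — the circumferential uniformity ratio estimate. With spatial
  Fourier coefficients `c_k` of the six sector csh values at each slice and
  frame, and harmonic powers `A0 = |c0|²`, `A1 = |c1|²`,

  `CURE = sqrt( Σ A0 / Σ (A0 + A1) )`,

  summed over slices and systolic frames: exactly 1 for synchronous
  (spatially uniform) contraction, exactly 0 for a zero-mean pure
  first-harmonic pattern.

On the tissue side it quantifies edema ("area-at-risk", T2-weighted signal
> 2 SD above remote tissue along the mid-myocardial circumference),
necrosis (LGE signal > 5 SD, as % circumference and as % LV mass over the
full stack), **salvaged myocardium** (edema − necrosis, %circ), and LV
volumes / ejection fraction by disc summation. A cohort module supplies the
accompanying statistics: Pearson correlations with least-squares lines,
paired/two-group comparisons with Kolmogorov–Smirnov-based test selection,
two-group sample-size computation, and summary tables.

Because no public image data exist for this kind of study, the package
ships a first-class synthetic-data module: an analytic deforming-annulus
phantom (prescribed per-sector shortening amplitudes and delays, exact
area-conserving motion, closed-form ground-truth csh), rendered tagged cine
series, T2w/LGE tissue maps, masks, and a calibrated measure-level cohort
generator. Every stage of the pipeline is tested against this ground truth.

## Worked example

Simulate a mid-ventricular slice of an acute anterior-infarct phantom
(hypokinetic, delayed sectors S1–S2 under a 108° necrosis arc nested in a
207° edema arc; SNR 20), HARP-track its midwall contour, and compute the
dyssynchrony report and tissue extents:

```r
library(tagsync)

cfg <- infarct_phantom(noise_sd = 5, seed = 7)
sa  <- render_tagged_series(cfg, slice = 5, cfg$tag_directions[[1]])
sb  <- render_tagged_series(cfg, slice = 5, cfg$tag_directions[[2]])
masks <- render_cine_masks(cfg)
myo <- masks$epi[, , 5, 1] & !masks$endo[, , 5, 1]

track  <- track_contour(sa, sb, init_midwall_contour(myo, 5, cfg$pixel_spacing))
field  <- sector_csh(track, cfg$avc_frame)
dyssynchrony_report(field)
#> LV dyssynchrony report
#>   CURE              0.9495  (1 = synchronous)
#>   CV_csh            45.1 %
#>   T_max mean (SD)   427.5 (93.3) ms over unflagged segments
#>   mean csh at AVC   9.60 %
#>   flagged segments  0

quantify_tissue(render_tissue_maps(cfg))
#> Tissue extents
#>   edema (area-at-risk)  57.8 %circ
#>   necrosis              30.6 %circ
#>   necrosis mass         30.1 %LV
#>   salvaged myocardium   27.2 %circ
```

The tracked per-sector csh at AVC, `(4.7, 4.4, 9.0, 11.6, 14.4, 13.5)` %,
recovers the phantom's analytic ground truth `(4.3, 4.3, 9.6, 12.0, 15.0,
15.0)` %; CURE lands below 1 because the infarcted sectors shorten less
and 90 ms later than remote myocardium, and the tissue extents recover the
configured 207°/108° arcs (57.5 and 30 %circ) within measurement noise.
Salvage is the area-at-risk minus necrosis, here ≈ 27 %circ.

Cohort-level, on synthetic subjects:

```r
tab <- generate_cohort_measures(22, seed = 7)
correlate(tab$edema_extent, tab$CURE_acute)
#> r = -0.879 (r^2 = 0.773), p = 7.08e-08, n = 22; y = 1.09 + -0.003145 x

compare_groups(tab$CURE_acute, tab$CURE_followup, paired = TRUE)
#> paired t-test: statistic = -8.371, p = 3.95e-08, n = 22 (paired)
#>   a: 0.889 +/- 0.059   b: 0.920 +/- 0.054

two_group_sample_size(delta = 0.04, sd = 0.03, alpha = 0.05, power = 0.8)
#> [1] 18
```

More edema means lower acute CURE (more dyssynchrony); CURE rises toward 1
as the infarct heals; detecting a CURE difference of 0.04 with SD 0.03 at
80% power needs 18 subjects in a two-group design.

`run_pipeline(cfg, "out/")` chains simulate → track → metrics → tissue
into one run, writing NIfTI/CSV/JSON products plus a manifest with MD5
content hashes (same config + seed ⇒ identical hashes). A thin command-line
front end lives at `inst/cli/tagsync.R`
(`simulate`, `cohort`, `run`, `power` subcommands).

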