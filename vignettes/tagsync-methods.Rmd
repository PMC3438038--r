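---
title: "Models and methods behind tagsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tagsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagsync)
```

## What the package computes

After an acute myocardial infarction the left ventricle (LV) contracts
non-uniformly: infarcted and edematous segments shorten less and later than
remote myocardium. Tagged cardiovascular MR quantifies this directly: a
spatial modulation of magnetisation (SPAMM) imprints a sinusoidal tag
pattern on the tissue at end-diastole, the pattern deforms with the
myocardium, and harmonic-phase (HARP) analysis recovers the motion of
material points from the phase of the pattern's first spectral harmonic.

`tagsync` implements that analysis chain end to end, together with a
synthetic deforming-LV phantom that provides exact ground truth for every
stage:

1. **Phantom** — analytic annulus motion, tagged cine rendering,
   T2-weighted (T2w) and late gadolinium enhancement (LGE) tissue maps,
   endo/epicardial masks, and a measure-level cohort generator.
2. **HARP tracking** — harmonic isolation, phase-invariance point tracking,
   midwall contour initialisation and tracking.
3. **Strain metrics** — segmental midwall circumferential shortening
   (csh), time to peak shortening (T~max~), the coefficient of variation of
   csh at end-systole (CV~csh~), and the circumferential uniformity ratio
   estimate (CURE).
4. **Tissue quantification** — edema and necrosis extents along the
   mid-myocardial circumference, necrosis mass fraction, salvaged
   myocardium, LV volumes and ejection fraction by disc summation.
5. **Cohort statistics** — correlations, paired/two-group comparisons with
   normality-based test selection, a two-group sample-size computation, and
   cohort summary tables.

Conventions used throughout: frames, slices, sectors and pixel indices are
1-based (the natural R convention); frame 1 is end-diastole and the
undeformed reference; `avc_frame` marks aortic valve closure
(end-systole). Angles are in degrees, 0° at the anterior junction of the
right and left ventricle, increasing clockwise as viewed from the apex;
sector S*s* spans `[(s-1)*60, s*60)` degrees. Positions are in mm relative
to the image centre.

## The phantom motion model

The phantom is a cylindrical annulus (default endocardial radius 20 mm,
epicardial 30 mm, 9 slices of 8 mm) deformed by an analytic,
polar-coordinate map. Each 60° sector $s$ carries a circumferential
stretch

$$\lambda_s(t) = 1 - \mathrm{csh}_s(t)/100,$$

where the prescribed shortening follows a raised-cosine activation
$\mathrm{csh}_s(t) = a_s\, g_0(t - d_s)$ with peak amplitude $a_s$
(percent), sector delay $d_s$ (ms), and $g_0$ rising from 0 at
end-diastole to 1 at the time of aortic valve closure, then falling back.
Because delayed sectors follow the *same* base curve shifted in time, a
configured delay appears verbatim as a T~max~ offset — a property the
tests exploit. An optional post-systolic component
(`post_systolic_fraction`) adds a late raised-cosine bump in sectors whose
centre lies inside the necrosis arc, reproducing the post-systolic
shortening typical of infarcted segments without modelling
electrophysiology.

A material point at reference angle $\theta$ and radius $r$ maps to

$$\varphi(\theta, t) = \frac{1}{\bar\lambda}\int_0^\theta
  \lambda(u, t)\,du, \qquad
  \rho^2(r, \theta, t) = (R_m\bar\lambda)^2 +
  \frac{\bar\lambda}{\lambda}\,(r^2 - R_m^2),$$

with $R_m$ the midwall radius and $\bar\lambda$ the circumferential mean
of $\lambda$. The construction has two properties that make it a good
oracle. First, it conserves local area exactly
($d(\rho^2)/d(r^2) \cdot d\varphi/d\theta = 1$), so contraction is
accompanied by wall thickening, as in incompressible myocardium. Second,
the midwall arc length of a material sector is exactly
$\lambda_s(t)$ times its reference length, so the ground-truth csh of
every sector at every frame is known in closed form
(`ground_truth_csh()`), and is independently verifiable by numerically
integrating deformed arc lengths through `motion_displacement()`. Since
$\varphi$ is piecewise-linear in $\theta$ the map inverts analytically,
which is how the renderers paint tag patterns and masks without any
iterative inversion.

The model is kinematic, not biomechanical: it prescribes motion rather
than deriving it from fibre mechanics. That is deliberate — the phantom's
purpose is exact, configurable ground truth for validating the analysis
chain, not physiological realism.

## Rendering

`render_tagged_series()` simulates a 1-1 SPAMM line-tag pattern per tag
direction $\mathbf e$: the frame-$f$ intensity at image position
$\mathbf y$ inside the deformed myocardium is

$$I(\mathbf y, f) = \frac{B}{2}\left(1 + \cos\frac{2\pi\, \mathbf e\cdot
  \mathbf X(\mathbf y, f)}{\Delta}\right),$$

where $\mathbf X(\mathbf y, f)$ is the reference position obtained through
the analytic inverse of the motion map and $\Delta$ the tag spacing
(default 6 mm). Two orthogonal tag directions per slice carry the full
in-plane motion. Tag fading is ignored by default (complementary SPAMM
acquisitions suppress it in practice); the true acquisition this emulates
is a 3D tagging scheme, but per-slice 2D line-tag pairs are sufficient
because only in-plane circumferential shortening feeds the metrics.

Noise is Gaussian on the magnitude images, a simplification of the Rician
statistics of actual magnitude MR. At the signal-to-noise ratios exercised
(SNR ≥ 20 in the remote myocardium) the difference is negligible away
from the near-zero background, but it is a known limitation: the phantom's
background noise can go negative where a real magnitude image would show a
Rayleigh floor.

`render_tissue_maps()` paints the tissue study at end-diastolic geometry: a
transmural hyperintense edema arc (default 207°, i.e. 57.5% of the
circumference) on three T2w slices (basal, midventricular, apical), a
nested hyperenhanced necrosis arc (default 108°, 30%) on the full LGE
stack, annular myocardial masks, and a 60°-wide remote reference ROI
centred in the unaffected circumference. Default signal levels (remote
100 ± 10, edema 160, necrosis 200, noise SD 5) keep both lesions far
above their detection thresholds while leaving realistic contrast margins.

## HARP tracking

`isolate_harmonic()` retains the first tag harmonic with a circularly
symmetric raised-cosine band-pass centred at $+1/\Delta$ along the tag
direction. The window radius defaults to $0.7/\Delta$ cycles/mm. This is
wider than the 0.4 factor often quoted for classical HARP; the choice was
calibrated on noise-free and SNR-20 phantoms by sweeping the factor over
0.4–0.9 and scoring (a) the RMS error between inter-frame phase
differences and the known motion, (b) recovered uniform contraction, and
(c) sector-csh RMS error. Accuracy improved monotonically up to ~0.7 with
no noise penalty, because the dominant error source at these geometries is
spatial truncation (edge effects of the annulus) rather than spectral
interference: the raised-cosine window falls to zero at its radius, so the
DC peak (at distance $1/\Delta$) and the conjugate peak (at $2/\Delta$)
stay fully excluded for any factor below 1. The factor is exposed as
`filter_radius` on every entry point for users who prefer the classical
setting.

Point tracking uses phase invariance: the wrapped phase pair of a material
point is constant in time, so `track_points()` finds the frame-$f{+}1$
position whose phases match the frame-$f$ target by Newton iteration on
the 2-vector of wrapped phase differences, with wrapped central-difference
gradients, a 0.01-pixel convergence threshold and at most 20 iterations.
Complex harmonic images are interpolated bilinearly (real and imaginary
parts); interpolating wrapped phase directly would be invalid at the wrap
seam. All phase arithmetic routes through a single `wrap_phase()` utility
mapping to $(-\pi, \pi]$. Three failure modes are detected per point:
harmonic magnitude below 5% of the slice maximum ("signal void"), a Newton
step exceeding one tag period ("tracking diverged", the phase-jumping
signature), and non-convergence.

`track_contour()` seeds 72 landmarks (5° steps) on the midwall — each the
midpoint of the endo- and epicardial crossings of a ray from the
myocardial centroid — and tracks them sequentially frame-to-frame, which
keeps each tracking step well below half a tag period. After each
sequential step the position is refined against the end-diastolic
reference phase (using the sequential estimate as the Newton start), so
interpolation bias cannot accumulate over long series. Landmarks that fail
in a frame are interpolated circularly from their angular neighbours and
flagged rather than manually corrected; if more than 25% of landmarks fail
in any frame the track is rejected outright.

### Accuracy on phantoms, and what it does and does not show

On noise-free default-geometry phantoms the tracked sector csh matches the
analytic ground truth to about 0.4–0.5 percentage points RMS over all
sectors and frames (the test suite enforces < 1), and stationary phantoms
show zero landmark drift over 20 frames. One systematic effect deserves
mention: the phantom allows *discontinuous* per-sector amplitude steps
(e.g. 15% next to 5%), which no band-limited method can follow exactly —
the harmonic phase smooths the step over roughly one tag period, biasing
the two sectors abutting a step by up to ~1.3 points toward each other
while sectors away from steps stay within 1 point. This plateau persists
for any admissible filter radius and finer tag spacings; it is a property
of HARP on discontinuous motion, not an implementation artefact, and real
ventricles deform smoothly across sector boundaries. Passing these phantom
tests therefore demonstrates correctness of the machinery, not performance
on clinical images, which add through-plane motion, tag fading,
off-resonance and segmentation error that the phantom deliberately omits.

## Strain metrics

`sector_csh()` computes, per sector and frame,

$$\mathrm{csh}_s(f) = 100\,\frac{L_s(1) - L_s(f)}{L_s(1)},$$

with $L_s$ the polyline arc length of the contour segments assigned to the
sector (by the reference angle of each segment midpoint). Shortening is
positive, so healthy systole gives csh around +10 to +15%.

`time_to_peak()` takes the frame time of each segment's csh maximum,
resolving ties to the earliest frame for determinism. Segments peaking in
the first three or the last frame are flagged — an automated stand-in for
the observer inspection such implausible peaks receive in manual
workflows — and excluded from the T~max~ mean/SD (but not from CURE or
CV~csh~, which have no such correction convention). All-zero curves are
flagged "no peak" with `NA`.

`cv_csh()` is $100 \cdot \mathrm{SD}/|\mathrm{mean}|$ of csh at the AVC
frame over all segments, refusing to divide by a mean below 0.1% (the
ratio is meaningless for a ventricle that barely shortens).

`cure_index()` takes the six sector values in circular order at each slice
and frame, computes discrete spatial Fourier coefficients
$c_k = \tfrac{1}{6}\sum_j x_j e^{-2\pi i k j/6}$, and returns

$$\mathrm{CURE} = \sqrt{\frac{\sum A_0}{\sum (A_0 + A_1)}},
  \qquad A_0 = |c_0|^2,\; A_1 = |c_1|^2,$$

summing over slices and frames. A spatially uniform field has $A_1 = 0$
and CURE exactly 1 (complete synchrony); a zero-mean pure first-harmonic
pattern has $A_0 = 0$ and CURE exactly 0 (pure dyssynchrony). Published
formulations differ on whether the first-harmonic power counts one or both
conjugate harmonics; both conventions share the 0/1 extremes and every
invariance (sector rotation, positive scaling, slice duplication), and the
`harmonics` argument selects between them, defaulting to one-sided. The
temporal summation range defaults to frames 2 through `avc_frame` —
systole, consistent with anchoring the other indices at end-systole — and
is configurable to all frames. These choices are verified against a
brute-force DFT oracle to 10⁻¹² on random fields.

## Tissue quantification

Edema and necrosis extents are measured along the mid-myocardial
centreline, sampled at 1° steps (well below pixel scale at the default
matrices) with bilinear interpolation; the midline avoids the
subendocardial border, where bright stagnant blood confounds T2w edema in
real studies. Sampling angles are offset by half a step so a configured
arc `[a, b)` covers exactly `(b − a)` samples on a noise-free phantom. A
sample is hyperintense if it exceeds the remote-ROI mean by `k` remote
SDs: `k = 2` for T2w edema (the conventional area-at-risk threshold) and
`k = 5` for LGE necrosis. The LGE default is the common automated
convention for bright infarct cores and replaces the manual delineation of
interactive workflows; both multipliers are arguments. The extent over the
three slices is the unweighted mean of per-slice fractions (a pooled mode
is available; the two agree when slices have equal sample counts). No
contiguity is imposed on supra-threshold samples — at the default noise
levels isolated false crossings are negligible, and a contiguity rule
would add a parameter the measurement does not need.

`necrosis_mass_fraction()` counts supra-threshold myocardial pixels over
the whole LGE stack; with uniform pixel volume the pixel ratio is the mass
ratio, so a transmural 108° arc yields 30.0% of LV mass by annular
symmetry, which the tests verify. Salvaged myocardium is edema minus
necrosis extent; anatomically necrosis nests inside edema so salvage is
non-negative, and a negative measured difference (possible under noise) is
clipped to zero with a warning. LV volumes use disc summation,
$V = \sum \text{area} \times (\text{thickness} + \text{gap})$, and LV mass
uses the standard 1.05 g/ml myocardial density.

## The cohort generator and its calibration

`generate_cohort_measures()` is the fast, measure-level fidelity tier: it
draws per-subject measures directly, without rendering images (the
image-level tier is simply one rendered phantom per subject). Its defaults
describe an acute anterior-infarct population: edema extent
57.5 ± 14 %circumference; necrosis occupying on average 53% of the edema
arc (hence necrosis ≈ 30.6 ± 12.6 %circ, and salvage = edema − necrosis
non-negative by construction); necrosis mass ≈ 29.6 ± 9.9 %LV via a
linear map from necrosis extent; LVEDV 156.8 ± 50.5 ml; EF 40.5 ± 8.2%;
LV mass 133 ± 36 g.

Acute CURE is linked linearly to edema extent with Gaussian noise. No
quantitative link function between edema and dyssynchrony is established
in the literature beyond observed correlation strengths, so the linear
form is a modelling choice; its two free parameters are set so that the
acute CURE distribution is 0.91 ± 0.05 and the edema–CURE coefficient of
determination is 0.63 (`cohort_r2()` returns the configured value, and a
parameter-recovery test checks that `correlate()` finds it at n = 5000).
Follow-up CURE adds a recovery term that grows with acute necrosis
extent — dyssynchrony regresses most in ventricles with the largest
necrosis — centred near 0.94 ± 0.03. All draws are clipped to valid
ranges, which slightly perturbs the moments at the distribution tails;
at the default settings the effect is well under the calibration
tolerances.

## Statistics

`compare_groups()` mirrors the conventional clinical-CMR analysis recipe:
paired or independent t-test when the data look normal, otherwise Wilcoxon
signed-rank or Mann–Whitney, two-sided throughout, with normality checked
by a Kolmogorov–Smirnov test (on paired differences, or each arm) at the
0.05 level when the caller does not force a choice. Zero-variance
differences are reported as degenerate rather than tested. A simulation
test verifies the paired t-test's type-I error within 1.5 points of 5%
under the null and its power against the closed-form noncentral-t value
(`paired_t_power()`).

`two_group_sample_size()` implements the normal-approximation formula

$$n_\text{per group} = \left\lceil 2\left(\frac{(z_{1-\alpha/2} +
  z_\text{power})\,\sigma}{\delta}\right)^2 \right\rceil,$$

returning the total over both groups — 18 for δ = 0.04, σ = 0.03,
α = 0.05, power 80%, the canonical design computation for a CURE
difference of that size. Note the reading: this is a *two-group* formula.
A paired design with difference SD 0.03 would need only about 5 subjects
for the same δ, so powering a paired follow-up study with the two-group
form is conservative; the function implements the two-group form because
that is the computation such study designs conventionally report. No
multiple-testing correction is applied anywhere, matching the exploratory
reporting style the summary table emulates.

## Numerical choices and degenerate inputs

* Phase wrapping: one utility, $(-\pi, \pi]$, property-tested for
  invariance to 2π offsets of either argument of a difference.
* Bilinear interpolation uses the incremental form
  $i_{00} + f_r\Delta_r + f_c\Delta_c + f_rf_c\Delta_{rc}$, which is exact
  on constant fields (the weighted-sum form can return
  `100 + 2^-46` on a constant-100 image, enough to cross a zero-noise
  threshold).
* T~max~ ties resolve to the earliest frame; T~max~ of flat curves is
  `NA`, flagged.
* `cure_index()` refuses all-zero fields; `cv_csh()` refuses near-zero
  mean shortening; `correlate()` refuses zero-variance inputs;
  `remote_stats()` refuses ROIs under 20 pixels; configuration validation
  (nesting of arcs, orthonormal tag directions, radii ordering, frame
  ranges) runs before any pipeline stage touches data.
* All randomness flows from explicit integer seeds through deterministic
  sub-seed derivation; rendering twice with one seed is bit-identical, and
  `run_pipeline()` manifests record MD5 content hashes to prove it.

## Problem sizes in the test suite

The routine unit tests run on compact phantoms (72-pixel grids, 10
frames); the accuracy-toleranced checks — csh recovery, drift, tissue
extents at SNR 20 — use the default 108-pixel, 20-frame geometry; the
statistical calibration tests use 5000 null replicates and n = 5000
cohorts. The full suite completes in well under a minute on one CPU.

## Known limitations

* Gaussian (not Rician) noise; no tag fading by default; no through-plane
  motion, k-space simulation or coil sensitivity — the phantom validates
  the analysis, not the acquisition.
* The motion model is kinematic with piecewise-constant sector stretch;
  its discontinuous amplitude steps are harder than physiological motion
  for any band-limited tracker (see above).
* Cylindrical geometry: no apex-to-base taper, so disc-summation volumes
  test bookkeeping, not curved-surface accuracy.
* The edema→CURE link in the cohort generator is a calibrated modelling
  assumption, not an estimated physiological relationship; conclusions
  drawn from synthetic cohorts inherit it.
* Masks are phantom-provided or user-supplied; the package does not
  segment myocardium from raw images.
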