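---
title: "Quantifying conjunctival microvascular hemodynamics from slit-lamp video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying conjunctival microvascular hemodynamics from slit-lamp video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemoflow)
```

## The measurement problem

The conjunctival microcirculation — the network of venules and arterioles on
the white of the eye — is one of the few microvascular beds that can be imaged
non-invasively at the bedside, with nothing more than a slit-lamp
biomicroscope and a video camera. Because microcirculatory dysfunction is an
early manifestation of cardiovascular disease, quantitative readouts from
these videos (vessel diameter, red-cell velocity, volumetric flow, wall shear
rate) are candidate screening markers.

`hemoflow` turns a short (seconds-long) grayscale video of the conjunctiva
into a table of per-vessel-segment hemodynamic parameters, and provides the
cohort-level statistics used to compare patient groups. Every stage is
validated against a synthetic-video generator with known ground truth,
because clinical videos come with no truth attached.

## Pipeline

The stages, each exposed as an ordinary function returning a plain container
or a tibble:

1. **Ingest** (`load_stack()`): multi-page TIFF or a directory of numbered
   PNG/TIFF frames, normalized to intensities in $[0,1]$. Colour sources are
   reduced to one analysis channel — green by default, since haemoglobin
   absorption makes red cells darkest there. A calibration (µm/pixel and
   frames/s) is a *required* input with no default: it depends on the
   microscope magnification and camera, and silently guessing it would
   corrupt every downstream number.
2. **Stabilize** (`select_reference()`, `register_stack()`): the sharpest
   frame (variance of the Laplacian — a standard focus measure, strictly
   decreasing under Gaussian blur) becomes the reference; every other frame
   is registered to it by a rigid transform. Translation comes from
   sub-pixel phase correlation with the peak search bounded to a quarter
   of the frame (eye motion is bounded, and an unbounded search can lock
   onto moving intravascular texture); rotation from a grid search over a
   small angular range (±2° by default; ocular drift at this magnification
   is dominantly translational). A frame whose registered residual is
   worse than its unregistered one is flagged and passed through
   unchanged — never silently dropped, because downstream stages index
   frames by time. The returned validity mask marks pixels in-bounds in at
   least 90% of frames: a strict all-frames rule would let one
   badly-estimated frame poison the whole mask.
3. **Map vessels** (`map_vessels()`): run on the *temporal mean* of the
   stabilized stack — averaging removes the moving erythrocyte texture and
   leaves the static vessel silhouette. A multiscale Hessian ridge filter
   (Frangi-type, oriented for dark-on-bright ridges, scales
   $\sigma \in \{1.5, 3, 6, 9, 12\}$ px) detects vessels; hysteresis
   thresholding (5% / 15% of the response maximum) binarizes; Guo–Hall
   thinning produces a one-pixel skeleton; branch and end points split it
   into segments; and the Euclidean distance transform of the mask,
   evaluated along each centreline, gives per-point radii. The segment
   diameter is $D = 2\,\overline{r}\,s$ with $s$ the µm/pixel scale.
4. **Velocimetry** (`build_sti()`, `estimate_axial_velocity()`): the
   spatio-temporal image $I(x,t)$ samples the video along the centreline at
   one-pixel arc-length steps; moving red-cell columns appear as oblique
   streaks whose slope (samples/frame) is the axial velocity. A Morlet
   continuous-wavelet band-pass along $x$ suppresses out-of-band noise,
   then an exhaustive orientation-energy search over 200 log-spaced
   velocity candidates (0.05–3 mm/s by default, both directions) finds the
   dominant slope; $V_a = |s| \cdot dx/dt$.
5. **Hemodynamics** (`build_segment_records()`): converts $(D, V_a)$ to
   cross-sectional velocity, flow and wall shear rate (below) and assigns
   each segment a diameter group.
6. **Statistics** (`cohort_table()` and friends): cohort comparison with
   normality gating, one-way ANOVA with variance-gated post-hoc tests, and
   test–retest repeatability.

## The hemodynamic model

With $V_a$ in mm/s and $D$ in µm:

$$
V_s \;=\;
\begin{cases}
V_a, & D/D_c \le 0.6\\[4pt]
\dfrac{V_a}{1.58\left(1 - e^{-\sqrt{2D/D_c}}\right)}, & D/D_c > 0.6
\end{cases}
\qquad D_c = 7.65\ \mu m ,
$$

$$
Q \;=\; V_s\,\frac{\pi D^2}{4} \quad [\mathrm{pl/s}],
\qquad
\mathrm{WSR} \;=\; \frac{8 V_s}{D} \quad [\mathrm{s^{-1}}].
$$

$D_c$ is the reference human erythrocyte diameter. In vessels narrower than
$0.6 D_c$ the cells fill the lumen in single file and the centreline
velocity *is* the mean velocity; in wider vessels the profile factor
(approaching 1.58 for large $D$) converts the centreline velocity into the
cross-sectional mean. The piecewise form is implemented exactly as written,
including its ~5% discontinuity at $D = 0.6 D_c \approx 4.6\ \mu m$: smoothing
the jump would silently shift $Q$ and WSR for the narrowest capillaries, and
fidelity to the published form matters more than elegance here. Units: $Q$ in
pl/s ($1\,\mathrm{pl/s} = 1000\,\mu m^3/s$), velocities in mm/s at every
interface, µm/s internally.

Diameter groups stratify the anatomy: group 1 ($D < 11$), 2 ($11 \le D < 16$),
3 ($16 \le D < 22$), 4 ($D \ge 22$ µm). The bins are implemented half-open so
every diameter belongs to exactly one group; which side of 16 µm an exactly
boundary-valued vessel belongs to is a convention, and ours is documented in
`assign_group()`.

```{r}
vs <- cross_sectional_velocity(0.53, 21.43)
c(vs = vs, q = volume_flow(vs, 21.43), wsr = wall_shear_rate(vs, 21.43))
```

## Design choices in the image stages

Several stages required choices the problem statement leaves open; the
rationale, and what we observed when the obvious choice failed, are part of
the package's record.

**Thinning.** Zhang–Suen thinning, the textbook default, completely erodes
even-width diagonal runs (a known pathology of its two-subiteration delete
conditions); on a 45°-oriented vessel mask it left a quarter of the skeleton.
We use Guo–Hall thinning instead, followed by a cleanup pass that deletes
redundant staircase pixels — a pixel with three or more neighbours whose
Yokoi 8-connectivity number is 1 can be removed without changing topology.
Without the cleanup, staircase corners masquerade as branch points and
fragment segments.

**Mask width convention.** The Hessian ridge response finds vessels robustly
but its support tracks curvature strength, not lumen width: thresholding it
underestimates Gaussian-blurred profiles and misses the flat interior of wide
vessels entirely (the ridge lives on the edges). `binarize(frame = ...)`
therefore refines the detection to the full-width-at-half-maximum convention:
per connected component, the vessel is the connected region where darkening
below the local background exceeds half the component's peak darkening. For a
hard-edged vessel any half-depth cut recovers the same support, so nothing is
lost in the ideal case.

**Border handling.** Where a vessel exits the frame, the medial axis of the
clipped shape grows a spurious tail toward the image corner with shrinking
EDT values. Centreline points closer to the border than the segment's
reference radius (95th percentile of its EDT values) are excluded from the
diameter average, as are points within 2 px of a branch cluster, where the
EDT inflates. Whole segments whose median border distance is below their
own median radius are discarded outright: they are slivers of mask running
along the frame edge, whose width the image cannot contain.

**Centreline smoothing for velocimetry.** An 8-connected skeleton staircase
is up to ~8% longer than the underlying smooth curve; resampling it directly
would inflate every velocity by the same factor. `build_sti()` therefore
smooths the path with a running mean (±5 px window) before arc-length
resampling. The residual velocity bias on synthetic videos is below 2%.

**Orientation search.** The streak slope is found by circularly shearing the
(filtered) STI along candidate slopes and maximizing the variance of the
time-collapsed profile — a Radon-style projection search on a log-spaced
velocity grid (2% grid spacing, parabolic peak refinement in log-velocity).
Speed, not signed direction, is reported: both shear directions are searched
and the magnitude returned, which also makes the estimate invariant to
reversing the centreline parameterization. The quality score is the
peak-to-mean ratio of the orientation-energy profile mapped to $[0,1]$;
segments with quality below 0.2 (configurable) are treated as having no
observable flow and excluded from records — an all-zero STI yields exactly
quality 0. The default search range 0.05–3.0 mm/s brackets conjunctival
velocities (cohort means all fall near 0.5 mm/s) with wide margin; estimates
can only fall inside it, so a vessel faster than 3 mm/s would saturate — at
this magnification such flow is not resolvable anyway.

**CWT filter band.** The Morlet bank (centre frequency $\omega_0 = 6$)
retains spatial wavelengths of roughly 4–40 centreline samples, matching
red-cell column texture at micron-scale sampling; the response is normalized
to unit peak gain so filtering can only remove energy. On very
low-frequency patterns (long plasma gaps) part of the signal lies below the
band; estimation quality is insensitive to this, but the band edges are
exposed as arguments.

## The synthetic generator: what it emulates, what it does not

`generate_vessel_video()` renders the study conditions this pipeline is
meant for: a bright scleral background (intensity 0.8), one dark vessel of
Gaussian cross-section whose FWHM equals the requested diameter (slit-lamp
optics blur a cylindrical absorber into an approximately Gaussian profile —
a hard-edged tube would be unrealistically easy to segment), red-cell
texture as a quasi-regular train of dark blobs spaced ~40 µm advected
along the centreline at the requested velocity (periodic along the curve
so a short clip has stationary statistics), per-frame rigid jitter
(σ = 0.5 px by default), and additive Gaussian sensor noise (σ = 0.01).
The blob train is evenly spaced with ±35% positional jitter and dispersed
amplitudes and widths: erythrocyte columns are roughly regular, a
uniformly random train would leave blob-free stretches that make the
time-averaged vessel unevenly dark, and a strictly periodic one would
alias the streak slope at integer harmonics. An optional static
background texture (`background_texture`, off by default) exists because
registration of a scene containing only one straight featureless vessel
is ill-posed along the vessel axis; tests that need a registrable scene
turn it on. Defaults follow the acquisition they
mimic: 60 frames/s, clips of 300 frames (5 s), vessels 5–45 µm, velocities
0.2–1.0 mm/s. `generate_sti()` produces the analogous ground-truthed
spatio-temporal images directly, and `generate_cohort()` samples two-arm
segment tables whose arm means and SDs default to the published
control-vs-infarct values (diameter 21.43 ± 7.57 vs 22.32 ± 7.66 µm, axial
velocity 0.53 ± 0.15 vs 0.49 ± 0.17 mm/s), truncated to physical bounds.

What the generator does **not** emulate: specular reflections, blinks and
eyelash occlusions, non-rigid conjunctival deformation, vessel crossings and
plexus geometry, illumination drift, and the arteriole/venule distinction.
Passing the recovery suites therefore demonstrates that the estimators are
correct and well-calibrated on clean-but-noisy single-vessel scenes; it does
not demonstrate robustness to the full messiness of clinical video, which
needs real annotated data.

The FWHM rendering convention also means the "true diameter" of a synthetic
vessel is a convention shared between generator and estimator; the
end-to-end tolerance (10%) absorbs any residual convention mismatch rather
than hiding it.

## Statistical procedures

Cohort comparison follows the two-rule aggregation scheme used in this
field, and the two rules are deliberately kept as separate functions because
they give different answers on unbalanced data:

- **Overall comparisons** (`aggregate_per_patient()`): one value per
  patient — the mean over all that patient's segments, all four views
  pooled — so patients contributing many segments do not dominate.
- **Per-group comparisons** (`aggregate_per_group()`): all segments of a
  diameter group enter individually.

`compare_two_cohorts()` gates on normality: Kolmogorov–Smirnov against a
normal with sample-estimated parameters (the Lilliefors-corrected variant is
available as an option; plain KS with estimated parameters is anticonservative
as a normality test, which here only makes the gate *more* willing to use the
t-test), then an independent-samples t-test if both arms pass, otherwise
Mann–Whitney. `anova_posthoc()` runs one-way ANOVA with Levene's test
(centred on the mean) deciding between Bonferroni-adjusted pairwise t-tests
and Games–Howell. `compare_categorical()` uses Pearson chi-square unless an
expected cell is below 5 *or* an observed cell is zero, in which case
Fisher's exact test is used. No correction is applied across the many
parameter-by-group comparisons beyond the post-hoc adjustments — mirroring
standard reporting practice in this literature, and documented so users can
add one.

Repeatability uses the conventional coefficient: for paired repeat
measurements, $\mathrm{CR} = 1.96 \times \mathrm{SD}$ of the paired
differences, the half-width of the interval expected to contain 95% of
repeat differences, reported with the interval
$\overline{d} \pm \mathrm{CR}$:

```{r}
set.seed(1)
first <- rnorm(38, 100, 30)
d <- rnorm(38); d <- (d - mean(d)) / sd(d) * 2.14 + 0.03
repeatability(first + d, first, parameter = "Q (pl/s)")
```

## Numerical conventions and degenerate inputs

- Intensities are floating point in $[0,1]$ end to end; 16-bit quantization
  only on disk.
- EDT distances are pixel-centre to pixel-centre with no half-pixel
  correction; the resulting sub-pixel bias is absorbed by the 1.5 px
  diameter tolerance and documented rather than corrected.
- Ties: reference-frame selection breaks toward the lowest index; skeleton
  traversal visits neighbours in row-major order, making segment
  decomposition deterministic.
- Degenerate inputs fail loudly: stacks need ≥ 2 frames, segments need
  enough samples for an STI, arms need ≥ 3 values, diameters must be
  positive. An all-zero STI is *valid* and means "no observable flow".
- All simulation is seeded; the same seed reproduces videos, STIs and
  cohorts bit for bit, and generators restore the caller's RNG state.

## Validation problem sizes

The shipped validation suites (the package tests and
`scripts/acceptance.R`) use 96–128 px frames, 120-frame clips, 50
repetitions per velocity for the noisy-STI sweep, ten videos for the
end-to-end recovery, and 2000 null replications for the type-I calibration
— sizes chosen so the whole suite runs on a laptop in minutes while keeping
Monte-Carlo error well below the tolerances being checked (e.g. the
binomial SE of a 0.05 rejection rate at 2000 reps is 0.005, a third of the
±0.015 acceptance band).

## Known limitations

- Arterioles and venules are not distinguished; all vessels pool into the
  diameter groups.
- Flow direction is not reported, only speed.
- The vessel filter is a Hessian ridge detector validated on synthetic
  ground truth; it is a stand-in for whatever enhancement a given lab used,
  not a claim of equivalence.
- Velocities outside 0.05–3 mm/s are not searched by default.
- Registration is rigid; blinks and non-rigid motion surface only as
  flagged frames and masked samples.
- MP4 containers are not read directly; convert to multi-page TIFF or frame
  directories first.
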