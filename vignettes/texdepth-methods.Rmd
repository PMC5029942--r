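---
title: "Inferring relative depth from texture: the model behind texdepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring relative depth from texture: the model behind texdepth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 6)
```

texdepth estimates a *relative* 3D depth map, a 2D boundary/ridge sketch
and local slant/tilt statistics from a single monocular grayscale image of
a textured surface. The estimator is a hierarchy of four modules that
abstract areas of the cortical ventral stream — V1, V2, V4 and IT — and
exploits one physical regularity: when a textured surface slants away from
the viewer, its image texture is compressed perpendicular to the tilt
axis, and under perspective projection its spatial-frequency content
shifts upward with distance. Texture gradients are therefore depth
gradients, and integrating them spatially yields a globally ordered depth
field.

This vignette explains the model, its parameters, the synthetic-stimulus
generator used to test it, and the numerical and design choices made where
the architecture left them open.

## The processing cascade

Every module applies the same three-stage dynamics to its input:

1. **Filtering** by a module-specific receptive-field bank (the drive).
2. **Modulatory feedback**: the drive is multiplied by `1 + net`, where
   `net` is a gated signal from modules higher in the hierarchy.
   Feedback can only enhance existing activity, never create it.
3. **Normalization**: a pooled inhibitory signal acts subtractively and
   divisively.

The steady-state response of a unit at location $i$ with feature
$(\theta, \omega)$ is

$$ r_{i} \;=\; \Big[\, \frac{\beta\, d_i\, (1 + \mathrm{net}_i) - \xi\, q_i + \eta}
                         {\alpha + \gamma\, d_i\, (1 + \mathrm{net}_i) + q_i} \Big]^+ $$

with drive $d_i$, feedback $\mathrm{net}_i$ and inhibitory pool

$$ q_{i} \;=\; \delta \Big( \sum_{\text{feat}} r_{i,\text{feat}}
      \;+\; \epsilon \sum_j \max_{\text{feat}} (r_{j,\text{feat}})\, \Lambda^{\text{pool}}_{ij} \Big), $$

where $\Lambda^{\text{pool}}$ is a unit-sum isotropic Gaussian over a
spatial neighbourhood and only the per-location feature maximum enters the
spatial term. Responses saturate at $\beta/\gamma$, are depressed toward
$-\xi$ by inhibition (then half-wave rectified), and $\alpha$ controls how
linearly saturation is approached. The feedback signal from a higher
module with activity $h$ is

$$ \mathrm{net}_i \;=\; \big[\lambda_{FB} - h_i\big]^+ \cdot
      \big(\Lambda^{\text{pool}} * h\big)_i , $$

a saturating gate *on the sending module's own activity*: where the higher
module already responds at $\lambda_{FB}$ or above, no further enhancement
is delivered; where it is locally weak but its neighbourhood is active,
the lower-level units are enhanced. This one mechanism both bridges gaps
(interpolation) and withholds enhancement from already-dominant structure,
which the rising divisive pool then actively suppresses — the origin of
the ridge reduction and noise cleanup seen when feedback is enabled.
During development we also evaluated the alternative reading in which the
*receiving* module's activity is gated; it made feedback amplify exactly
the anisotropy ridges it is supposed to tame, so the sender-gated form is
the default (`feedback_signal()` retains an `r_own` override).

The four modules are coupled V1 → V2 → {V4-sketch, V4/IT-depth}, with
feedback edges depth→grouping, sketch→grouping and grouping→V1 (gains in
`fb_gains`; the direct depth→V1 edge is wired but defaults to gain 0 —
the replicated, single-band IT activity otherwise stamps its own spatial
structure into V1). The loop runs for `n_cycles` synchronous passes
(default 3; the first pass is feedforward). Updates are damped,
`r <- relax * new + (1 - relax) * old`, because a fully synchronous
loop of saturating stages can sustain a slow period-two oscillation;
`relax` below 1 contracts the cycle-to-cycle changes.

### Receptive-field banks

* **V1**: quadrature (even/odd) Gabor pairs on a log-polar grid — 8
  orientations linearly spaced on $[0, \pi)$ and 4 frequency bands
  octave-spaced on $[0.03, 0.25]$ cycles/pixel by default. The envelope
  sigma is $0.562/\omega$ (about one octave of bandwidth). Texture energy
  is the quadrature amplitude, so it is phase- and offset-invariant.
  Bands carry a gain $(\omega/\omega_{\min})^{\text{band\_gain}}$
  (default exponent 1). This matters: with flat band gains, compressing a
  texture merely moves energy between bands and the *summed* energy — the
  quantity the depth pathway differentiates — stays constant; weighting
  finer bands makes summed energy grow under compression, which is the
  texture-gradient signal itself.
* **V2**: bipole lobe pairs — two collinear, unit-mass anisotropic
  Gaussians displaced along the orientation axis (figure-eight layout),
  length 2.5 Gabor envelopes so they can bridge texture gaps. Subfield
  responses pass through a saturating transfer
  $g(x) = x/(s + x)$ and are multiplied, so a cell fires only when both
  sides receive aligned input.
* **V4 (sketch)**: three alternating anisotropic Gaussians across the
  orientation axis (a second-derivative profile, zero total weight)
  acting as an edge/line detector on the grouped maps, followed by an
  isotropic difference-of-Gaussians for sharpening.
* **V4 (gradient)**: two opposite-sign unit-mass Gaussians displaced
  along the gradient direction (a first-derivative profile, zero total
  weight), applied in a single contrast polarity so responses are signed.
  They differentiate the *total* grouped energy map; spatially constant
  energy — however anisotropic the texture — cancels exactly. The signed
  responses then pass a local contrast gain control (division by the
  Gaussian-pooled magnitude of the channel, `fd_gain_sigma`, 36 px): the
  rectified-response floor over an untextured gradient field scales with
  local texture coarseness, which under perspective projection is itself
  a depth correlate of the *wrong* sign; the gain pool equalises that
  floor while preserving the sign structure of genuine energy gradients.
  Finally the responses are apodized at the image frame
  (`border_taper`), which is not a texture gradient.
* **IT (integration)**: for each orientation, a pair of large anisotropic
  Gaussians truncated by a 2D sigmoid so each keeps weight on one side of
  the center only. The positive lobe trails the cell against the
  integration direction, so its response accumulates where energy has
  been *rising*; the negative lobe is the mirrored, sign-flipped opposite
  path. The paths are combined by a rule favoring the maximum,
  `max(a, b) - it_opponent * min(a, b)` (the plain hard maximum at the
  default `it_opponent = 0`). The reach is an object-scale property (a
  third of the mask diameter by default), not a texture-scale one, so
  this bank carries a single frequency band; the lobe geometry
  (`length_factor`, `offset_factor`, `lateral_factor`) is exposed, and
  stretching the length factor far past 1 turns the windowed integration
  into a near-cumulative sum over the visual field.

## From orientation distributions to slant and tilt

Grouped activity summed over frequency gives a per-orientation
distribution $d_{\theta}$ at every pixel (pooled with a Gaussian window,
`patch_sigma`, default 8 px — pointwise histograms are noise-dominated).
Because orientation is axial, angles are doubled before averaging:

$$ R = \frac{\sum_o d_{\theta_o} e^{2 i \theta_o}}{\sum_o d_{\theta_o}},
   \qquad \Theta = \tfrac{1}{2}\,\mathrm{atan2}(\Im R, \Re R), \qquad
   \|R\| \in [0, 1], $$

$\Theta$ (mapped into $[0,\pi)$; the two-argument arctangent fixes the
quadrant) is the axis of anisotropy — the slant direction is perpendicular
to it, ambiguous by $\pi$ — and $\|R\|$ grows with slant (1 for a single
active orientation, 0 for a uniform distribution). The anisotropy index
$A = 1 - \min_o d / \max_o d$ is a second slant correlate. Neither is
calibrated to metric slant angles; the model claims proportionality only.

## Depth formation and finalization

The signed gradient responses are integrated by the one-sided IT lobes;
activity therefore accumulates in the direction of rising texture energy
and, through the opposite path, of falling energy. Summing all channels
gives a raw activity field in which **higher activity means farther
away**. Finalization masks the field, smooths it (`smooth_sigma`, 3 px),
inverts it by subtracting from its maximum and divides by that maximum —
so values live in $[0,1]$ with 1 nearest. Dividing by the maximum (rather
than rescaling by the range) matters for flat scenes: activity has a
natural zero, and a frontoparallel surface yields a field whose
fluctuation is small relative to its mean, hence a near-constant depth
map. If no gradient activity at all survives normalization, the percept
is reported as exactly frontoparallel (a constant map) rather than as
noise rescaled to full contrast.

Two properties follow from the architecture and are worth keeping in mind
when reading results:

* **Convexity preference.** An isolated object whose rim is strongly
  foreshortened (e.g. a semisphere) generates inward- and outward-rising
  energy gradients; both one-sided integration paths deposit activity
  between rim and border, leaving the object center as the activity
  minimum — i.e. the nearest point. Ambiguous convex/concave stimuli are
  resolved convex.
* **Underestimation.** Saturating normalization compresses large energy
  ratios, so steep surface inclinations and deep concavity modulations
  come out shallower than the ground truth.

### Contour (planar-cut) textures

Contour textures do not disambiguate the integration direction, so
`contour_mode()` requires an explicit direction. It is interpreted as the
integration *axis*: both one-sided paths of the aligned orientation
channel keep full weight while transverse channels fall toward
`direction_low_weight` (attenuating a single one-sided path instead would
force a monotone profile and could never produce the interior depth
maximum a striped cylinder shows), and the integration reach is enlarged.
The direction is never guessed; omitting it is an error. Multi-axis inclined sinusoidal
surfaces remain a known failure case of the architecture.

## The synthetic-stimulus generator

`render_scene()` replaces rendered test imagery with analytically
controlled height fields: slanted planes, a plane with a central
semisphere, bell convexities/concavities, a doubly curved surface (a
gentle slope carrying one bump and one dip), multi-level depth steps,
cylinders and an inclined sinusoidal plane. Textures are drawn *on the
surface*, locally: dots are scattered on a jittered world lattice with
uniform density per unit surface area (extra dots appear in slanted
cells) and each dot is a disc on the local tangent plane, so its
projection is an ellipse with minor/major ratio exactly
$\cos(\text{slant})$ — the foreshortening cue — while orthographic
projection carries no dot-size cue; contour lines are true planar cuts
(level sets of a tilted cutting-plane family, height contours in the
shape-linked case); noise is 3D value noise sampled on the surface.
Because texturing is local there is no global surface parameterization
and hence no path-dependent distortion behind curved objects.
Perspective projection (pinhole, configurable field of view) adds the
scale/density gradient. Ground-truth depth is the distance along the
camera ray, inverted and min-anchored to $[0,1]$ (height fields have an
arbitrary offset; model activity does not, which is why the model side
is only divided by its maximum). Everything is deterministic in
`(spec, seed)`.

Default dot geometry is 18 px spacing and 6 px radius with full-cell
jitter: at low jitter the dot lattice itself is strong collinear
structure that the grouping stage legitimately picks up as global
streaks, and with much smaller dots a strongly foreshortened dot's minor
axis falls below both the render's resolution and the filter bank's
frequency range, erasing the rim-anisotropy signal the model needs. The
generator emulates texture compression, frequency shift and masking; it
does not emulate shading, shadows, occlusion of dots at grazing angles,
or sensor noise — so passing tests here show the texture-gradient
pathway works, not that the model is robust to photometric confounds.

## Numerical choices

* Filtering is FFT cross-correlation with mirror-reflected borders
  (a hard zero border would masquerade as a texture gradient); kernel
  spectra are cached per fit and reused across feedback cycles.
* Gradient responses are apodized at the image frame (`border_taper`,
  raised cosine over 12 px): the frame edge is not a texture gradient.
* Kernel supports are $6\sigma$, rounded to odd sizes; constructors
  reject supports truncating the envelope below $3\sigma$.
* The cascade runs a fixed number of cycles (3, with an early stop at
  max-change $10^{-4}$ inside `run_stage()`); no convergence tolerance is
  claimed beyond the damped updates described above.
* Degenerate inputs are contracts, not surprises: an all-zero orientation
  distribution yields flagged-NA slant statistics; an empty mask or an
  all-zero depth field is an error in `depth_finalize()` (the full model
  maps the latter to the flat percept); a missing integration direction
  in `contour_mode()` is an error.
* With $\eta = 0$ (default) a blank image propagates to blank outputs
  exactly; $\eta$, and a pointwise V1 nonlinearity (`v1_transfer`),
  are exposed but off by default.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| `n_orientations`, `n_frequencies` | 8, 4 | — | channel grid; orientation bin width $\pi/8$ |
| `freq_range` | 0.03–0.25 | cycles/px | V1 band limits, octave spacing |
| `band_gain` | 1 | exponent | frequency weighting; the compression-to-energy link |
| `beta, gamma` | 1, 1 | — | activity ceiling $\beta/\gamma$ |
| `xi, delta, eps` | 0.5, 0.04, 1.5 | — | inhibition strength; the noise gate |
| `alpha` | 0.25 | — | contrast semi-saturation |
| `lambda_fb` | 0.35 (0.2 for V2) | activity | feedback gate level |
| `fb_gains` | 2 / 0 / 1 / 3 | — | edge gains I←II, I←IV, II←III, II←IV |
| `n_cycles`, `relax` | 3, 0.8 | — | feedback passes, update damping |
| `bipole_length` | 2.5 | Gabor envelopes | grouping reach (gap bridging) |
| `transfer_s` | 0.05 | activity | bipole subfield saturation |
| `it_extent` | mask diameter / 3 | px | integration reach |
| `it_lateral` | 0.35 | fraction of reach | lateral pooling of IT lobes |
| `it_opponent` | 0 | — | opponent weight of the opposing integration path |
| `it_drive_gain` | 10 | — | gain of the integrated depth drive into module IV's normalization |
| `fd_gain_sigma` | 36 | px | gradient contrast gain pool |
| `border_taper` | 12 | px | frame apodization of gradient responses |
| `patch_sigma` | 8 | px | slant/tilt pooling window |
| `smooth_sigma` | 3 | px | final depth smoothing |

The cascade constants are implementer calibrations: they were tuned on
the package's property suite (saturation bound, flat-scene null, slant
monotonicity, ridge reduction under feedback, convexity preference) and
are all exposed in `texdepth_config()`. Counts, scales and gains are
configurable throughout; none is hard-wired.

## Problem sizes used by the test suite

The equation-level checks run on 8×8×4×2 stacks against brute-force loop
oracles. Filter and grouping behaviour is tested on 41–96 px synthetic
images. The scenario-level properties (flat null, slant/field-of-view
dissociation, semisphere convexity and feedback effects, depth-step
ordering, texture invariance of a doubly curved surface) run on rendered
scenes at 300×300 px — the scale at which the default filter grid and the
stimulus geometry are matched — with smaller 96–128 px scenes used where
only qualitative behaviour is exercised.

## Known limitations

* Relative, not metric: outputs are depth *orderings*; slant statistics
  are proportional correlates, not calibrated angles.
* No compensation for perspective distortion of the image frame itself.
* Figure-ground segregation is assumed (the mask is an input), and
  T-junction detection on the sketch is out of scope.
* Contour textures need an externally supplied integration direction;
  multi-axis inclined sinusoidal planes are not recovered.
* The convexity preference is a bias: genuinely concave isolated objects
  will tend to be reported convex.
* A single texture realization carries realization noise into the depth
  field; profiles on flat scenes undulate at the few-percent level even
  when the scene is perfectly planar.
* The within-surface slant profile under perspective is the weakest
  output: local texture-coarseness variation modulates the rectified
  gradient responses by more than the true energy ramp does, so the
  recovered mid-profile of a uniformly slanted plane can come out flat
  or even inverted relative to ground truth (the acceptance script
  reports the measured rank correlation). Depth *contrasts* between
  differently slanted regions (domes, rims, steps) are recovered much
  more reliably than smooth within-surface ramps.
* Recovered depth amplitudes are strongly compressed relative to
  geometry (the underestimation bias taken to its extreme), so
  value-based error statistics are meaningful only after rescaling;
  rank statistics are the robust way to read the maps.

## Interface note

The package is a library, not a shell tool: `texdepth()` (with its
`print`, `summary`, `plot`, `predict`, `coef`, `fitted` and `residuals`
methods), `render_scene()`, `contour_mode()`, `sketch_map()`,
`orientation_map()`, `relative_error()` / `compare_profiles()` and the
`export_*()` helpers are the operations a shell front-end would otherwise
expose as subcommands.
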