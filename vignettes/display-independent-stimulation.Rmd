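---
title: "Display-independent visual stimulation: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Display-independent visual stimulation: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5, fig.height = 4)
library(retinowin)
```

## The problem retinowin addresses

Vision experiments specify stimuli in *degrees of visual field* — a grating
of 0.05 cycles/degree, a 5° dot at +60° azimuth — but hardware delivers
*pixels on a panel* whose size, distance and orientation differ between
rigs. retinowin separates the two concerns. A stimulus is defined once, in
retinocentric coordinates; the rig (displays, projector meshes, stereo
eyes) is described separately; and a fixed geometric pipeline guarantees
that every rig shows the same visual-angle image. The same separation makes
display calibration a measurement problem (photograph the rig) rather than
a tape-measure-and-protractor ritual.

The pipeline has three stages:

1. **Retinocentric canvas.** 2D stimuli live on an equirectangular chart:
   azimuth on the horizontal axis, elevation as latitude on the vertical
   axis, both linear in degrees. True Mercator (log-tangent latitude)
   diverges at the poles and would make "span of 120° elevation"
   ill-defined, so the chart is linear in latitude; this is a deliberate
   reading of an ambiguous convention and is documented rather than
   configurable.
2. **Observer-centred cube map.** The canvas (or a 3D scene of planes,
   spheres and cubes) is projected onto six square faces around the
   observer. Each face texel stores the luminance along one view
   direction, so the cube map is a complete, display-agnostic record of
   the 360° surround.
3. **Windows.** Each display pixel corresponds to the ray from the
   observer through that pixel's physical location; the pixel simply
   fetches the cube-map texel its ray points at. Projector domes use a
   warp mesh (pixel → direction lookup) instead of a flat-panel pose, and
   stereo paths raycast the scene once per eye through supplied
   view/projection matrices.

## Coordinate conventions

All frames are right-handed with **+x right, +y up, +z forward** (the
gaze direction at zero azimuth/elevation). Azimuth is positive to the
observer's right and wraps on (−180°, 180°]; elevation is positive up in
[−90°, 90°]. The direction of (azimuth *a*, elevation *e*) is
(cos *e* sin *a*, sin *e*, cos *e* cos *a*).

A display panel's local frame has +x and +y being "right" and "up" *as
seen by the observer*, with +z completing the right-handed frame — i.e.
pointing from the viewable surface into the panel, away from the viewer.
With this convention a display one-fifth of a metre straight ahead has the
identity orientation, and texture coordinate *u* = 1 (the right edge of
the image) lands on the physical point at positive local x. Pixel centres
sit at half-integer texture offsets; the top-left pixel is (0, 0) with *v*
increasing downward, the usual image convention. Both choices are made
explicitly to avoid off-by-half and mirror-image errors, the two classic
failure modes of window-geometry code.

Orientations are stored as rotation matrices (orthonormality checked at
construction). Rig files give them as three angles in degrees applied as
`Rz(rz) Ry(ry) Rx(rx)`; pose streams interpolate position linearly and
orientation by quaternion slerp. Pose averaging in the calibration module
uses the chordal mean of unit quaternions (principal eigenvector of the
outer-product sum), the standard choice when a handful of nearly-agreeing
rotations must be fused.

## Rendering: the reference raycaster

All rendering is software raycasting with analytic intersections (quadric
for ellipsoids, slab method for boxes, plane-rectangle for planes) and
exact nearest-hit depth resolution. There is no GPU path: the point of
this implementation is a deterministic, platform-free reference whose
output *defines* correctness, at desk-scale problem sizes (cube-map faces
of 64–256 texels, displays of 10⁴–10⁵ pixels). An observer inside an
object sees its interior surface — the nearest intersection at positive
ray parameter is used regardless of surface side.

Cube-map details worth knowing:

- Face selection uses the largest direction component, with ties broken
  in the fixed order +x, −x, +y, −y, +z, −z. Seams are measure-zero but
  the tie-break makes them testable.
- Within-face sampling is gnomonic with bilinear interpolation, clamped
  at face borders, so luminance is continuous across seams to within one
  texel. A nearest-texel mode exists for bit-exact tests.
- No antialiasing by default; `supersample = TRUE` averages a 2×2 sub-grid
  per texel. Tests use the default so expected values are exact.

The angular pitch of a face texel at face centre is atan(2/n)·√2 ≈ 0.63°
for n = 256; every rendering tolerance in the test-suite ("within one
texel of blur") is stated relative to this pitch.

Warp meshes store *directions* (azimuth/elevation per node), not 3D dome
points, which decouples the mesh from any dome radius. Rendering through
a mesh bilinearly interpolates the node direction *vectors* (then
renormalises) rather than the angles, so meshes may straddle the ±180°
azimuth wrap safely. Cells with any invalid node render black.

The stereo path accepts per-eye view and projection matrices. The package
convention keeps +z forward in eye space (an OpenGL-style matrix, which
looks down −z, converts by negating its third row); only the two diagonal
frustum terms shape rays, so any standard symmetric perspective matrix
works. Eyes are displaced ±ipd/2 along the head's x axis with parallel
gaze (no toe-in).

## Stimuli

Gratings are defined on the azimuth/elevation chart relative to the canvas
centre: `L = mean(1 + c·sin(2π f (a cosθ + e sinθ) + φ))`, clipped to
[0, 1]. The stated cycles/degree therefore hold exactly along the chart's
equator; away from it the chart compresses physical angle, and this
distortion is documented rather than compensated — correcting it would
change the stimulus class, not just its parametrisation. Checkerboards
take the parity of ⌊a/size⌋+⌊e/size⌋ about the canvas centre. Dots use
*great-circle* distance, so a 5° dot subtends 5° of arc anywhere in the
field, including high elevations where the chart is strongly stretched.

Sparse noise presents exactly one black or white square per
presentation, 0.1 s each, at a grid location drawn uniformly **with
replacement** (independent draws — the simplest sampling rule that makes
every presentation exchangeable), polarity uniform. The whole sequence is a pure function of its seed.
Default canvas resolution is 4 texels/degree — fine enough that a 5° dot
spans 20 texels, coarse enough that a full 360°×180° panorama stays under
a megatexel.

## Calibration

A photograph of the rig with square fiducial markers recovers display
poses. The marker family is generated in code: 4×4 payload bits inside a
one-cell black border, scanning 16-bit patterns in numeric order and
keeping those whose four rotations are mutually ≥ 4 bits apart (so
orientation is decodable) and ≥ 4 bits from every rotation of every
earlier marker. Packaging the generator rather than a table keeps the
synthetic tests self-contained.

Detection: global threshold at the midrange, connected dark components,
convex-hull quadrilateral fit, perspective payload decoding over all four
rotations, then sub-pixel corner refinement by intersecting
total-least-squares line fits to threshold crossings along each border
edge. On synthetically rendered photos the refined corners are good to
about 0.2 px, and the pose to well under 1% of range.

Pose estimation is planar perspective-n-point: a DLT homography between
marker-plane and normalised image coordinates is decomposed into an
initial rotation/translation; both branches of the planar ambiguity (the
second obtained by reflecting the plane normal about the line of sight)
are refined by BFGS minimisation of the reprojection error, and the branch
with lower RMS wins. Camera intrinsics must be supplied — self-calibration
is out of scope.

Markers attach to displays (or to the observer) flush on the attachment
plane with the pattern upright, which makes the offset rotation the
identity and leaves only an in-plane offset in the marker map. If no
observer marker is present, the camera's optical centre is taken as the
observer; the camera frame shares the observer frame's axis convention,
so the fallback is a pure frame identification.

Luminance linearisation fits `L(v) = L_min + (L_max − L_min)·v^γ` by
Levenberg–Marquardt; the offset-plus-power form is this package's model
choice, flexible enough for LCDs and projectors with non-zero black
levels. The inverse lookup `v = x^{1/γ}` is
quantised to the display's command levels. The fit rejects fewer than four
distinct commands, commands not spanning [0, 1], and data whose rank
correlation with luminance is ≤ 0.8 — a deliberate softening of "reject
non-monotonic" so that honest 1%-noise measurements, which are locally
non-monotonic near black, still fit.

## Protocols

The virtual platform is a three-state machine (running → grey → next
trial) with the trial ending at 100 cm or 60 s, a 2 s grey interval, and
backward displacement clamped at the start line. Threshold comparisons
carry a 1 ns slack so that exact boundary crossings survive floating-point
accumulation of time steps. The wheel maps encoder counts to displacement
by circumference (2πr·counts/cpr, r = 10 cm by default).

Frame-drop accounting declares a drop when an inter-presentation gap
exceeds 1.5× the nominal interval, counting `round(gap/nominal) − 1`
drops per gap; the 1.5× threshold is this package's rule, chosen so
uniform ±2 ms jitter at 60 Hz never false-alarms. The photodiode sync
square is white on even frames, black on odd, stamped after rendering and
*before* any linearisation LUT, so photodiode contrast stays maximal.

The defensive-behaviour classifier applies the field's standard
definitions on the raw (unsmoothed) speed trace: freezing is speed
strictly below 2 cm/s for strictly more than 0.1 s (event time = interval
start), flight is the first crossing strictly above 40 cm/s, and events
count only if they begin within 3.5 s of stimulus onset. Interval duration
is measured between first and last sub-threshold samples, so at 60 Hz a
run of ⌈0.1·60⌉+2 samples is the shortest detectable freeze. Multi-dip
trials report every qualifying freeze interval; callers wanting "the"
freeze take the first row.

For augmented-reality windows the observer pose is interpolated at the
query time, the scene re-rendered from that pose, and each fixed display
rendered as a window. Approaching a window *shrinks* an outside object's
footprint on the glass while *growing* its visual angle — both are
asserted in the tests, because the first is the counter-intuitive
signature of correct window optics.

## The synthetic neuron and what passing tests show

`simulate_sparse_noise_neuron()` is an inhomogeneous Poisson cell: a
homogeneous baseline plus, per presentation, extra rate
`gain·exp(−d²/2σ²)` (d = grid distance to the receptive-field centre)
during a 0.1 s window after a fixed latency. The default study condition
for recovery tests is a 12×12 grid, 2000 presentations of 0.1 s, gain
50 spikes/s over baseline 2 spikes/s — sizes chosen to mirror a short
real mapping session.

The analysis chain bins spikes at 60 Hz, smooths with a Gaussian kernel
(σ = 300 ms by default, truncated at ±3σ, unit-normalised, symmetric edge
padding; an FWHM interpretation is selectable, since the literature quotes
Gaussian filter widths both ways), and maps the receptive field
as the mean response in a 0–0.2 s window after each location's onsets,
minus the grand-mean baseline. Never-stimulated locations are `NA`, not
zero. The LFP path is the same code on a continuous trace.

What the passing recovery tests do show: the full pipeline — seeded
stimulus sequence, Poisson spiking, binning, smoothing, reverse
correlation — returns the planted centre within one grid cell in ≥ 19/20
seeded runs, and map amplitude is linear in gain. What they do not show:
robustness to spike-sorting errors, non-Poisson firing, adaptation,
correlated noise, or misaligned clocks; real recordings have all of
these, and the synchronisation step that aligns spike times to stimulus
timestamps is explicitly an input here, not something the package checks.

## Numerical choices collected

- Rotation orthonormality and unit-vector checks at 1e-9.
- Azimuth fold onto (−180°, 180°] maps atan2's −180° to +180°.
- Bilinear sampling clamps within half a texel of borders (canvas, cube
  faces, warp meshes alike); nearest modes are provided wherever a test
  needs bit-exactness.
- Poles: elevation ±90° maps to a single direction; round-trip tests
  exclude the poles where azimuth is undefined.
- Ray intersections reject hits closer than 1e-9 m; the observer
  coincident with a display point (< 1e-12 m) is an error, not a NaN.
- Gamma-fit start values come from the data range and a log-log slope;
  Levenberg-Marquardt then converges to machine precision on noise-free
  input.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script run at: 1°-grid round trips
(64 440 directions); cube maps of face resolution 256 with 1000-direction
raycast comparisons on 3-object scenes; two-display invariance at
220–260 px panels over a 120°×120° canvas at 4 texels/degree; 960×720
synthetic calibration photographs; 26-level gamma curves; and 20
receptive-field recovery runs of 2000 presentations each. These sizes
keep a full run in the low minutes on one CPU while leaving every
tolerance meaningfully exercised.

## Known limitations

- No lighting, shading, transparency or mipmapping; surfaces are flat
  albedo. The renderer is a geometric reference, not a graphics engine.
- Chart-coordinate gratings distort away from the equator (documented
  above); users needing constant spatial frequency along great circles
  should generate stimuli per-direction.
- Single global threshold in marker detection: it is robust for
  photographs where markers are the darkest structures, which is the
  intended use, but strongly shaded photos may need pre-processing.
- One photo, no bundle adjustment: multi-view refinement is out of scope.
- Real-time hardware I/O is out of scope; encoder and pose streams are
  files or in-memory tables.
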