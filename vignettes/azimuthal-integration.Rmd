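---
title: "Azimuthal integration of 2D scattering images: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Azimuthal integration of 2D scattering images: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsdr)
```

# The reduction model

A 2D scattering frame is a grid of photon counts `p`. Azimuthal integration
averages all pixels falling into the same radial element of scattering-vector
magnitude `q`, producing a 1D curve. saxsdr formulates the whole reduction as
one sparse matrix–vector product per frame:

$$\mathbf I = (\mathbf C\,\mathbf p) \oslash \mathbf A, \qquad
  \mathbf A = \mathbf C\,\mathbf 1, \qquad
  \mathbf E = \sqrt{\mathbf I \oslash \mathbf A},$$

where $\mathbf C$ is the $n_\mathrm{bins}\times n_\mathrm{pixels}$ weighting
matrix, $\mathbf A$ the per-bin effective area in pixels and $\oslash$
elementwise division. $\mathbf C$ depends only on the calibration, so it is
built once and reused across frames; per-frame cost is a sparse matvec.

The error model assumes independent Poisson-distributed pixel counts — the
appropriate statistics for photon-counting detectors. A bin averaging $A_j$
pixels of mean $I_j$ then has variance $I_j/A_j$, giving the standard error
$E_j=\sqrt{I_j/A_j}$ of the reported mean. This is validated in the test
suite by a 10 000-frame Monte-Carlo experiment on a bin of area 100 fed
Poisson(9) pixels: the empirical spread of the bin mean reproduces the
predicted $E = 0.3$ to within a few percent. The model ignores detector
read-out noise (negligible for photon-counting sensors) and inter-pixel
correlations (e.g. charge sharing).

## Tilted-detector geometry

The geometry follows the FIT2D angle convention: a tilt rotation $\varphi$
(the in-plane direction of steepest tilt, from the horizontal detector axis)
and a tilt angle $\tau$ (between the primary beam and the detector normal).
Each pixel is described by its in-plane distance $r$ from the beam center
and azimuth $\psi$. The full 3D problem collapses into a per-pixel
distortion angle

$$\alpha = \arcsin(\sin\tau\,\cos(\psi-\varphi)),$$

after which the plane spanned by the beam, the beam center and the pixel is
an exactly solvable 2D triangle:

$$l = \sqrt{d^2 + r^2 + 2dr\sin\alpha}, \qquad
  \tan 2\theta = \frac{r\cos\alpha}{d + r\sin\alpha}, \qquad
  q = \frac{4\pi}{\lambda}\sin\theta.$$

These expressions are exact (no small-angle approximation). Their
correctness is pinned down not by transcription but by contracts: at
$\tau=0$ the full frame must match the closed form
$q=(4\pi/\lambda)\sin(\tfrac12\arctan(r/d))$ to $10^{-9}$ nm⁻¹; pixels on
the tilt axis ($\psi-\varphi=\pm90^\circ$) must be tilt-invariant; and for
randomized $(\varphi, \tau\le30^\circ)$ the result must agree to $10^{-6}$
relative with an independent 3D ray-construction oracle that rotates the
detector plane in space and measures the angle between the incident and
scattered rays directly.

**Sign convention.** The orientation of the tilt-axis rotation is the one
genuinely open choice: both orientations satisfy every magnitude contract.
saxsdr fixes it so that the steepest-tilt direction $\psi=\varphi$ tips
*away* from the sample for positive $\tau$ (lengthening the light path
there), and the test-suite oracle constructs its rotation with the same
orientation. Swapping both signs consistently would describe the mirrored
mounting.

Pixels are evaluated at their centers, 0-based, row = vertical/slow axis
from the top-left of the stored image; the beam center is specified in the
same center-based frame and may be fractional. Calibration I/O keeps the
file units (degrees, mm, µm, Å, nm⁻¹); all internal trigonometry is in
radians.

## Binning and anti-aliasing

Bins are uniform in $q$ from 0 to the largest unmasked $q$, with the bin
count taken from the calibration's radial step width in detector-pixel
units: $n_\mathrm{bins} = \lfloor r_\mathrm{max,px}/\mathrm{step}\rfloor$
(at least 1). Whether the radial elements live in detector radius or in $q$
only matters under tilt, where equal-width $r$ annuli map to unequal $q$
intervals; binning in $q$ keeps the output grid physically meaningful and
coincides with $r$-binning at zero tilt, which is why it was chosen. For
anisotropic pixels the mean of the vertical and horizontal pixel size
defines the pixel-radius unit.

Nearest-bin assignment of whole pixels causes visible artifacts where bins
are only a few pixels wide (near the beam center): a pixel lies on the
border of two radial elements, or an element cuts through a pixel. The
anti-aliasing scheme subdivides each unmasked pixel into $k\times k$ equal
subpixels ($k$ = `oversampling`) and deposits weight $1/k^2$ into the bin
containing each subpixel center's $q$. Consequences, all tested:

* every unmasked pixel fully inside the binned range has column sum exactly
  1, so a constant frame integrates to a constant curve and total intensity
  is conserved ($\sum_j A_j I_j$ = total in-range unmasked counts, to
  $10^{-9}$ relative);
* $k=1$ reproduces plain nearest-bin assignment exactly, and the whole
  reduction then agrees with a brute-force per-pixel loop to $10^{-10}$;
* as $k$ grows ($1\to2\to4\to8$) curves converge monotonically to the
  scheme's own high-$k$ limit. Note the limit of bin $j$ is the *bin
  average* of the underlying profile over the pixels it covers, not the
  profile evaluated at the bin center; against bin-center values the error
  plateaus at that (small) averaging bias instead of decreasing
  indefinitely.

Ties at bin edges are broken by half-open intervals (`findInterval`
semantics, last edge closed), so each subpixel lands in exactly one bin.
Bins with zero effective area are omitted from the output curve rather than
emitted as NaN rows, keeping `.chi` files plot-ready.

## Masks, sentinels and degenerate inputs

A mask is a logical grid in which `TRUE` excludes a pixel (the FIT2D
polarity). Masked pixels are structurally absent columns of $\mathbf C$ —
exclusion by construction, with nothing to poison sums. Frames may
additionally carry negative sentinel counts (module-gap markers such as
−1/−2); these pixels are excluded per frame, with their weights also removed
from $\mathbf A$ so the affected bins stay unbiased. A fully masked frame is
rejected at binning time; a frame of the wrong shape or with non-finite
counts is rejected at integration time.

The `.msk` dialect implemented is the de-facto FIT2D binary layout: a
1024-byte header with an ASCII magic and the two dimensions, then bit-packed
rows padded to 4-byte multiples, least-significant bit first. The reader
cross-checks the header dimensions against the calibration and is tested
bit-for-bit against the package's own writer on randomized masks up to
1024×1024. Image-file masks (TIFF/PNG, any nonzero pixel = masked) are
provided as a convenience.

## GISAXS slices

Slices average a band of $2\cdot\mathrm{margin}+1$ rows (x direction) or
columns (y direction) and report the mean against the detector-plane
component $q_H$ or $q_V$, using the same $\sin(\tfrac12\arctan(x/d))$
mapping as the radial $q$ along the detector axes. Deliberately **not**
applied: Ewald-sphere distortion correction, incidence-angle correction, and
detector tilt. In grazing-incidence experiments the incidence angle is only
known reliably after the specular peak has been located, so a conversion
fixed at calibration time would silently mis-scale $q$; the slices are
quick-look monitors in detector coordinates, valid at small angles, and
reciprocal-space mapping is left to specialized offline tools. The `plane`
attribute (`InPlane`/`Vertical`) is orientation bookkeeping relative to the
sample surface and never changes the numerics — a property the tests pin
down.

## Image classifiers

The three per-image summaries are the standard SAXS integral parameters,
evaluated by trapezoidal integration over the curve points inside the
configured window $[q_1, q_2]$ only:

* integral intensity $\int I\,\mathrm dq$ — overall scattering power;
* Porod invariant $\int q^2 I\,\mathrm dq$ — proportional to the total
  scattering contrast volume;
* correlation length $\ell_c = \pi\int qI\,\mathrm dq \big/ \int q^2
  I\,\mathrm dq$ — a mean structural size, in nm.

No extrapolation to $q\to0$ or $q\to\infty$ is attempted: these are
quick-look monitors of change over a measurement series, not absolute
structural parameters, and extrapolation behavior would depend on models the
pipeline cannot know. Windows with fewer than two curve points, and a
vanishing invariant in the denominator of $\ell_c$, yield `NA`. Acquisition
time is read from the ISO-8601 timestamp embedded in the frame's TIFF
header comment when present, else the file modification time. The history's
per-data-set selector keys on the file-name prefix before the trailing frame
number — the serial-acquisition naming convention at beamlines.

# The processing pipeline

The engine state (q map, binning, weighting matrices, masks) is derived from
the calibration once; the picture queue deduplicates by path and is filled
either by the recursive directory walker (offline) or by `"new file"`
events (online). Each worker takes a frame, writes its `.chi` (and slice)
files and appends a classifier record; a corrupt frame increments the
failure counter and never stops the queue. Because frames are independent,
the output files are byte-identical whatever the worker count — the test
suite verifies this at 1 vs 8 workers, and that event-fed and walker-fed
runs produce identical output sets.

Event transport is a file-backed message spool: messages are JSON documents
written atomically (temp file + rename) into a spool directory and consumed
in publication order, carrying exactly the two-field contract
`{"command": "new file", "argument": <path>}`. A feeder publishes an event
only once the target file's size is stable across two polls (100 ms apart by
default) — announcing a half-written frame would make the server read
garbage. Control messages (`new`, `reintegrate`, `abort`, `status`) use a
second spool; `new` carries a full calibration and atomically replaces the
engine state. An optional shared secret adds an HMAC-MD5 tag (built on the
MD5 primitive available in base R) to every message; receivers reject
messages without a valid tag. This is integrity/authenticity tagging of a
trusted-network transport, not encryption. Completed paths are persisted in
a `processed.txt` sidecar next to the output so that re-runs skip done work
unless a reintegration is forced.

Frame decoding reads single-page uncompressed TIFF with 8/16/32-bit
unsigned, 32-bit signed or 32-bit float samples — the layout photon-counting
detectors write — preserving raw counts and sentinels exactly (graphics-
oriented image libraries rescale to a display range, which destroys count
statistics). The reader is cross-checked against libtiff output in the test
suite.

# The synthetic-frame generator

Tests and examples run entirely on generated data. The default synthetic
geometry is a 256×256 sensor with 172 µm pixels (Pilatus-style), 1000 mm
sample–detector distance, beam center (128, 128) and Cu Kα wavelength
1.54 Å — realistic in scale and small enough for sub-second tests. The
generator produces flat fields, sharp rings, and isotropic frames whose
pixel values follow an analytic radial profile (e.g. the homogeneous-sphere
form factor with radius 5 nm and ~1000 peak counts/pixel, matching a
well-exposed dilute-particle exposure), optionally Poisson-sampled under a
fixed seed.

What the generator does *not* emulate — hence what passing tests do not
show about real data: flat-field texture, module gaps beyond simple
sentinels, charge sharing and point-spread, beam polarization and
solid-angle variation, parasitic background, and detector distortion. The
corresponding intensity corrections are likewise out of the package's
scope.

# Problem sizes and tolerances in the checks

The test suite and the acceptance script use 64×64 randomized-calibration
frames for the oracle-equivalence (50 frames), flat-field and conservation
properties; the full 256×256 default sensor for the closed-form geometry
check; 8 randomized tilted geometries (φ uniform on [0°, 360°], τ on
[0°, 30°]) against the 3D ray oracle; a 10 000-frame Monte Carlo for the
error band; and 200 frames for the pipeline invariance runs. These sizes
exercise every code path with comfortable statistical resolution while
keeping a full run in tens of seconds. Tolerances follow the property
class: exact identities (conservation, flat fields, oracle equivalence) are
held to $10^{-9}$–$10^{-10}$ relative; the tilted-geometry oracle to
$10^{-6}$ relative; the Monte-Carlo spread to 5%, the sampling accuracy of
10 000 repetitions.

# Known limitations

* Slices ignore detector tilt and all reciprocal-space distortion (by
  design, above).
* No absolute-intensity calibration, dark/flat correction, polarization or
  solid-angle correction; curves are mean counts per pixel.
* No azimuthally resolved ("cake") regrouping.
* The classifier integrals are window-restricted; they are comparable
  within a series measured with one calibration, not across q windows.
* The worker pool relies on process forking where available; on platforms
  without it, work runs sequentially (same outputs, lower throughput).
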