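---
title: "Modeling ground-level shade and incident solar energy on gridded landscapes"
author: "shadewalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ground-level shade and incident solar energy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shadewalk)
```

## The model

Ground-level solar energy in heterogeneous landscapes is shaped by two
kinds of interception: opaque terrain (a hillslope between a cell and the
sun) and partially transparent objects (tree canopies, buildings). shadewalk
simulates both on a regular grid, per timestep, under a single-distant-source
assumption: at any instant all light arrives along parallel rays fixed by
the solar azimuth $\alpha$ and altitude $\gamma$.

Three co-registered rasters describe the landscape: a digital elevation
model (DEM, bare-earth elevation in metres), a normalized digital surface
model (nDSM, object height above ground), and an object transmittance model
(OTM, the fraction of light each cell's object lets through, 0 = opaque,
1 = transparent). Each cell's object is an implicit voxel of uniform
transmittance; an optional second layer (understory height + transmittance)
splits the column into two stacked voxels so a tree's dense crown and more
open trunk space can differ. Either the DEM or the nDSM may be omitted to
run terrain-only or object-only simulations.

### Solar geometry and clear-sky energy

Per timestep the solar position is computed from spherical astronomy:
declination by the standard $23.45^\circ \sin$ day-of-year model, the hour
angle from civil clock time via the site longitude, the configured UTC
offset and the equation of time, altitude as
$\gamma = \arcsin(\cos\phi\cos\delta\cos\Omega + \sin\phi\sin\delta)$, and
azimuth from the matching horizontal direction components through a
quadrant-safe arctangent (degrees clockwise from north). The implementation
is validated against a second, independently written ephemeris
(`solarPositionMeeus()`, a Meeus-style low-accuracy solar theory using
Julian centuries, the equation of center and sidereal time) — the two agree
to well under a degree, with $r^2 > 0.999$ on hourly series.

Top-of-atmosphere irradiance uses the orbital-eccentricity correction
$EI = S_{sun}\,(1 + 0.034\cos(2\pi n/365.25))$ with $S_{sun} = 1367$ W/m²,
and the incident clear-sky energy on a horizontal surface is

$$EI_{cos} = \sin(\gamma)\; EI \; \mathrm{CS_{CALI}} \; (1 - c),$$

zero whenever $\gamma \le 0$. The $\sin\gamma$ factor is the cosine of the
solar *zenith* angle; all atmospheric losses are folded into the clear-sky
calibration multiplier $\mathrm{CS_{CALI}}$ rather than an explicit
atmosphere model. $c$ is an optional flat daily cloud-cover fraction; no
sub-daily cloud dynamics are modeled, and this flat multiplier is the
package's own minimal interpretation of a daily cloud input.

### The walking algorithm

For every origin cell the model traces the light ray that reaches the
cell's centre, marching *toward* the sun in steps of $v$ metres (default a
quarter of the cell size). The per-timestep step vector is computed once —
run $= \sin(\alpha)\,v$ eastward, rise $= \cos(\alpha)\,v$ northward — and
reused for all origins. Each time the march enters a new cell the ray
height there is

$$\mathrm{Solar_{AH}} = z_{origin} + |\tan\gamma| \times X_{TOTAL},$$

and the cell is assessed:

* **Terrain.** If the ray is strictly below the cell's ground elevation the
  walk terminates; the origin receives terrain shade
  $\mathrm{GR_{CALI}} / n_{cells}$, an inverse-distance weakening (a wall
  one cell away gives maximal topographic shade, distant terrain
  progressively less, standing in for scattered indirect light). A tie
  (ray exactly at ground level) does not terminate.
* **Objects.** If the ray is below the cell's object top
  (elevation + height), the transmittance of the voxel containing the ray
  height — canopy, or understory below the understory top — multiplied by
  $\mathrm{TR_{CALI}}$, is multiplied into the origin's accumulated object
  light fraction $O_{LD} = \prod OT$. Transmittance is applied once per
  *distinct cell*, never per step. The origin's own object never shades
  itself.

A walk ends at terrain interception, at the data-space edge, or when the
ray exceeds the precomputed *ceiling* (the maximum of elevation + object
height over the landscape), above which nothing can intercept it. The
ceiling bound is what keeps a whole-landscape simulation tractable: over
flat ground walks terminate after a single step.

Several traversal details are the package's own resolutions of questions a
step-marching formulation leaves open, chosen for determinism and exactness:

* A sample landing exactly on a cell edge belongs to the cell *ahead* in
  the walk direction, so grazing rays behave deterministically.
* The march detects which cells are entered, but the ray height assessed in
  each new cell is computed at the *exact* geometric boundary-crossing
  distance, not at the sample position. Consequently the accumulated light
  fraction does not depend on the step length $v$ (any $v$ no larger than
  the default reproduces the same result), and agreement with a continuous
  ray march is limited only by knife-edge threshold cases.
* When one step changes both row and column, the intermediate cell the ray
  actually crossed between the two edge crossings is inserted, and the last
  in-grid cell crossed before the ray exits the domain is still assessed —
  without these, cells clipped near corners or at the data edge would be
  skipped systematically at oblique azimuths.
* DEM nodata cells are excluded as walk origins (outputs carry nodata
  there) and are transparent, non-blocking when encountered mid-walk:
  fabricating shade from unknown terrain would bias the outputs darker.
* An area-of-interest mask restricts which cells are walk *origins* only;
  masked-out cells still cast shade, so the physics does not change with
  the reporting region.
* The terminating terrain cell contributes terrain shade but its own object
  is not additionally applied; terrain termination is final.

### Output composition and aggregation

With object light $O_{LD}$ and terrain shade $T_{SHADE}$ per cell, the
surviving light fraction is $L = O_{LD}(1 - T_{SHADE})$, total shade is
$1 - L$, and ground-level energy is $L \times EI_{cos}$. On the shade scale
0 means no shade and 1 complete shade, so an unshaded cell keeps its full
energy and the decomposition identity
$1 - \mathrm{Shade_{TOTAL}} = (1-\mathrm{O_{SHADE}})(1-\mathrm{T_{SHADE}})$
holds cell-wise, exactly. (Read literally, the printed composition of total
shade times energy would zero the energy of a fully *unshaded* cell; the
light-fraction form used here is the only reading consistent with a scale
on which 1.0 is "no reduction".)

Timesteps aggregate over configurable windows: shade grids as means over
*daylight* timesteps only (shade is undefined without incident light; a
window entirely at night yields NA shade), energy either as mean power over
all steps of the window (W/m², nights contributing zero) or accumulated as
power × step duration (J/m²). Energy can be reported as PAR photon flux
via a configurable conversion factor, default 2.02 µmol s⁻¹ W⁻¹ — a
generalized shortwave-to-PAR conversion appropriate when no site spectral
data exist. Outputs are written as ESRI ASCII grids with deterministic
names; identical configurations produce byte-identical files.

## Calibration

Three multipliers adapt the physical skeleton to a site:
$\mathrm{CS_{CALI}}$ scales clear-sky energy (atmospheric losses),
$\mathrm{TR_{CALI}}$ multiplies every object transmittance uniformly
(multiplication rather than an additive shift keeps transmittances inside
[0, 1] and composes naturally with the product rule), and
$\mathrm{GR_{CALI}}$ scales terrain shade (initial setting 0.5). All are
nominally in (0, 1]; the peak update can exceed 1 when the model
under-predicts, which is reported with a warning rather than clamped.

`calibrationWorkflow()` reproduces the staged procedure: a baseline run at
the initial settings; then

$$\mathrm{CS_{CALI}} = 1 - \frac{PSE_{SIM} - PSE_{OBS}}{PSE_{OBS}}$$

from the baseline and observed peak energies (note the observed-peak
denominator: one application matches the peaks exactly only to first order
in their relative difference, which is ample when the discrepancy is a few
percent); then a deterministic grid search (default resolution 0.005 over
[0, 1]) over $\mathrm{TR_{CALI}}$ and $\mathrm{GR_{CALI}}$ in a
configurable order — calibrate the dominant influence first — minimizing
the RMSE of the probe-cell series against the observations. The grid
search replaces a manual visual-fit procedure with a reproducible
equivalent driven by the same criteria. The probe comparison adds the
configured sensor height to the probe cell's ground elevation, matching
how PAR sensors are mounted above ground.

Because the three multipliers act on structurally separate parts of a walk
(incident energy; each penetrated voxel's transmittance; terrain shade),
the workflow walks the probe cell once per timestep, records the penetrated
transmittances and terrain state, and evaluates every candidate parameter
triple exactly from that summary — hundreds of grid points cost no further
walks.

Fit statistics are mean-error (mean of simulated − observed), RMSE, and
percent-agreement defined here as $\sum obs / \sum sim$, so values below 1
indicate over-prediction. Percent-agreement lacks a standard definition in
this context; this ratio is the package's documented choice, and no claim
is made that it reproduces any particular published agreement figure.

## Synthetic landscapes and the validation oracle

`makeFixture()` generates the test landscapes: flat plains, single
partially transparent columns, bare terrain ridges, uniform slopes, and
seeded random canopies (default conditions: 20×20 cells of 10 m, 30–35%
canopy cover, heights uniform on 5–25 m, transmittances uniform on
0.2–0.8 — magnitudes typical of conifer stands represented at stand
scale). Identical seeds give bit-identical landscapes, and generation never
disturbs the caller's global random state. What these fixtures deliberately
do *not* emulate: within-crown structure and light dappling, terrain-canopy
correlation, LiDAR noise, or any real site's geometry — so passing tests
demonstrate the geometry and bookkeeping of the algorithms, not predictive
skill on field data, which requires site observations for calibration.

`bruteForceLightFraction()` is the independent check on the walking
algorithm: it marches a 3-D point along the exact sun direction at a fine
step (default cellsize/50), with plain floor cell-indexing, per-sample
height tests, and none of the engine's rise/run caching, entry-distance
geometry or quarter-cell stepping — agreement between the two is evidence,
not tautology. In validation studies the oracle runs at cellsize/400: a
fixed-step march misses cells whose chord through a corner is shorter than
its step (at azimuths within a fraction of a degree of a grid diagonal
every cell is corner-grazing), and the finer step keeps this discretization
error of the *oracle* from dominating the comparison. Residual
disagreements sit on knife-edge geometry: ray heights within the step's
vertical resolution of a canopy top, or chords shorter than the oracle
step.

One discrete-geometry fact matters when testing shadow lengths analytically.
A single column of height $h$ on flat ground casts, for rays evaluated from
cell centres, a shadow over the cells whose centre lies within
$h/\tan\gamma$ of the column's shaded edge — that is
$\lfloor h/(\tan\gamma\,\Delta) + 0.5\rfloor$ cells of size $\Delta$. This
equals the simpler $\lfloor h/(\tan\gamma\,\Delta)\rfloor$ exactly when the
fractional part of $h/(\tan\gamma\,\Delta)$ is below one half; the
altitudes used in the shadow-geometry checks (15°, 20°, 30°, 40°, 60° with
$h = 20$ m, $\Delta = 10$ m) were chosen up front to satisfy that
condition, so the simple formula is the true geometry in every tested case.

## Problem sizes and numerical choices

The validation studies use 20×20-cell landscapes (ten sun positions per
landscape, twenty landscapes for the oracle comparison), four simulated
days at hourly grain for calibration recovery, and single days for solar
validation — sizes at which every study completes in well under a minute
apiece while exercising thousands of individual walks. Height comparisons
use a $10^{-9}$ m tolerance so exact ties (ray at ground level, ray at an
object top) resolve to "no interception" deterministically. Grid-search
ties resolve to the smallest candidate. The calibration-recovery landscape
(seeded random canopy plus a bare 25 m wall three cells east of an open
probe cell) is fixed, so the experiment is the same under every run; its
known multipliers (0.95, 0.9, 0.3) are recovered to within the 0.005
search resolution plus the first-order peak-matching bias, comfortably
inside ±0.01.

## Known limitations

* Shadows are hard-edged at cell resolution; no soft shadow edges,
  diffuse-sky anisotropy, or inter-cell reflection.
* The voxel model is vertically uniform (at most two stacked layers); no
  within-crown gaps.
* Atmospheric transmission is a single multiplier; no air-mass, Rayleigh
  or aerosol terms, and clouds reduce energy by a flat daily fraction.
* Terrain shade is a calibrated inverse-distance heuristic, not a
  radiative-transfer quantity.
* Temporal grain is bounded below at one minute and the clear-sky seasonal
  cycle uses a fixed 365.25-day period.
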