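---
title: "A positional-information model of moss phyllid morphogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A positional-information model of moss phyllid morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`phyllidsim` simulates the development of a *Physcomitrium patens* phyllid
— the leaf-like lateral organ of the moss gametophore, one cell layer
thick with a central midrib — from a day-1 primordium of a handful of
cells to a mature lanceolate organ at 5.5 days after initiation.  The
model is two-dimensional and cell-based: the organ is a conforming tiling
of polygonal cells, each refined into three-node triangular membrane
finite elements that never cross cell boundaries.

Development is driven by *positional information* rather than lineage:
cells read their distance from the organ base and the gradient of a
distance field computed from the single apical cell, and decide their own
growth rates, division competence and differentiation state from that
position.  The simulation loop interleaves four processes.

**Growth.** Each cell carries specified growth rates `k_par` and `k_per`
(per day) parallel and perpendicular to its polarity vector.  Growth is
applied to the *rest configuration* of the cell's elements: each rest
shape is mapped by
`G = R diag(exp(k_par * dt), exp(k_per * dt)) R'`,
where `R` rotates the polarity onto the first axis.  The exponential form
makes the specified rates independent of the step size `dt`.

**Mechanics.** Elements are linear St. Venant (Kirchhoff) isotropic
membranes under plane stress with unit thickness: with `F` the map from
rest to current shape and `Eg = (F'F - I)/2` its Green strain, the stored
energy density is `W = lambda/2 tr(Eg)^2 + mu tr(Eg^2)` with plane-stress
moduli `lambda = E nu/(1 - nu^2)`, `mu = E/(2(1 + nu))`; defaults
`E = 100` MPa and `nu = 0.3`.  After every growth increment the elastic
energy is minimized over vertex positions (quasi-Newton L-BFGS-B with the
analytic gradient) subject to Dirichlet conditions: the bottom-most
vertices cannot move longitudinally, and one anchor vertex is fully fixed
to remove the remaining rigid modes.  Residual stresses are then
*released* — every rest shape is replaced by the current shape — so each
step starts from a stress-free state.  Stress release is what makes cell
division mechanically free: when a cell divides, its elements are
discarded and the daughters are re-triangulated, and because the tissue is
stress-free this changes no force anywhere.

**Positional control.**  Three developmental phases are clocked in days
after initiation: initiation (to 1.5 d; slow, isotropic growth),
expansion (to 4.0 d; fast anisotropic growth) and maturation (after 4.0 d;
all divisions cease, growth decays).  During expansion, divisions are
confined to a proliferative zone within a cell-count graph distance of the
base; a cell displaced beyond it differentiates irreversibly, recording
its differentiation time.  Blade growth rates are graded from a slow floor
at the first cell rows to their full value deeper into the zone.  A
midrib is specified once, at 2.0 d, as the blade cells within a small
mediolateral offset of the midline and a few rows of the base; midrib
identity is heritable and midrib cells grow with strongly reduced
mediolateral rates, which is what straightens the initially zigzagging
merophyte boundaries.  Differentiating cells elongate transiently
(parallel rate boosted for `tau_e` days) and then both rates decay
exponentially with timescale `tau_d`.

**Division.**  An ordinary cell divides when its area reaches a threshold,
along the shorter of the two chords through its centroid oriented parallel
versus perpendicular to its polarity; ties go to the perpendicular wall.
New wall endpoints are inserted into the neighbouring rings so the tiling
stays conforming, and endpoints landing within 5% of an edge end are
snapped to the existing vertex — the edge-point regularization that keeps
triangle aspect ratios reasonable as walls accumulate junctions.  The
apical cell is the exception: it divides on a fixed schedule along a wall
at 60 degrees to its polarity axis, alternating left and right; the distal
daughter keeps the apical identity, the proximal daughter founds the next
merophyte (clonal sector).

## Polarity: one design choice worth recording

Polarity is the negative normalized gradient of a distance field computed
from the apical cell, estimated per cell by a weighted least-squares plane
fit of the distances of the cell and its wall-sharing neighbours at their
centroids (weights: shared wall length), with the global organ axis as
fallback for degenerate neighbourhoods.  Growing cells re-read this field
every step.  Differentiated cells do not: a cell that leaves the
proliferative zone keeps elongating parallel to the main organ axis from
then on.  Re-reading the apical field during the late elongation phase is
unstable — once the tip is displaced slightly off-axis (which the
alternating oblique apical divisions guarantee), tip-directed elongation
amplifies the displacement and the organ bends.  Freezing the axis of
differentiated cells reflects the observation that differentiated cells
elongate parallel to the main organ axis, and keeps maturation straight.

Two further dialect choices: the "euclidean wall weight" distance flavour
weights each adjacency by the centroid-to-centroid distance of the two
cells, and the gradient estimator above is per cell (rates and directions
are specified at the cellular level and passed to the cell's elements).

## Parameters

Times are days after phyllid initiation; the simulation starts at 1.0 d
(the template stands for a day-1 primordium) and ends at 5.5 d with
`dt = 0.05` d.  The calibrated wild-type defaults
(`scenario_params("wt_upper")`) are, in brief:

* phases: `t_phase12 = 1.5`, `t_phase23 = 4.0` d;
* apical cell: first division 1.05 d, period 0.4 d, wall angle 60°,
  rates (0.55, 0.30) /d — below the division-balance rate, so the apical
  cell and its late derivatives shrink across successive divisions as the
  organ matures;
* proliferative zone: within 5 cells of the base during expansion
  (unbounded during initiation);
* division threshold: 65 µm² against template cells of ~100–200 µm² (the
  template dimensions and the threshold are calibrated jointly — only
  their ratio is meaningful, and it sets the number of division rounds);
* blade rates: isotropic 0.15 /d in phase 1; (0.72, 0.45) /d in phase 2,
  multiplied by a basal ramp rising from 0.06 at rows ≤ 2 to 1 at row 3 —
  this graded slow base is what keeps the first two merophytes small and
  lets the third and fourth dominate the final organ;
* midrib: onset 2.0 d, |x| ≤ 6 µm of the midline within 3 rows of the
  base, mediolateral rate × 0.15;
* differentiation: parallel boost 1.7 for `tau_e = 0.5` d, then decay
  with `tau_d = 0.6` d;
* attachment zone: isotropic 0.02 /d, never divides.

The scenario presets change only the positional-control dials, mirroring
the biological interpretation that auxin accelerates the
division-to-differentiation transition and promotes elongation: the
pin-mutant preset shrinks the proliferative zone, advances maturation and
raises elongation; auxin treatment advances maturation further with a
stronger elongation boost; auxin on the mutant eliminates divisions after
initiation (`d_prolif = 0`) with the strongest anisotropy; the juvenile
basal phyllid differs from the wild type *only* by earlier division
cessation (`t_phase23 = 3.2` d, i.e. 0.8 d earlier), which alone yields
8 instead of 10 merophytes and a smaller organ.

## The synthetic template and fixtures

No segmented microscopy meshes ship with the package.  `make_template()`
builds the day-1 primordium the simulator consumes: an attachment row
whose base vertices carry the Dirichlet conditions, two merophyte rows of
two cell files each, and one apical wedge cell, ~40 µm wide — the
cell-size magnitude of a day-1 primordium.  It is exactly mirror-symmetric
at `jitter = 0` (the shipped default, so scenario runs are fully
deterministic); Gaussian vertex jitter with a seed is available and is
used by the property suites.  What the template does *not* emulate:
curvature of the real meristem surface (the model is flat 2D), unequal
file widths, and natural cell-size noise.  Passing tests on this template
therefore demonstrate the internal consistency of the rules, not fidelity
to any particular imaged primordium.

`make_lineage_fixture()` generates time-lapse-like lineage tables with
known ground truth for the quantification pipeline: a cell grid deformed
by an exactly integrated growth map (optionally a linear basal gradient of
the parallel rate), scheduled divisions, and optional junction-position
noise.  Because the vertical map is integrated in closed form, the stored
per-cell rates are exact, and parameter-recovery tests compare against
them rather than against a re-derivation.

## Numerical choices

* Equilibrium tolerance: largest residual force component on free
  coordinates below `1e-8 × E × mean rest area`; up to six L-BFGS-B
  restarts before erroring.  The solver is deterministic, so reruns are
  bit-identical.
* Inverted elements (`det F ≤ 0`) are guarded by a convex quadratic
  penalty below `det F = 0.05`; at the shipped `dt` the guard never
  engages, and its firing indicates a bug or a pathological parameter set.
* Division chords: if the chosen orientation fails to split the polygon
  into two simple parts (degenerate geometry), the other orientation is
  tried before erroring.  At most one division per cell per step prevents
  within-step cascades.
* Wall-orientation scoring replaces the manual longitudinal/mediolateral
  call with a fixed 45° threshold on the angle to the local longitudinal
  axis; exactly 45° scores mediolateral.
* The printed area-expansion formula is read as relative increase,
  `(sum of daughter areas / parent area − 1) × 100`, consistent with a
  no-growth interval reporting 0%.
* Growth anisotropy is `(l1 − l2)/(l1 + l2)` over the principal stretches
  of the symmetric part of the fitted deformation; bounded in [0, 1).
* Quartiles are type-7; binned profiles report raw per-bin medians and
  interquartile ranges (any spline smoothing is presentation-only and not
  used in any computation).

## Problem sizes

The shipped scenario runs use the 8-cell template, `dt = 0.05` d and
`t_end = 5.5` d (90 steps), producing organs of roughly 50–100 cells and
40–90 division events — an order of magnitude below the cell counts of a
real upper phyllid, chosen so that a full scenario sweep (all five
presets) completes in a few minutes on one core.  The cellular rules are
size-free (rates per day, graded by graph distance), so the dynamics scale
with the template/threshold ratio rather than with absolute cell number;
the quantification pipeline is routinely run on the simulator's own
output, and all sector-level statements (merophyte counts, contribution
fractions, division-orientation ratios) are made at this reduced size.

## Known limitations

* The organ is strictly 2D and flat; no out-of-plane buckling, no
  multilayered midrib mechanics (midrib identity only rescales in-plane
  growth).
* Auxin is not modelled explicitly — scenario presets encode its
  *effects* (earlier differentiation, stronger elongation) as parameter
  deltas, so the model cannot address transport dynamics.
* The apical division schedule is a fixed timetable, not an emergent cell
  cycle; merophyte number is emergent from the schedule and the
  maturation time, which is exactly the coupling the basal-phyllid preset
  exploits.
* Very late tip geometry can be slightly asymmetric (the last oblique
  apical divisions leave the tip off-axis); quantities defined over
  sectors or the whole organ are insensitive to this.
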