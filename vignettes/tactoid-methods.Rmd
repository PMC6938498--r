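---
title: "Hard rods in tactoid-shaped confinement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hard rods in tactoid-shaped confinement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tactoidMC)
```

## The physical problem

Colloidal rods such as filamentous viruses form nematic liquid crystals whose
director field, when the suspension is confined to a container comparable in
size to the particles, is decided by a competition between bulk alignment and
wall anchoring. This package simulates hard spherocylinders confined to
shallow, quasi-two-dimensional spindle-shaped (lens-shaped) chambers that
mimic the shape of tactoids — the pointed nematic droplets of an
isotropic–nematic phase separation — and provides the analysis stack needed
to characterise the resulting textures: local order parameters, topological
defect detection, pattern classification, and classification of the
relaxation pathways from controlled initial states.

All lengths are expressed in units of the rod diameter $d$; there is no
physical time, Monte Carlo sweeps serve as the time proxy.

## Container geometry

The container cross-section is the intersection of two equal disks: vertices
(cusps) at $(0,\pm L_y/2)$, waist half-width $L_x/2$, arc radius
$R=(L_x^2+L_y^2)/(4L_x)$ and arc centres $(\pm c,0)$ with $c=R-L_x/2$. The
cusp opening angle is $\alpha = 4\,\mathrm{arccot}(L_y/L_x)$, so aspect
ratio 1 is a circle ($\alpha=180^\circ$) and $\alpha=30^\circ$ corresponds
to aspect ratio $\cot(7.5^\circ)\approx 7.60$. The cross-section is extruded
to a depth $h$ ($h/d = 6$ by default), giving a slab thin enough that rods
of length $L/d = 20$ stay essentially in-plane, while avoiding the jamming
artefacts of a strictly two-dimensional system.

Because the lens is convex, eroding it by a margin $m$ equals intersecting
the two disks of radius $R-m$ (plus shrinking the slab), and a capsule of
diameter $d$ lies inside the container **iff** both centreline endpoints lie
in the region eroded by $d/2$. The wall test is therefore exact and O(1),
with no special-casing at the (non-smooth) cusps.

## Monte Carlo engine

Particles are hard spherocylinders; the only interactions are steric
(rod–rod) and the hard wall. A trial move combines a uniform displacement in
$[-\delta r,\delta r]^3$ with a rotation by a uniform angle in
$[0,\delta\theta]$ about a uniformly random axis; it is accepted iff the rod
remains inside the wall and overlaps no other rod (centreline distance below
$d$, computed with a robust clamped-quadratic segment–segment distance).
One sweep is $N$ such moves with the particle drawn uniformly at random,
which satisfies detailed balance without a fixed update order.

Choices that the physics does not pin down, made once:

* **Amplitudes.** $\delta r = 0.5\,d$, $\delta\theta = 0.1$ rad. At the
  working volume fraction $\eta=0.16$ this accepts roughly 20–40% of moves,
  a reasonable compromise between step size and acceptance for hard rods of
  this aspect ratio.
* **Rotations are fully 3D.** The quasi-2D slab itself suppresses
  out-of-plane tilt (the planar anchoring of hard rods at the top and bottom
  plates penetrates at least a rod length); no artificial 2D constraint is
  imposed. The out-of-plane director component can be monitored via the
  $z$-component of the director.
* **Acceleration.** A uniform cell grid with edge $\ge L+d$ over the lens
  bounding box; only the 3×3 cell neighbourhood is scanned, with a
  centre-distance prefilter ($|\Delta r| > L+d$ cannot overlap) and an
  axis-aligned bounding-box rejection before the exact segment test. The
  accelerated path is cross-checked in the tests against an all-pairs oracle
  built from the exported primitives.
* **Determinism.** All randomness flows from R's RNG seeded with the run
  seed, so trajectories are bitwise reproducible; the seed is recorded in
  the trajectory header.

## Controlled initial states

Four initial conditions are supported: rods aligned with the major axis,
aligned with the minor axis, tilted by 45° with respect to the minor axis,
and a radial hedgehog (which carries a single $+1$ defect at the centre).
States are built by randomized sequential insertion: uniform centre
proposals, the mode orientation plus a small in-plane jitter ($\le 3^\circ$,
enough to break jamming while leaving the global order above 0.98), $z$
uniform in the allowed slab, rejecting proposals that violate the wall or
overlap a placed rod. Rods that cannot be placed are retried at fresh
positions, never with changed orientations, so the hedgehog's central defect
is preserved by construction. If fewer than 90% of the target rods can be
placed the builder fails loudly, reporting the volume fraction it reached.

## Order parameters

The global tensor order parameter of $N$ rods with orientations
$\hat u_i$ is
$$\mathbf{Q}=\frac{1}{N}\sum_i\left(\tfrac{3}{2}\hat u_i\otimes\hat u_i -
\tfrac12\,\mathbb{1}_3\right),$$
whose top eigenvalue is the scalar order parameter $S$ and whose top
eigenvector is the director (defined up to sign).

The local field divides the bounding box into cuboidal sub-volumes of equal
square footprint and full height $h$ and weights each rod by the length
$l_i^k$ of its centreline inside sub-volume $k$:
$$\mathbf{Q}^k=\frac{1}{\sum_i l_i^k}\sum_i
l_i^k\left(\tfrac{3}{2}\hat u_i\otimes\hat u_i-\tfrac12\,\mathbb{1}_3\right).$$
The clipped lengths come from exact parametric slab clipping and are
additive: summed over the grid they recover $N\,L$ (asserted to $10^{-6}$
relative in the tests). The default cell edge is $L/2$, which resolves
defect cores — these extend over roughly a rod length — with at least two
cells; a cell lying exactly on a rod's path cannot double-count it because
degenerate-axis membership is half-open.

From the per-cell directors $\hat n^k$ an angular deficit is built for every
cell with four occupied neighbours,
$$\delta=\min\angle(\hat n^W,\hat n^E)+\min\angle(\hat n^S,\hat n^N),$$
with the minimum (nematic) angle folded into $[0,\pi/2]$. Opposite-neighbour
pairing makes $\delta$ vanish for uniform *and* smoothly bent fields and
peak at defect cores; $\delta$ is reported in radians and does not resolve
the charge sign.

## Defect detection

Interior disclinations are found by the nematic winding number of every 2×2
plaquette of occupied cells: director-angle increments folded into
$(-\pi/2,\pi/2]$, summed around the loop, divided by $2\pi$. Plaquettes with
$|w|\ge 1/4$ are clustered (8-connected components) into defects whose
charge is the cluster winding rounded to the nearest half-integer. Before
winding analysis the director field is smoothed with a gauge-safe 3×3
tensor average, and cells whose occupancy falls below 15% of the median are
masked — sliver cells crossed by a single rod tip carry meaningless
directors.

Defects whose core sits *on* the wall (boojums), including the cusps where
the core lies outside the occupied grid entirely, cannot be enclosed by any
plaquette. They are recovered by **boundary probes**: for a probe point on
the wall, the occupied cells within 2.5 cells are ordered by azimuth, the
largest angular gap is identified as the exterior, and the director rotation
$\Delta\theta$ is accumulated along the interior arc. For a charge-$q$ core
at the probe, $\Delta\theta$ grows linearly with the swept azimuth at slope
$q$; the slope is estimated by least squares and rounded to the nearest
half-integer. Two gates suppress false positives:

* a **linearity test** (RMS residual of the linear fit below 0.30 rad):
  the apparent rotation induced by a *distant* charge is strongly
  non-linear in the swept azimuth;
* a **co-localised melt test**: the minimum scalar order within two cells
  of the probe must dip at least 0.08 below the median occupied-cell $S$ —
  defect cores melt, and this is the same co-localised $S$ depression used
  to identify defects visually.

Boundary probes are smoothing-free: the 3×3 average would flatten the field
inside the narrow cusp wedge and wash out the very rotation being measured.

At the cusps one more convention is needed. The wall tangent itself turns by
$\pi-\alpha$ across a cusp, so a defect-free wall-aligned field (e.g. the
early minor-axis-aligned state) already carries an apparent *negative*
rotation there — geometric, not topological. Cusp probes therefore only ever
report the $+1/2$ boojum of the bipolar family; apparent negative cusp
charges are discarded. With this convention the detected charges of every
complete pattern sum to $+1$, the Euler characteristic of the
disk-topology container.

Detected defects are assigned a locale — cusp (within
$\max(L/2,\,0.05\,L_y)$ of a vertex), boundary (within $L/2$ of the wall),
or interior — reflecting that defect cores and wall layers extend over
about one rod length.

## Pattern taxonomy and classifier

The pattern classes are: homogeneous H; bipolar B (circle) and
B$_\parallel$ (both $+1/2$ defects in the cusps); diagonal states D$^*$
(one defect off-cusp), D$^{**}$ (both off-cusp) and D$_h$ (defects at
opposite ends of the minor axis); wavy S / S$^{**}$ (an S-shaped director
with cusp / non-cusp defects); and multi-domain M$_n$ with $n$ defect
points (M$_4$: three $+1/2$ on the wall plus one interior $-1/2$; M$_6$:
four $+1/2$ plus two interior $-1/2$). In every class the charges total
$+1$.

The classifier is a decision tree over the defect list and the field, with
tolerances chosen once: homogeneous alignment within 10° mean deviation;
D$_h$ recognition within $0.1\,L_x$ of the minor-axis ends, *or* two
non-cusp wall defects facing each other across the waist band
$|y|\le L_y/4$ — the freshly formed D$_h$ pair has not always settled
exactly onto the ends; the "wavy" criterion samples the signed director
deviation from the major axis along the axis (averaged over the cell
columns straddling it, which cancels the symmetric bipolar bend) and
requires sign-changing excursions beyond 15° on both sides. B is reserved
for aspect ratio exactly 1, following the naming of the circular domain.
Anything that fits no branch is UNKNOWN rather than a forced guess.

## Relaxation pathways

Starting from rods aligned with the minor axis, the system first forms the
D$_h$ pattern quickly and then relaxes to B$_\parallel$ along one of three
routes: **melt** (a central nematic drop bounded by defect lines — a
six-defect M$_6$ intermediate — that eventually dissolves), **slide** (an
M$_4$ intermediate whose defects collectively slide toward a cusp), or
**turn** (no extra defects; the defect-pair axis of a D$^{**}$ sequence
rotates into the cusps). The classifier reads a majority-filtered defect
count trace: sustained counts of six mark melt, four mark slide, and a
trace never exceeding two with a net defect-axis rotation of at least
$\pi/6$ marks turn. The filter window is 3 samples — long enough to remove
single-frame detection noise, short enough not to erase genuinely
short-lived intermediates.

The formation time of D$_h$ is dated from the birth of its defect
signature — the first detected $+1/2$ non-cusp wall defect inside the waist
band — rather than from the first frame whose *label* is D$_h$: the strict
label requires both cores above the detection threshold simultaneously,
which lags the visually obvious pattern by several thousand sweeps.

Equilibration is declared at the first sweep where the global order looks
like the bipolar equilibrium — $S \ge 0.6$ and the director within 5° of
the major axis — sustained for 10 consecutive samples. These defaults make
a homogeneous start in a high-aspect spindle register as equilibrated
almost immediately, while the minor-axis start at the smallest geometry
needs a few hundred thousand sweeps.

## Synthetic director fields

Every pattern class has an analytic fixture: the in-plane nematic angle is
the standard multi-defect solution
$\theta(\mathbf r)=\sum_j q_j\,\mathrm{atan2}(y-y_j,\,x-x_j)+\theta_0$,
with $\theta_0$ fixed so the centre director points along the major axis
(along the defect-connecting axis for D$_h$), plus a sinusoidal wave term
of amplitude 35° for the S-shaped classes — the wave changes no winding
numbers, only the waviness the S-criterion measures. The scalar order is 1
away from the cores and ramps linearly to 0 within one cell of each core.

These fixtures exercise the entire analysis stack (they live on the same
field type as simulation frames), but they idealise real data in three
ways: uniform occupancy, zero out-of-plane tilt, and noise only when
explicitly injected. Passing the fixture suite therefore validates the
*detection and classification logic*, not the statistical robustness on
simulation frames — the latter is probed separately with angular-noise
sweeps (classification of the two-cusp bipolar fixture survives 5° noise in
at least 95 of 100 seeds) and with full Monte Carlo relaxation runs.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately reduced scale,
chosen as the smallest systems that still show the phenomena: containers of
$L_y/L = 4.5$–6 at aspect ratio 1.5 (about 230–410 rods at $\eta=0.16$),
relaxation runs of a few hundred thousand sweeps sampled every 1000, and
10⁵–10⁶-point sampling oracles for the geometric primitives. At these sizes
the minor-axis start relaxes through the melt pathway, consistent with the
expectation that melt dominates in small containers while turn takes over
only in containers several times larger; observing the full
melt/slide/turn crossover requires system sizes and run lengths far beyond
a test suite. Degenerate inputs are handled explicitly: point segments in
the distance primitive, zero-occupancy cells (masked), fields with fewer
than 3×3 occupied cells (refused), and infinite sentinels for runs that
never equilibrate within their sweep budget (recorded as pathway "other",
never dropped).

## Known limitations

* Defect *lines* in 3D are not tracked; all analysis is of the 2D
  footprint, which is adequate for slabs a few diameters deep.
* The boundary-probe charge estimator quantises to $\{\pm 1/2,\pm 1\}$ and
  relies on a scalar-order depression; a boojum whose core sits more than
  about two cells outside the occupied grid would be missed.
* No Frank-elasticity continuum fitting is attempted; the package stays at
  the particle and director-field level.
* Electrostatics is absorbed into the effective hard diameter, as is
  conventional for charged colloidal rods.
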