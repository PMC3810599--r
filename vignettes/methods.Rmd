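---
title: "Methods: a vertex-centred finite-volume membrane-potential solver with stochastic channel kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a vertex-centred finite-volume membrane-potential solver}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tetvolt)
```

This vignette is the package's own account of its model, its numerical
choices, and what its validation does and does not demonstrate.

## The physical model and its assumptions

Below MHz frequencies the coupling of electric and magnetic fields is
negligible, so the field problem reduces to a potential problem.  Inside
the cell the cytoplasm has a relatively high conductivity $\sigma$
(order 1 S/m) that prevents static charge accumulation, so the
potential obeys the Laplace equation $\nabla^2 \Phi = 0$.  The membrane
is treated as a thin-plate capacitor with specific capacitance
$C_{spec} \approx 1\,\mu F/cm^2$: on a membrane patch of area $A$,
$C_{spec} A\, \partial\Phi/\partial t + I = 0$ with $I$ the
transmembrane current.  The bath is earthed ($\Phi = 0$ outside), so
potentials are absolute; only one membrane surface is supported, and no
extracellular field is computed.  These are the standard assumptions of
a single-membrane quasi-static model; systems where extracellular
gradients or internal charge-separating membranes matter fall outside
them.

## Discretisation: median-dual control volumes

The potential is stored at mesh vertices and interpolated linearly in
each tetrahedron.  Each vertex owns the median-dual control volume
formed by cutting each adjacent tetrahedron through edge midpoints, face
centroids and the tet centroid; the piece of dual surface separating
vertex $p$ from the rest of a tet with edge vectors $a, b, c$ has
area-weighted normal $x = (a\times b + b\times c + c\times a)/3$.  With
a per-tet constant gradient $g = A^{-1}(\Phi_a - \Phi_p, \ldots)$ the
flux $\sigma\, g \cdot x / 2$ gathers into one conductance $G_{pq}$ per
mesh edge.  On linear interpolants this construction is algebraically
identical to the P1 Galerkin stiffness matrix; the test suite asserts
agreement with an independently assembled Galerkin matrix to 1e-9
relative.  Two consequences are inherited from P1: the scheme is
consistent on any valid mesh, and meshes with obtuse tetrahedra can
produce negative edge conductances.  Negative $G_{pq}$ are reported
(`coupling_assembly$n_negative`) but never altered, and the discrete
maximum principle is only guaranteed on Delaunay-quality meshes.

Membrane capacitance is lumped per vertex: each membrane triangle
contributes $C_{spec}\,A_{tri}/3$ to each corner (the median subdivision
splits a triangle into equal-area thirds), and $C_p = 0$ off the
membrane.  Triangle currents are likewise split in equal thirds.

## Time stepping and the banded solve

Backward Euler on $C\,dV/dt = \sum_q G_{pq}(V_q - V_p) + I$ gives

$$(C_p + \delta t \textstyle\sum_q G_{pq})\,V_p^{t+1}
  - \delta t \textstyle\sum_q G_{pq} V_q^{t+1} = C_p V_p^t + I_p \delta t.$$

The matrix is symmetric positive definite whenever the mesh is connected
and at least one vertex carries capacitance ($x^T M x = x^T C x +
\delta t\, x^T L x$ vanishes only for a constant vector that is zero on
the membrane).  It is therefore factorised once per $(G, \delta t)$ pair
with a banded Cholesky (LAPACK `dpbtrf`) and each step costs one banded
back-substitution.  Because the band must hold every edge, vertices are
renumbered first:

* **principal-axis ordering** sorts vertices by projection on the
  largest-variance eigenvector of the coordinate covariance, with
  stable tie-breaks by the remaining axes and then the original index.
  On an axisymmetric rod the minor axes are degenerate, so tie
  resolution — and hence the bandwidth, by $\pm$1–2 — can differ between
  rotated copies of the same rod; the achieved ordering is still
  monotone along the axis.
* **breadth-first ordering** numbers vertices in BFS visit order,
  optionally with the Cuthill-McKee refinement (neighbours enqueued by
  ascending degree; a reverse variant is available but off by default,
  as plain Cuthill-McKee is the named method).  The start-vertex scan
  ranks candidate starts by achieved bandwidth; `start_fraction < 1`
  samples starts uniformly under a fixed seed, which is the only
  stochastic element of the ordering layer.

Orderings never change the solution (asserted to 1e-10): they only
change the cost.  An ordering can be saved to a plain-text file carrying
the vertex count and an adjacency checksum, so mismatched meshes are
rejected on load.  When clamps are present, or the bandwidth under the
supplied ordering would exceed the storage cap, the solver falls back to
a general sparse Cholesky with the clamped rows eliminated
symmetrically.

Clamped vertices are held exactly; injected current is divided over a
vertex set either equally or by area weight.  If `efield_step()` is
asked for a different `elapsed` than the factorised `dt`, it
re-factorises — this supports the hybrid engine's adaptive
communication step, which prefers hitting the requested step exactly
when the SSA clock allows precisely to avoid that cost.

## Channels, GHK currents, and the hybrid loop

Channels are Markov schemes over named states; rates are constants or
voltage-dependent tables (default grid $-150$ to $+100$ mV at 0.01 mV —
fine enough that linear interpolation of the Hodgkin-Huxley rate
functions stays below 1e-6 of their range; clamping at the grid ends is
chosen over extrapolation, with a one-time warning).  Conducting states
carry Ohmic specs ($n\,g\,(V-E)$, no ion transport) or GHK specs.  The
GHK single-channel current uses the constant-field equation with the
convention $V_m$ = inside minus outside, positive current = outward
cation flux; for $|z V F / RT| < 10^{-4}$ a second-order series removes
the $0/0$ while keeping relative error below 1e-9.  With equal
concentrations on both sides the equation collapses exactly to an Ohmic
current of conductance $P z^2 F^2 S / RT$, which the tests assert to
1e-10 — the sense in which an Ohmic current is the good-approximation
limit of GHK.

In stochastic mode, gating transitions and GHK single-ion passages are
SSA events (Gillespie direct method, one RNG stream per simulation so
the method stays exact).  A GHK event moves one ion between the inner
tetrahedron's discrete pool and the bath (an infinite reservoir with a
book-keeping ledger; a well-mixed option pools all tetrahedra) and adds
$z e$ (signed) to its triangle's accumulated charge.  Concentrations are
sampled per adjacent tetrahedron; no volumetric diffusion between
tetrahedra is simulated.  Propensities are refreshed lazily: a gating
event touches one triangle, an ion event touches the triangles adjacent
to the changed tetrahedron, and a field update touches everything.

Communication: events are executed while they fall before the sync
target (last update + `efield_dt`); the field update happens at the last
executed event's time — usually slightly early, never late — or exactly
at the target if the window had no events.  At a sync, each triangle's
current is its accumulated charge divided by the elapsed interval plus
its Ohmic and leak currents sampled at the current potential (sampled,
not integrated: the charge accumulator is the integral part of the
scheme, and windows are short against membrane time constants), the
solver advances by exactly the elapsed interval, triangle potentials and
all voltage-dependent propensities refresh, and the accumulators reset.

Deterministic mode integrates the per-triangle master equations with an
embedded Cash–Karp Runge–Kutta (relative tolerance 1e-8) inside each
window, rates held at the window-start potential — first-order operator
splitting in `efield_dt`, which is what the Rallpack 3 step-halving test
measures.  Deterministic GHK transport updates concentrations once per
window from the expected flux; windows (microseconds) are far below
concentration time constants, so this is not a practical accuracy limit.

## Fixture meshes

The cylinder builder stacks polygon-disc slabs along the axis and
tetrahedralises each slab by coning all its faces (two disc
triangulations and a wall strip) to an interior point.  Sharing the disc
triangulations between neighbouring slabs makes every internal interface
conforming with no diagonal bookkeeping — this is why coning was chosen
over the more common prism-into-3-tets split, and the same primitive
tetrahedralises the branched tree's junction plugs, where a prism split
does not apply.  The polygon order $m$ grows as
$\sqrt{N_{target}\,\pi d / (4L)}$ so chord length and slab thickness
stay comparable.  The cross-section is scaled so polygon area equals
$\pi r^2$ exactly, making total volume exact to machine precision; the
price is a perimeter (hence side-area) overshoot of order 1% that
shrinks with $m$ and is reported so membrane parameters can be
corrected.

The branched builder grows a symmetric binary tree: daughters carry
$d\,2^{-2/3}$ (the 3/2 power law, $\sum d^{3/2}$ conserved) and length
$l\,2^{-1/3}$, which keeps every level's electrotonic length equal and
makes an 8-level tree from a 32 um x 16 um root span about 130 um.
Daughter pairs diverge by a fixed half-angle (default 0.5 rad) in planes
rotating 90 degrees per level; branch-pair distances are checked against
summed radii and intersections are an error.  Each parent ends in a
split disc whose halves feed conforming plugs into the daughter base
discs; a global radial scale is solved (Brent) so total volume matches
the union of ideal cylinders exactly.  The slab distribution along
branches is uniform per branch — nothing in the benchmark constrains how
tetrahedron sizes vary axially, and uniform slicing is the simplest
reproducible choice.

## The Rallpack runners and what they show

Passive parameters are the published benchmark values: axial resistivity
1.0 Ohm m, membrane resistance 4.0 Ohm m^2, $C_{spec}$ 0.01 F/m^2, rest
$-65$ mV, 0.1 nA step at one end, 0.01 ms field steps, 250 ms.  The
benchmark cable is sealed: its 1D definition has no end membrane, so the
runners place the membrane on the side wall only and leave the end caps
as passive conductor cross-sections; injection and probing use
area-weighted end-cap vertices, and the surface correction then targets
$\pi d L$ exactly.  (The fixtures' general-purpose membrane remains the
full closed boundary.)  Hodgkin-Huxley runs add the squid Na/K schemes
(1200 and 360 S/m^2 peak, $+50$/$-77$ mV reversals) with channel counts
surface-corrected the same way.

References are analytic: the sealed-end finite-cable cosine series
(truncated when the amplitude-decay tail is below 1e-9 V; cross-checked
against a brute-force 1D finite-difference oracle), and for the tree the
equivalent-cylinder mapping — exact for this symmetric power-law
geometry — cross-checked at steady state against recursive impedance
composition and an independently assembled 1D branched resistor network.
End potentials are area-weighted means over end-cap vertices, the lumped
quantity a 1D cable predicts.

Two honest caveats about what passing shows.  First, because the
generated meshes match volume exactly and the membrane is
surface-corrected, the dominant mesh-induced error of unstructured
meshes is removed *a priori*: the refinement ladder (40k to 200k
tetrahedra) sits at the backward-Euler temporal floor (~0.005 mV RMS)
essentially flat, so "accuracy does not degrade with refinement" is
asserted at 1e-4 mV resolution rather than as a visible decline, and
halving the timestep roughly halves the RMS rather than leaving it
unchanged.  Second, the Hodgkin-Huxley benchmark has no analytic
solution; absent an external reference trace the suite asserts internal
step-halving convergence (< 1 mV RMS between 5 us and 1 us steps) and
stochastic/deterministic agreement.  The stochastic check uses a
*subthreshold* stimulus deliberately: near threshold, channel noise
systematically advances spikes, so agreement-in-mean at fixed time is a
large-count limit statement that a desk-scale test cannot honestly
resolve on a spiking trace.  `run_rallpack3(reference = <csv>)` computes
RMS and spike-timing metrics against an externally produced trace when
one is supplied.

Problem sizes used by the shipped validation: the full-scale benchmarks
run ~200,000 (cylinder) and ~60,000 (tree) tetrahedra for the full
250 ms; unit tests use desk-scale meshes (hundreds to thousands of
tetrahedra) and a single-tetrahedron membrane patch with up to a few
thousand channels for the stochastic checks, chosen so the whole suite
completes in minutes on one CPU.

## What the synthetic fixtures do not emulate

Generated meshes are structured and high-quality; real reconstructed
morphologies bring irregular element quality (more obtuse tets, hence
more negative couplings), surface errors that do not shrink under the
generator's control, and geometric features (spines, varicosities) whose
discretisation error the Rallpack suite does not probe.  The ion-pool
model has no volumetric diffusion, so concentration gradients within a
compartment are not represented between field updates.  Passing the
suite validates the discretisation, the solver, the kinetics and their
coupling — not the fidelity of any particular reconstructed mesh.
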