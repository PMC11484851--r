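---
title: "Profiling GPCR activation geometry, G-protein interfaces and hydration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling GPCR activation geometry, G-protein interfaces and hydration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrprofiler)
```

## The problem this package addresses

Class-A GPCR activation is read off a structure through a small vocabulary
of geometric observables. On the receptor side: the D3.49–R3.50 salt bridge
of the DRY motif (closed in inactive states, broken on activation), the
hydrogen bond from Y5.58 that holds the rotated R3.50, the outward swing of
the cytoplasmic end of TM6 that opens the G-protein crevice, and the
behaviour of the TM7 NPxxY motif. Receptors that carry a leucine at 7.53
(NPxxL — the endothelin ET-B receptor is the canonical case) cannot form
the usual Y7.53-centred water-mediated network; instead TM7 shifts toward
the intracellular side and the 3.46–7.53 pair, normally in van der Waals
contact (≤ 4.5 Å), separates to ~7 Å, leaving a cavity that simulations
show to be hydrated above bulk density. On the G-protein side, the α5 helix
of Gα inserts into the crevice and the interface is summarized as a table
of residue–residue contacts under generic numbering.

This package computes those observables — on static models, on
trajectories, and on the functional-assay data used to corroborate them —
and ships generators that plant each observable's value exactly, so the
whole chain is testable against known ground truth.

## Generic numbering

Ballesteros–Weinstein (BW) labels are computed from per-segment anchors:
the residue at each helix's most conserved position is declared `x.50` and
every other residue in the declared segment range is labelled by plain
sequence offset. Two consequences are deliberate:

* **No bulge/deletion handling.** Labels like `7.451` are not produced. If
  a helix has an insertion the user must split the segment. This mirrors
  how the source analyses number residues and keeps the map a pure offset
  table.
* **Loop tags are annotations, not labels.** Papers tag several residues
  `ICL2`; a bijective map cannot hold duplicate labels. BW and CGN entries
  are strictly bijective (duplicates are an error); loop tags (scheme
  `"loop"`) may be shared, appear in reports, and refuse *reverse* lookup
  with an ambiguity error.

CGN numbering for Gα is not offset-computable, so it is table-driven. The
packaged table covers the Gα-i1 α5 helix T340 (H5.12) through F354 (H5.26)
plus E318 (h4s6.12). Published accounts are inconsistent about whether
H5.24 is G352 or G353; the wavy hook is 352-GLF-354, so this table fixes
H5.24 = G352 and H5.25 = L353, and the discrepancy is surfaced here rather
than silently absorbed.

## Geometry: conventions and numerical choices

* **Superposition** is the standard least-squares rigid fit via SVD of the
  3×3 covariance matrix, with the reflection excluded by flipping the
  smallest singular direction when the determinant is negative. Collinear
  or coincident point sets are rejected (second singular value below
  1e-10 of the first). The test suite checks the RMSD against an
  independent quaternion (Kearsley key-matrix) oracle at 1e-9.
* **Atom pairing** for two-structure RMSD is by (chain, residue number,
  insertion code, atom name); unpaired atoms are dropped, and fewer than 3
  surviving fit pairs is an error.
* **Inter-residue distances** are minimum heavy-atom distances over all
  atom pairs — the convention the field uses for reported inter-motif
  distances — with an `atoms = "all"` option when hydrogens matter.
* **Helix axes** are principal components of the Cα trace after a
  4-residue moving average. The smoothing matters: the raw first principal
  component of a helical spiral is biased by the phase ramp of the winding
  (for a 15–20-residue helix the bias is ~2°); averaging over one turn
  cancels it, bringing ideal-helix recovery below 0.3° and σ = 0.2 Å noisy
  recovery inside 2°. Multi-helix *bundles* use `principal_axis()`, the
  unsmoothed variant, since averaging across helix boundaries would mix
  helices.
* **Axis orientation.** "Downward" in activation parlance means toward the
  cytoplasm, but structures carry no intrinsic up. The bundle axis is
  oriented extracellular→intracellular using the mean position of
  ICL-tagged residues (or an explicit `ic_point`), and the TM7 displacement
  is reported intracellular-positive. Every hallmark report records this
  convention in its notes.

## Hallmark metrics

Defaults, all overridable: salt bridge = charged-group N/O distance
≤ 4.0 Å; hydrogen bond = donor–acceptor N/O distance ≤ 3.5 Å (side-chain
atoms only for the intra-receptor pairs, since the polar contacts of
interest are side-chain-mediated); 3.46–7.53 contact = minimum heavy-atom
distance ≤ 4.5 Å. Static models usually lack hydrogens, so no angle term
is applied to static structures — a deliberate divergence from the
trajectory criterion below, stated here because the two numbers are not
strictly comparable.

TM6 outward movement superposes the inactive reference onto the active
structure over a core Cα set (default: all shared TM1–TM4 positions, the
part of the bundle that moves least) and reports the in-membrane-plane
component of the 6.30 Cα displacement. TM7 displacement is the mean signed
axial displacement of the 7.49–7.53 Cα positions. Published analyses
rarely state which atoms their reported TM6/TM7 displacement figures were
measured on; these probe choices are documented defaults, and both metrics recover
purely translational plants exactly (the synthetic pair keeps TM1–TM4
identical, so the core fit is the identity).

## Interface contacts

A residue pair with any heavy-atom pair within 4.5 Å is a contact; it is
classified `hbond` if its minimum donor–acceptor N/O distance (backbone
included, per a standard residue template table; His, Ser, Thr, Tyr both
donor and acceptor) is within 3.5 Å, else `vdw`. One record per residue
pair, never both types; the minimal-distance atom pair is retained as
evidence and ionic pairs within 4.0 Å are flagged `salt_bridge` in a notes
column. The cutoffs are decisions validated against planted synthetic
interfaces and a brute-force all-pairs oracle, not against any particular
deposited model's supplementary table.

## Trajectory statistics

The hydrogen-bond criterion for trajectories is pinned to the documented
defaults of the standard MD tools: donor–acceptor distance ≤ 3.5 Å (0.35
nm) and hydrogen–donor–acceptor angle ≤ 30°, the angle term applying only
when the topology carries hydrogens (a hydrogen within 1.25 Å of the donor
is taken as bonded). Without hydrogens the distance term alone decides,
and the result carries an `angle_term` attribute saying which rule ran.
Occupancy is the fraction of frames in which *any* qualifying
donor–acceptor combination of the residue pair satisfies the criterion
(the per-pair "any triple" reading; a specific named atom pair can be
obtained by restricting the residues' atoms).

The water-occupancy density at grid point *i* is

$$\rho_i = \frac{1}{T\,V_r}\sum_{t=1}^{T}\sum_{j=1}^{N}
H\!\left(r - \lVert x_{j,t} - c_i\rVert\right),$$

with *T* frames, water-oxygen positions $x_{j,t}$, $V_r = \tfrac{4}{3}\pi
r^3$, defaults r = 1 Å and grid spacing 0.4 Å, and frames superposed onto
frame 1 over a fit selection (all receptor Cα by default) before counting.
Two conventions are worth stating. First, $H(0) = 1$: a water exactly at
distance *r* counts (the boundary has measure zero for real data). Second,
one water contributes to *every* grid point within *r* — the estimator is
a local density, not a partition, so the grid does not sum to *N*. The
estimator is exact (the tests require bit-equality with a literal
double-sum oracle) and unbiased for uniform hydration (checked at 0.0334
waters Å⁻³, the literature bulk density, within 5% Monte-Carlo error at
T = 50). Trajectories are assumed pre-imaged/whole; no periodic imaging is
applied. Bulk density for the k-fold enrichment report (default k = 2)
defaults to 0.0334 Å⁻³ and can be replaced by a user-estimated shell mean;
high-density regions are 26-connected components above k× bulk, sorted by
peak ratio. Note that a cluster's *peak* ratio is a maximum statistic and
sits above the planted enrichment under sampling noise; the acceptance
script therefore also reports the mean enrichment over the eroded hotspot
interior, which is the unbiased estimate of the planted multiplier.

## Assay models

Concentration–response data are fitted to the 3-parameter logistic (Hill
slope fixed at 1 — that fixation is what makes the model 3-parametric;
pEC₅₀, top, bottom free; span = top − bottom reported as the Emax
measure). Vehicle (zero-dose) wells cannot enter a log-concentration fit
directly; they are kept as bottom-informative points at a
pseudo-concentration three log units below the lowest nonzero dose. The
optimizer is bounded Levenberg–Marquardt with a 5-point multi-start over
the concentration span; non-convergence is a flagged result, not an
exception, and a flat response returns a degenerate flag with span 0.
Saturation binding uses total = Bmax·L/(Kd + L) + ns·L fitted jointly
(default) or, when a separate nonspecific series is supplied, by pointwise
subtraction and a 2-parameter specific fit. Concentrations are rescaled by
their maximum inside the optimizer: on a picomolar design the raw
parameterization spans ~25 orders of magnitude across parameters and
defeats the step-size heuristics. Exact zero-dose handling and weighting
in the commercial software that papers cite is unpublished; the choices
above are this package's own and are stated so results can be compared
knowingly.

## What the synthetic generators emulate — and what they do not

The generators plant *observables*, not physics. Bundles are seven
idealized vertical helices with Cα traces exactly on their axis lines and
all segments sharing one z-range, so the bundle principal axis is the z
axis by construction and planted displacements are recovered to 1e-6 Å
rather than within an estimation tolerance. Side chains are straight
schematic extensions carrying correct atom names (so donor/acceptor
tables apply) whose tips are translated until the planted pair distance is
exact; the inactive partner of a bundle pair is derived by pure lateral
(TM6) and axial (TM7) translations with re-planted inactive-state polar
contacts. The interface generator places one receptor residue per planted
contact on its partner's side-chain azimuth and verifies that no
unplanned residue pair comes within the van der Waals cutoff, erroring on
contradictory plants. Hydration frames are i.i.d. uniform (plus a uniform
hotspot sphere); there is no excluded volume, no water–water structure,
and no autocorrelation between frames.

Passing tests therefore demonstrate that the *measurement layer* is exact
and correctly conventioned. They do not demonstrate robustness to
real-structure pathologies — missing side-chain atoms, alternate
conformations beyond simple occupancy ties, helix bulges, or the
frame-to-frame correlation of real MD — and the occupancy and density
error bars appropriate to correlated trajectories are explicitly out of
scope.

## Problem sizes

The shipped tests and the acceptance script run synthetic problems sized
for exactness checks rather than realism: bundles of ~150 residues,
interfaces of ~40 residues, hydration boxes of 16–20 Å with 50–100 frames
(~270 waters per frame), 100-simulation recovery studies for each assay
model. These sizes were chosen so the whole validation chain reruns in
well under a minute per stage; all scale linearly if enlarged.

## Known limitations

* BW bulges/deletions unhandled (documented above).
* Static hydrogen-bond calls are distance-only; protonation states are
  not modelled (His is treated as both donor and acceptor).
* Binary trajectory formats are not parsed natively; convert to
  multi-model PDB, or adapt via `new_trajectory()` with coordinates from
  any reader.
* The water-density superposition fits all receptor Cα by default; if a
  sub-selection was used in a published map, pass it as `fit_idx`.
* `high_density_regions()` reports geometric clusters only; no volume or
  free-energy interpretation is attached.
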