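---
title: "Modelling DBS electric fields and axonal activation with dbsfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling DBS electric fields and axonal activation with dbsfield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep brain stimulation (DBS) delivers charge through small contacts on an
implanted lead. Whether a stimulator is programmed in voltage or current
mode, the clinically relevant quantity is the spatial distribution of the
electric field (EF) in the surrounding tissue, because the EF — not the
contact potential — determines which axons fire. `dbsfield` models this
chain end to end for four lead designs: the cylindrical-contact leads
Medtronic 3389 and St. Jude 6148, the split-ring steering lead St. Jude
6180, and the 40-contact SureStim1 research array. The package solves the
quasi-static volume-conductor problem around a parametric lead embedded in
a voxel-based conductivity map, couples the solution to a myelinated-axon
cable model, and computes the comparison metrics used to contrast lead
designs: the volume inside a fixed EF isolevel, the maximal isocontour
extension per plane, and azimuthal steering asymmetry.

## Volume-conductor model

Brain tissue is treated as a purely resistive medium, so a single stimulus
amplitude determines a steady-current problem

$$\nabla \cdot \mathbf{J} = -\nabla \cdot (\sigma \nabla V) = 0,$$

with the active contact(s) held at the drive potential (voltage mode) or
scaled to deliver a target total current (current mode), the outer cuboid
boundary grounded ($V = 0$), inactive contacts floating (equipotential with
zero net current), and the lead shaft insulating. The quasi-static
approximation neglects capacitive, inductive and propagation effects; the
frequency content of the stimulus pulse is absorbed into the tissue
conductivity values instead.

Tissue conductivities (S/m) follow the tabulated pulse-weighted values:
grey matter 0.123, white matter 0.075, blood 0.7, cerebrospinal fluid 2.0.
A patient-specific-style model assigns each voxel a conductivity by
piecewise-linear interpolation between per-class reference intensities of a
T2-weighted image (partial-volume voxels land between class values, and
out-of-range intensities clamp to the nearest class — extrapolating would
produce unphysical conductivities). The chronic tissue reaction is modelled
as a 0.25 mm peri-electrode space (PES) around the whole lead at the
white-matter conductivity.

A modelling point that is easy to miss: the *homogeneous* grey-matter
reference model carries **no** PES. That model defines the amplitude
equivalence used everywhere (3 V delivers 3.4 mA, and both drives must
produce the *same* field, i.e. a 0% volume difference); with a PES the 3 V
drive would deliver only ≈2.7 mA and the equivalence would break. We
verified this with an independent high-resolution axisymmetric solve of the
same geometry. `solve_field(pes = "auto")` therefore applies the PES to
heterogeneous volumes only; `"on"`/`"off"` override the convention.

### Discretisation

The solver uses cell-centred finite volumes on a graded tensor-product
(rectilinear) grid: uniform fine cells (default 0.1 mm) in a box around the
active contacts, widths growing geometrically (ratio 1.3, capped at 3 mm)
out to the ~100 mm grounded boundary. Face conductances use harmonic
averaging of the two adjacent cell conductivities, which is exact for
layered media and makes the scheme conservative by construction. A
two-level fine/coarse composite grid would serve the same purpose but needs
a conservative inter-grid coupling; the graded single grid achieves the
refinement with none of that machinery. Floating contacts are represented
as high-conductivity domains ($\sigma_{metal} = 10^3$ S/m), which enforces
the equipotential/zero-net-current condition to far below solver tolerance
without constraint equations (results are identical to 4 significant digits
for $\sigma_{metal}$ between $10^3$ and $10^6$). The insulating shaft is
excluded from the solve (zero-flux faces). The linear system is solved with
conjugate gradients preconditioned by modified zero-fill incomplete
Cholesky (dropped fill lumped onto the diagonal) to a relative residual
of $10^{-8}$.

The delivered current is the discrete flux sum over all faces between the
active-contact cells and the tissue, which is exact for the scheme. Current
mode exploits linearity: the unit-voltage problem is solved once and scaled
so the delivered current matches the request; `at_amplitude()` exposes the
same rescaling for amplitude sweeps, so a lead/tissue geometry costs one
linear solve regardless of how many amplitudes or modes are analysed.

Verification: against the closed-form concentric-sphere electrode solution
$V(r) = V_0 a (1/r - 1/R)/(1 - a/R)$, the solver reproduces potential,
total current, isolevel volume and extension within 3% at the default
resolution; the discrete flux through any source-free box vanishes to
$<10^{-3}$ of the delivered current; voltage-mode solutions respect the
maximum principle; and the 0.2 V/mm isolevel volume changes by <2% when the
fine spacing halves from 0.2 to 0.1 mm.

## Lead geometry

Leads are parametric: body cylinder with a hemispherical tip cap, ring
contacts as full-circumference bands (the 6148's 3 mm distal contact covers
the cap), split-ring segments as 108.3° arcs (so that each segment has the
published 1.8 mm² area), and SureStim1 contacts as 0.66 × 0.74 mm ellipses
on the cylinder surface. Geometric areas reproduce the published values
(6, 6.6, 1.8 per segment, 0.39 mm²) within 3%. The SureStim1 row layout is
not fully published; we place 10 rows at 0.75 mm axial pitch starting
0.5 mm above the tip, 4 contacts per row at 90° spacing with alternate rows
rotated 45°, which yields an 8-contact two-row set spanning ≈1.5 mm like
one 3389 ring. All of this lives in an editable YAML catalogue
(`inst/extdata/leads.yaml`).

Contacts are indexed from the tip (index 0) with vendor labels carried
alongside (C0–C3 Medtronic; C1–C8 St. Jude), so the "third contact" is
index 2 = C2 on 3389 and index 2 = C3 on 6148, and the third ring of 6180
is indices 4–6 = C5–C7. The steering configurations are a single split
segment (6180 C5) and a four-contact diamond on SureStim1 (two adjacent
ring-6 contacts flanking one azimuth plus one contact each from rings 5 and
7). By default both steering sets face the same azimuth for a fair
comparison; `build_lead(rotation_deg = )` reorients a lead to reproduce
asymmetric published setups.

Voxelization happens in the lead frame (axis = +z), which makes the
occupancy exactly independent of the world-frame lead orientation;
heterogeneous conductivities are sampled through the frame transform. The
voxelized contact surface area is measured with face normals weighted by
the analytic surface normal — a plain face count converges to the Manhattan
area, about 27% high for a cylinder — and agrees with the analytic area
within 5% at 0.1 mm.

## Axon model and the 0.2 V/mm isolevel

The EF isolevel used for all comparisons is justified by a myelinated-axon
cable model. Nodes of Ranvier carry fast Na⁺, persistent Na⁺, slow K⁺ and
leak channels with mammalian 36–37 °C kinetics; internodes are passive
with myelin-dominated membrane parameters (per-lamella capacitance
0.1 µF/cm² and conductance 0.001 S/cm², divided by twice the lamella
count). Geometry scales with fibre diameter $D$ following the published
morphometry of mammalian motor fibres (internode 500/750/1000 µm at
$D$ = 5.7/7.3/8.7 µm, node length 1 µm, node diameter ≈ $D/3$, axon core
≈ 0.6 $D$).

That table stops at 5.7 µm while the sweep covers 1.5–7.5 µm, so the
small-fibre internodal length must be extrapolated — and it is the one
parameter the activation distance is most sensitive to (the activating
function grows quadratically with internodal length). We extrapolate
linearly below 5.7 µm and calibrate the slope (192 µm per µm of diameter,
floored at 40 $D$) so that the 4 µm fibre reproduces the reference
excitability of this model family at a 60 µs pulse: a threshold EF of about
0.2 V/mm. This is the single calibrated quantity in the package; with it
fixed, the 3 V activation distance (≈3.2 mm) and the amplitude-sweep-median
calibrated isolevel (≈0.2 V/mm) both follow as predictions.

Stimulation applies the extracellular potential sampled along 62 lines
parallel to the lead axis, spaced 0.1 mm radially, the first at the lead
surface, in one of the four directions (anterior/posterior/medial/lateral)
of the axial plane through the active-contact centre. The pulse is a single
rectangular cathodic 60 µs pulse (amplitudes rescale the line potentials by
linearity). A line counts as activated when the membrane potential crosses
0 mV at a node at least 5 nodes away from the peak-drive node within 3 ms —
a propagating action potential, not a local stimulus artefact. The
activation distance of a sweep entry is the radius (from the lead axis) of
the farthest activated line. We report distances from the axis rather than
from the lead surface because only that convention makes the activation
distance, the isocontour extension and the isolevel mutually consistent;
subtract the lead radius (0.635 mm) to convert.

Numerics: 21 nodes with 3 passive segments per internode
(doubling the segmentation leaves the activation distance unchanged); backward-Euler
time stepping at 1 µs with exponential-integrator gate updates (halving the
step changes the activation distance by less than one line spacing); the
membrane is settled for 2 ms before the pulse, and the settled state is
computed once per fibre and reused across lines and amplitudes. The search
over lines exploits monotonicity of activation in drive, amplitude and
diameter, so a full 832-curve sweep costs tens of thousands rather than
half a million membrane simulations.

## Metrics

The isolevel volume integrates all cells with $|E| \ge$ 0.2 V/mm outside
the lead body, with a sub-voxel fraction for cells cut by the isosurface
(first-order, from the local EF gradient). Isocontours are traced at
sub-voxel precision on lead-local planes through the active-contact centre:
axial (perpendicular to the axis), sagittal (containing the axis and the
anterior direction) and coronal (axis and lateral); anatomical planes
require a world affine, which a patient-independent model does not have.
The maximal extension is the largest distance from the contact centre to
the isocontour, ignoring contour vertices within 0.25 mm of the lead
surface: the conductivity contrast and metal edges concentrate the field in
that sheath, producing slivers along the shaft whose extent grows with
resolution, while the outer contour lobe is stable under refinement.
Steering is quantified by the ratio of the maximal to minimal azimuthal
extension in the axial plane; a ratio above 1.2 is reported as a visible
steering effect.

## Synthetic heterogeneous volumes

No patient imaging ships with the package, so heterogeneous models come
from a seeded generator that emulates the *statistical* structure of an
intensity-classified tissue map: a grey-matter cuboid (default 100 mm at
0.5 mm voxels) with white-matter tracts as capsules (one always brushing
the centre region, because the deep targets of interest lie among fibre
tracts), a curved CSF slab kept 12 mm from the centre, thin blood vessels,
and a 0.25 mm Gaussian blur of the class fractions that produces
partial-volume voxels before mapping to conductivity. Two virtual targets
4 mm apart along the trajectory stand in for the two stimulation targets.
The generator makes no anatomical claims: passing tests on synthetic
volumes demonstrates that the pipeline responds correctly to tissue
heterogeneity (lower near-contact conductivity raises impedance, current
mode outgrows voltage mode, directions decouple), not that any specific
patient's numbers are reproduced. Real patient values depend on the actual
anatomy and are reproduced in structure only.

## Campaigns and problem sizes

`campaign_spec("ef")` enumerates the 38-run field campaign in five stages
(6 single-lead tissue comparisons, 16 four-lead/two-target/two-mode runs, 4
patient-amplitude runs at 1.6 V and its equivalent current, 8 steering
runs, 4 reduced-amplitude steering runs); `campaign_spec("neuron")` the
832-curve activation sweep (4 leads × 2 tissue models × 2 modes × 4
directions × 13 diameters). One linear solve is shared wherever geometry
permits, so the 38 runs cost 13 solves.

Problem sizes in the shipped tests and acceptance script are chosen to keep
a full run on one CPU comfortable: the headline homogeneous quantities use
the 0.1 mm fine grid (≈4.7 M cells, a few minutes), supporting
property checks use 0.2–0.25 mm (results there enter only as ratios,
orderings and invariants, which are far less resolution-sensitive than
absolute volumes: the 0.25 mm grid under-resolves the contact and biases
the delivered current low by ≈10%, which cancels in every such comparison).

## Known limitations

* Tissue is isotropic; anisotropic conductivity tensors from tractography
  are out of scope.
* The electrode–tissue interface is purely resistive: no double-layer
  capacitance, no biphasic charge-balanced waveforms (the pulse enters only
  through the conductivity weighting and the 60 µs cable-model pulse).
* The axon model is a single-cable reduction (no explicit periaxonal
  space); its small-fibre geometry is calibrated, not measured.
* Voxelized contacts are staircase approximations; delivered current at
  0.1 mm is accurate to a few percent, coarser grids bias it low.
* The synthetic brain reproduces conductivity statistics, not anatomy.
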