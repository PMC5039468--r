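# dbsfield

Quasi-static electric-field and axonal-activation modelling for deep brain
stimulation (DBS) lead designs.

DBS programming increasingly involves choices the classic quadripolar lead
never posed: current versus voltage mode, and directional ("steering")
contact configurations. `dbsfield` is an R package for simulating and
comparing what those choices do to the stimulation field. It models four
lead designs — Medtronic 3389, St. Jude 6148, the split-ring steering lead
St. Jude 6180, and the 40-contact SureStim1 array — embedded in homogeneous
or heterogeneous (MRI-classified or synthetic) conductivity volumes, and is
aimed at researchers in computational neuroengineering who need a
self-contained, scriptable alternative to commercial FEM workflows.

## What it computes

* **Field solver** — the steady-current equation ∇·(σ∇V) = 0 on a locally
  refined finite-volume grid, with the active contacts as a common source
  (voltage or current mode), floating inactive contacts, an insulating
  shaft, a 0.25 mm peri-electrode space for chronic-stage models, and a
  grounded ~100 mm cuboid boundary. Current mode uses the linearity of the
  problem: one unit solve serves every amplitude and both modes.
* **Axon model** — a myelinated-fibre cable model (nodes of Ranvier with
  fast Na⁺, persistent Na⁺, slow K⁺ and leak; passive internodes; geometry
  scaled with fibre diameter) driven by the extracellular potential along
  62 lines parallel to the lead, giving activation distances over
  amplitude and diameter sweeps and the calibration of the 0.2 V/mm EF
  isolevel used for comparisons.
* **Metrics** — volume inside an EF isolevel, maximal isocontour extension
  in the axial/sagittal/coronal planes, relative differences between modes
  and leads, and steering-asymmetry profiles.
* **Tissue models** — homogeneous grey matter; T2-intensity classification
  into grey/white/blood/CSF conductivities with partial-volume
  interpolation (NIfTI in/out); and a seeded synthetic brain generator so
  the whole pipeline runs without any patient data.
* **Campaigns** — the built-in 38-run field campaign and 832-curve neuron
  sweep, with CSV/JSON/VTK/NIfTI outputs.

## Worked example

Solve the standard reference case — lead 3389 in homogeneous grey matter
(σ = 0.123 S/m), third contact (C2) at 3 V — and compute the comparison
metrics at the 0.2 V/mm isolevel:

```r
library(dbsfield)

vol  <- homogeneous_volume(side_mm = 100, voxel_mm = 0.5, sigma = 0.123)
lead <- build_lead("3389")
cfg  <- standard_config(lead, "ring_equivalent", "voltage", amplitude = 3)
sol  <- solve_field(vol, lead, cfg, solver_options(fine_mm = 0.2))
sol
#> <field_solution 3389> voltage mode, 3 V -> total current 3.326 mA
#>   grid 1,061,208 cells, CG 336 iters, relres 8.1e-09

isosurface_volume(sol)          # 141.3  (mm^3 inside 0.2 V/mm)
max_extension(sol, "axial")     # 3.295  (mm from the contact centre)
equivalent_current(sol)         # 3.326  (mA delivered at 3 V)

# couple to the axon model: farthest activated 4 um fibre at 3 V
lines <- extract_potential_lines(sol, "posterior")
activation_distance(lines, axon_spec(4), amplitude = 3)
#> [1] 3.235
```

The total current is the 3 V ↔ ~3.4 mA equivalence that motivates comparing
the two operating modes at those amplitudes; the ~3.2–3.3 mm agreement
between the 0.2 V/mm contour and the 4 µm activation distance is what
justifies using that single isolevel as an activation proxy. At the 0.1 mm
study resolution (`solver_options(fine_mm = 0.1)`, a few minutes) the
isolevel volume is ≈143 mm³ and the delivered current ≈3.36 mA.

Heterogeneous models work the same way:

```r
vols <- campaign_volumes(seed = 1)        # synthetic brain + two targets
lead <- build_lead("3389", tip_position = vols$targets$zi,
                   axis = vols$targets$axis)
sol  <- solve_field(vols$heterogeneous, lead, cfg)  # PES applied
```

and `run_campaign(campaign_spec("ef"), vols)` /
`run_sweep(neuron_campaign_solutions(vols))` execute the full built-in
simulation campaigns.

## Package layout

| Path | Contents |
| --- | --- |
| `R/leads.R`, `R/voxelize.R` | lead catalogue, contact configurations, voxelization |
| `R/tissue.R`, `R/synthetic.R` | conductivity volumes: homogeneous, classified, synthetic |
| `R/solver.R`, `src/solver.cpp` | finite-volume assembly + preconditioned CG |
| `R/axon.R`, `src/cable.cpp` | potential lines, cable model, activation sweeps |
| `R/metrics.R` | isolevel volume, extensions, isocontours, steering |
| `R/pipeline.R`, `R/io.R` | campaigns, scenario analysis, VTK/NIfTI/CSV export |
| `vignettes/dbsfield-methods.Rmd` | the model, its assumptions and numerical choices |

See the methods vignette for the physics, the discretisation, the axon
model calibration and the known limitations.
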