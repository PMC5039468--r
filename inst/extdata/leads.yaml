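# DBS lead catalogue (dimensions in mm). Versioned; values follow the
# manufacturers' published specifications.
version: 1
leads:
  "3389":
    vendor: Medtronic
    body_diameter: 1.27
    tip_gap: 1.5          # tip to lower edge of first contact
    contact_height: 1.5
    insulation_gap: 0.5
    n_ring_contacts: 4
    label_base: 0         # vendor labels C0..C3
    tip_contact: false
  "6148":
    vendor: St. Jude Medical
    body_diameter: 1.4
    tip_gap: 0.0
    contact_height: 1.5
    distal_contact_length: 3.0   # covers the tip (hemispherical cap)
    insulation_gap: 0.5
    n_ring_contacts: 4
    label_base: 1         # vendor labels C1..C4
    tip_contact: true
  "6180":
    vendor: St. Jude Medical
    body_diameter: 1.27
    tip_gap: 1.5
    contact_height: 1.5
    insulation_gap: 0.5
    split_rings: [2, 3]   # second and third ring split into 3 segments
    segment_area: 1.8     # mm^2 per split segment; sets the arc angle
    label_base: 1         # vendor labels C1..C8
    tip_contact: false
  SureStim1:
    vendor: Medtronic Eindhoven
    body_diameter: 1.27
    n_rows: 10
    contacts_per_row: 4
    row_pitch: 0.75       # axial pitch between rows
    first_row_offset: 0.5 # tip to lower edge of first row
    ellipse_azimuthal: 0.66  # arc-length extent of a contact
    ellipse_axial: 0.74
    row_angle_step: 90
    alternate_row_offset: 45
    tip_contact: false
pes_thickness: 0.25
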