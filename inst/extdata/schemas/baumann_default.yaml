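# Canonical Baumann score-sheet schema (whole-lung CVID scoring method).
#
# The published method description fixes: 13 abnormalities scored by extent
# (number of affected lobes, lingula counted as a sixth lobe), severity
# grades for bronchiectasis and bronchial wall thickening, a three-level
# nodule size category, subtype notes for reticulation and GGO, the largest
# lymph node measured in mm, and a printed total of 22 values per CT.
# The original score sheet itself is not public, so the three values not
# pinned down by the description are shipped as explicitly flagged
# placeholders (reconstructed: true); replacing them is a config change,
# not a code change.
method_name: baumann
lobes: [RUL, RML, RLL, LUL, lingula, LLL]
multipliers:
  bronchiectasis: {"1": 1.00, "1.5": 1.25, "2": 1.50, "2.5": 1.75, "3": 2.00}
  bronchial_wall_thickening: {"1": 1.00, "2": 1.25, "3": 1.50}
items:
  - item_id: bronchial_wall_thickening_extent
    abnormality: bronchial_wall_thickening
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [airway, total]
  - item_id: bronchiectasis_extent
    abnormality: bronchiectasis
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [airway, total]
  - item_id: mucus_plugging_extent
    abnormality: mucus_plugging
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [airway, total]
  - item_id: atelectasis_extent
    abnormality: atelectasis
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [total]
  - item_id: nodules_extent
    abnormality: nodules
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [glild, total]
  - item_id: reticulation_extent
    abnormality: reticulation
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [glild, total]
  - item_id: consolidation_extent
    abnormality: consolidation
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [total]
  - item_id: ggo_extent
    abnormality: ggo
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [glild, total]
  - item_id: cysts_extent
    abnormality: cysts
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [total]
  - item_id: emphysema_bullae_extent
    abnormality: emphysema_bullae
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [total]
  - item_id: scars_bands_extent
    abnormality: scars_bands
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [total]
  - item_id: trapped_air_extent
    abnormality: trapped_air
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [total]
    excludable: true
  - item_id: lymphadenopathy_extent
    abnormality: lymphadenopathy
    scope: whole_lung
    value_kind: extent_lobe_count
    allowed: {set: [0, 1, 2, 3, 4, 5, 6]}
    composites: [total]
  - item_id: bronchiectasis_severity
    abnormality: bronchiectasis
    scope: whole_lung
    value_kind: severity_grade
    allowed: {set: [0, 1, 1.5, 2, 2.5, 3]}
    composites: []
  - item_id: bronchial_wall_thickening_severity
    abnormality: bronchial_wall_thickening
    scope: whole_lung
    value_kind: severity_grade
    allowed: {set: [0, 1, 2, 3]}
    composites: []
  - item_id: nodule_size_category
    abnormality: nodules
    scope: whole_lung
    value_kind: size_category
    # 0 none, 1 largest nodule < 5 mm, 2 between 5 and 10 mm, 3 > 10 mm
    allowed: {set: [0, 1, 2, 3]}
    composites: []
  - item_id: reticulation_subtype
    abnormality: reticulation
    scope: whole_lung
    value_kind: subtype_category
    # 0 none, 1 inflammatory, 2 fibrotic, 3 mixed
    allowed: {set: [0, 1, 2, 3]}
    composites: []
  - item_id: ggo_subtype
    abnormality: ggo
    scope: whole_lung
    value_kind: subtype_category
    # 0 none, 1 inflammatory, 2 fibrotic
    allowed: {set: [0, 1, 2]}
    composites: []
  - item_id: lymph_node_mm
    abnormality: lymphadenopathy
    scope: whole_lung
    value_kind: measurement_mm
    allowed: {min: 0, max: 99}
    composites: []
  # ---- placeholders: qualifiers not pinned down by the published method ----
  - item_id: mucus_plugging_severity
    abnormality: mucus_plugging
    scope: whole_lung
    value_kind: severity_grade
    allowed: {set: [0, 1, 2, 3]}
    composites: []
    reconstructed: true
  - item_id: atelectasis_type
    abnormality: atelectasis
    scope: whole_lung
    value_kind: subtype_category
    # 0 none, 1 subsegmental, 2 segmental or larger
    allowed: {set: [0, 1, 2]}
    composites: []
    reconstructed: true
  - item_id: emphysema_bullae_type
    abnormality: emphysema_bullae
    scope: whole_lung
    value_kind: subtype_category
    # 0 none, 1 predominantly emphysema, 2 predominantly bullae
    allowed: {set: [0, 1, 2]}
    composites: []
    reconstructed: true
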