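# Canonical Hartmann score-sheet schema (lobe-wise CVID scoring method,
# derived from the cystic-fibrosis CT score).
#
# Published constraints: 13 abnormalities each scored per lobe (lingula as a
# sixth lobe) for both extent and severity on 0-3 scales, 26 values per lobe,
# lymphadenopathy scored once as presence (short-axis diameter >= 10 mm),
# 157 values per CT: 13 x 2 x 6 + 1.  The original score sheet is not
# public; this file is the documented reconstruction satisfying every
# printed constraint (bullae, cysts and emphysema as separate rows;
# reticulation and distortion as separate rows).
method_name: hartmann
lobes: [RUL, RML, RLL, LUL, lingula, LLL]
multipliers:
  bronchiectasis: {"1": 1.00, "1.5": 1.25, "2": 1.50, "2.5": 1.75, "3": 2.00}
  bronchial_wall_thickening: {"1": 1.00, "2": 1.25, "3": 1.50}
abnormalities:
  # expanded by the loader into <abn>_extent and <abn>_severity per-lobe items
  - name: bronchial_wall_thickening
    severity_allowed: [0, 1, 2, 3]
    composites: [airway, total]
  - name: bronchiectasis
    severity_allowed: [0, 1, 1.5, 2, 2.5, 3]
    composites: [airway, total]
  - name: mucus_plugging
    severity_allowed: [0, 1, 2, 3]
    composites: [airway, total]
  - name: atelectasis
    severity_allowed: [0, 1, 2, 3]
    composites: [total]
  - name: nodules
    severity_allowed: [0, 1, 2, 3]
    composites: [glild, total]
  - name: reticulation
    severity_allowed: [0, 1, 2, 3]
    composites: [glild, total]
  - name: consolidation
    severity_allowed: [0, 1, 2, 3]
    composites: [total]
  - name: ggo
    severity_allowed: [0, 1, 2, 3]
    composites: [glild, total]
  - name: bullae
    severity_allowed: [0, 1, 2, 3]
    composites: [total]
  - name: cysts
    severity_allowed: [0, 1, 2, 3]
    composites: [total]
  - name: emphysema
    severity_allowed: [0, 1, 2, 3]
    composites: [total]
  - name: distortion
    severity_allowed: [0, 1, 2, 3]
    composites: [total]
  - name: trapped_air
    severity_allowed: [0, 1, 2, 3]
    composites: [total]
    excludable: true
items:
  - item_id: lymphadenopathy_presence
    abnormality: lymphadenopathy
    scope: once
    value_kind: presence
    allowed: {set: [0, 1]}
    composites: []
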