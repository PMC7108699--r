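# Head-and-neck tissue registry: ICRP 103 weighting factors, fractions
# irradiated, and the dosimeter sites contributing to each tissue.
# Out-of-field ICRP tissues are treated as zero-dose and omitted; the
# weights listed here (plus the shared remainder weight) sum to 0.36.
#
# Notes:
# - Bone marrow: subsite fractions sum to 0.123; a printed total of 12.2%
#   circulates in the literature and is NOT enforced, the registry derives
#   the total from the subsites.
# - Bone surface, cervical spine: the default dosimeter site is 19 (the
#   cervical-spine slot, shared with bone marrow). Some sources print
#   site 21 (a thyroid slot) for this row, likely a typo; the loader option
#   boneSurfaceCspineSite = 21 selects that mapping instead.
sites:
  - {site_id: 1,  anatomical_label: "calvaria anterior",        phantom_slice: 2}
  - {site_id: 2,  anatomical_label: "calvaria posterior",       phantom_slice: 2}
  - {site_id: 3,  anatomical_label: "fronto-parietal lobe",     phantom_slice: 3}
  - {site_id: 4,  anatomical_label: "parieto-occipital lobe",   phantom_slice: 3}
  - {site_id: 5,  anatomical_label: "fornix",                   phantom_slice: 4}
  - {site_id: 6,  anatomical_label: "pituitary",                phantom_slice: 4}
  - {site_id: 7,  anatomical_label: "right eye",                phantom_slice: 4}
  - {site_id: 8,  anatomical_label: "left eye",                 phantom_slice: 4}
  - {site_id: 9,  anatomical_label: "midbrain",                 phantom_slice: 5}
  - {site_id: 10, anatomical_label: "cerebellum",               phantom_slice: 5}
  - {site_id: 11, anatomical_label: "nasal cavity",             phantom_slice: 5}
  - {site_id: 12, anatomical_label: "palate",                   phantom_slice: 6}
  - {site_id: 13, anatomical_label: "cheek skin",               phantom_slice: 6}
  - {site_id: 14, anatomical_label: "right mandible body (parotid region)", phantom_slice: 7}
  - {site_id: 15, anatomical_label: "left mandible body (parotid region)",  phantom_slice: 7}
  - {site_id: 16, anatomical_label: "esophagus",                phantom_slice: 9}
  - {site_id: 17, anatomical_label: "right submandibular gland", phantom_slice: 8}
  - {site_id: 18, anatomical_label: "left submandibular gland",  phantom_slice: 8}
  - {site_id: 19, anatomical_label: "cervical spine",           phantom_slice: 9}
  - {site_id: 20, anatomical_label: "neck skin",                phantom_slice: 9}
  - {site_id: 21, anatomical_label: "right thyroid lobe",       phantom_slice: 10}
  - {site_id: 22, anatomical_label: "left thyroid lobe",        phantom_slice: 10}
remainder_weighting_factor: 0.12
tissues:
  - tissue_name: bone_marrow
    weighting_factor: 0.12
    category: weighted_tissue
    aggregate: weighted_sum
    apply_meacr: false
    subsites:
      - {subsite_name: mandible,       subsite_fraction: 0.008, dosimeter_site_ids: [14, 15]}
      - {subsite_name: calvaria,       subsite_fraction: 0.077, dosimeter_site_ids: [1, 2]}
      - {subsite_name: cervical_spine, subsite_fraction: 0.038, dosimeter_site_ids: [19]}
  - tissue_name: thyroid
    weighting_factor: 0.04
    category: weighted_tissue
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: thyroid, subsite_fraction: 1.0, dosimeter_site_ids: [21, 22]}
  - tissue_name: esophagus
    weighting_factor: 0.04
    category: weighted_tissue
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: esophagus, subsite_fraction: 0.10, dosimeter_site_ids: [16]}
  - tissue_name: skin
    weighting_factor: 0.01
    category: weighted_tissue
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: skin, subsite_fraction: 0.05, dosimeter_site_ids: [13, 20]}
  - tissue_name: bone_surface
    weighting_factor: 0.01
    category: weighted_tissue
    aggregate: weighted_sum
    apply_meacr: true
    subsites:
      - {subsite_name: mandible,       subsite_fraction: 0.013, dosimeter_site_ids: [14, 15]}
      - {subsite_name: calvaria,       subsite_fraction: 0.118, dosimeter_site_ids: [1, 2]}
      - {subsite_name: cervical_spine, subsite_fraction: 0.034, dosimeter_site_ids: [19]}
  - tissue_name: salivary_glands
    weighting_factor: 0.01
    category: weighted_tissue
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: parotid,       subsite_fraction: 1.0, dosimeter_site_ids: [14, 15]}
      - {subsite_name: submandibular, subsite_fraction: 1.0, dosimeter_site_ids: [17, 18]}
  - tissue_name: brain
    weighting_factor: 0.01
    category: weighted_tissue
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: brain, subsite_fraction: 1.0, dosimeter_site_ids: [3, 4, 5, 6, 9, 10]}
  - tissue_name: lymphatic_nodes
    category: remainder_component
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: lymphatic_nodes, subsite_fraction: 0.05, dosimeter_site_ids: [14, 15, 17, 18, 19]}
  - tissue_name: muscle
    category: remainder_component
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: muscle, subsite_fraction: 0.05, dosimeter_site_ids: [14, 15, 17, 18, 19]}
  - tissue_name: extrathoracic_airways
    category: remainder_component
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: extrathoracic_airways, subsite_fraction: 1.0, dosimeter_site_ids: [14, 15, 17, 18, 16]}
  - tissue_name: oral_mucosa
    category: remainder_component
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: oral_mucosa, subsite_fraction: 1.0, dosimeter_site_ids: [14, 15, 16, 17, 18, 19]}
  - tissue_name: eyes
    category: remainder_component
    aggregate: mean
    apply_meacr: false
    subsites:
      - {subsite_name: eyes, subsite_fraction: 1.0, dosimeter_site_ids: [7, 8]}
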