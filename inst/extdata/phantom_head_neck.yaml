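# Stylized adult head-and-neck phantom for the Monte Carlo arm.
#
# This is a bespoke geometric phantom (documented here and in the package
# vignette), not a reproduction of any proprietary phantom model. Organs are
# simple primitives; EARLIER entries shadow LATER ones where they overlap,
# which is how embedded organs (brain inside the calvaria shell, viscera
# inside the neck) are expressed.
#
# Coordinates in cm. Origin at the rotation-center reference point (jaw
# centroid); +z up, -y anterior, +x patient right. Dimension semantics by
# primitive: sphere d1 = radius; cylinder (z-aligned) d1 = radius,
# d2 = half-height; ellipsoid d1,d2,d3 = semi-axes; box d1,d2,d3 =
# half-sizes. Organ masses are derived at load time by grid integration of
# the shadowed geometry times material density
# (soft tissue 1.06, bone 1.40, air 0.0012 g/cm^3).
reference_point: [0.0, 0.0, 0.0]
organs:
  - {id: eye_right,        organ: eyes,                  primitive: sphere,    material: soft_tissue, center: [ 3.0, -6.8,  6.0], dims: [1.2]}
  - {id: eye_left,         organ: eyes,                  primitive: sphere,    material: soft_tissue, center: [-3.0, -6.8,  6.0], dims: [1.2]}
  - {id: oral_mucosa,      organ: oral_mucosa,           primitive: box,       material: soft_tissue, center: [ 0.0, -4.0,  0.0], dims: [2.5, 2.0, 1.0]}
  - {id: thyroid_right,    organ: thyroid,               primitive: box,       material: soft_tissue, center: [ 1.5, -4.5, -9.0], dims: [1.0, 0.8, 1.5]}
  - {id: thyroid_left,     organ: thyroid,               primitive: box,       material: soft_tissue, center: [-1.5, -4.5, -9.0], dims: [1.0, 0.8, 1.5]}
  - {id: esophagus,        organ: esophagus,             primitive: cylinder,  material: soft_tissue, center: [ 0.0,  1.0, -9.0], dims: [0.9, 5.0]}
  - {id: airways,          organ: extrathoracic_airways, primitive: cylinder,  material: soft_tissue, center: [ 0.0, -1.5, -7.0], dims: [0.8, 5.0]}
  - {id: submandibular_right, organ: submandibular,      primitive: sphere,    material: soft_tissue, center: [ 3.0, -4.0, -3.0], dims: [1.4]}
  - {id: submandibular_left,  organ: submandibular,      primitive: sphere,    material: soft_tissue, center: [-3.0, -4.0, -3.0], dims: [1.4]}
  - {id: parotid_right,    organ: parotid,               primitive: sphere,    material: soft_tissue, center: [ 5.5, -1.0,  1.5], dims: [1.7]}
  - {id: parotid_left,     organ: parotid,               primitive: sphere,    material: soft_tissue, center: [-5.5, -1.0,  1.5], dims: [1.7]}
  - {id: lymph_right,      organ: lymphatic_nodes,           primitive: sphere,    material: soft_tissue, center: [ 4.0, -2.0, -8.0], dims: [1.0]}
  - {id: lymph_left,       organ: lymphatic_nodes,           primitive: sphere,    material: soft_tissue, center: [-4.0, -2.0, -8.0], dims: [1.0]}
  - {id: mandible,         organ: mandible,              primitive: box,       material: bone,        center: [ 0.0, -4.0, -1.5], dims: [4.0, 3.0, 1.2]}
  - {id: cervical_spine,   organ: cervical_spine,        primitive: cylinder,  material: bone,        center: [ 0.0,  2.8, -8.0], dims: [1.5, 6.0]}
  - {id: brain,            organ: brain,                 primitive: ellipsoid, material: soft_tissue, center: [ 0.0,  0.0, 12.0], dims: [6.5, 8.0, 5.5]}
  - {id: calvaria,         organ: calvaria,              primitive: ellipsoid, material: bone,        center: [ 0.0,  0.0, 12.0], dims: [7.3, 8.8, 6.3]}
  - {id: skin_right,       organ: skin,                  primitive: box,       material: soft_tissue, center: [ 7.6,  0.0,  6.0], dims: [0.5, 2.0, 2.0]}
  - {id: skin_left,        organ: skin,                  primitive: box,       material: soft_tissue, center: [-7.6,  0.0,  6.0], dims: [0.5, 2.0, 2.0]}
  - {id: face,             organ: face_residual,         primitive: box,       material: soft_tissue, center: [ 0.0, -3.5, -0.5], dims: [5.5, 4.5, 2.5]}
  - {id: neck_muscle,      organ: muscle,                primitive: cylinder,  material: soft_tissue, center: [ 0.0, -1.0, -8.0], dims: [5.5, 6.0]}
  - {id: head,             organ: head_residual,         primitive: ellipsoid, material: soft_tissue, center: [ 0.0,  0.0,  8.0], dims: [8.0, 9.5, 11.0]}
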