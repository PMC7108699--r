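# Exposure protocols of the two CBCT units, one mapping per examination
# mode. Beam width/height are stated at the rotation center. Exposure time
# and beam height are assigned per mode consistently with the FOV column
# alignment of the manufacturer specifications.
protocols:
  - machine_name: CS9300
    mode_name: facial
    fov_width_cm: 17.0
    fov_height_cm: 13.5
    tube_voltage_kVp: 90.0
    tube_current_mA: 8.0
    exposure_time_s: 20.0
    rotation_angle_deg: 360.0
    filtration_mmAl: 2.8
    source_to_reference_cm: 49.50
    beam_width_at_center_cm: 17.0
    beam_height_at_center_cm: 13.5
  - machine_name: CS9300
    mode_name: dual jaw
    fov_width_cm: 10.0
    fov_height_cm: 10.0
    tube_voltage_kVp: 90.0
    tube_current_mA: 8.0
    exposure_time_s: 12.0
    rotation_angle_deg: 360.0
    filtration_mmAl: 2.8
    source_to_reference_cm: 49.50
    beam_width_at_center_cm: 10.0
    beam_height_at_center_cm: 10.0
  - machine_name: RAYSCAN alpha+
    mode_name: large jaw
    fov_width_cm: 16.0
    fov_height_cm: 10.0
    tube_voltage_kVp: 80.0
    tube_current_mA: 12.0
    exposure_time_s: 14.0
    rotation_angle_deg: 360.0
    filtration_mmAl: 2.8
    source_to_reference_cm: 55.88
    beam_width_at_center_cm: 16.0
    beam_height_at_center_cm: 10.0
  - machine_name: RAYSCAN alpha+
    mode_name: jaw
    fov_width_cm: 10.0
    fov_height_cm: 10.0
    tube_voltage_kVp: 80.0
    tube_current_mA: 12.0
    exposure_time_s: 14.0
    rotation_angle_deg: 360.0
    filtration_mmAl: 2.8
    source_to_reference_cm: 55.88
    beam_width_at_center_cm: 10.0
    beam_height_at_center_cm: 10.0
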