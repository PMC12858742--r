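# Scenario sampling presets.
# Azimuth is measured in the horizontal plane about +z, in degrees, relative to
# the named zero-reference axis:
#   bed_right : the right-hand side of the bed (-y in world coordinates)
#   bed_front : the front (foot end) of the bed (-x in world coordinates)
# Elevation is degrees above the horizontal plane through the pelvis (positive
# = camera above the plane). Roll is about the camera's optical axis. Distance
# is in scene units; the camera is placed at distance * unit_scale metres from
# the target.
defaults:
  elevation_range_deg: [-54.0, 18.0]
  roll_range_deg: [-115.0, -30.0]
  distance_range: [0.3, 0.6]
  unit_scale: 5.0
  flip_elevation: false
  renders_per_config: 4
  n_configs: 2700
  intensity_range: [0.3, 3.0]
presets:
  B:
    azimuth_range_deg: [-35.0, 35.0]
    azimuth_zero_reference: bed_right
  C:
    azimuth_range_deg: [15.0, 35.0]
    azimuth_zero_reference: bed_front
  D:
    azimuth_range_deg: [0.0, 0.0]
    azimuth_zero_reference: bed_front
skin_palette:
  - [255, 224, 196]
  - [241, 194, 167]
  - [224, 172, 138]
  - [198, 134, 98]
  - [161, 102, 74]
  - [128, 80, 56]
  - [96, 57, 38]
  - [66, 37, 24]
hair_palette:
  - [20, 16, 12]
  - [60, 40, 20]
  - [120, 80, 40]
  - [180, 150, 90]
  - [200, 200, 200]
blanket_palette:
  - [200, 215, 235]
  - [225, 225, 225]
  - [190, 220, 200]
  - [235, 225, 200]
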