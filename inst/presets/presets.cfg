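# Named parameter presets for the airway pipeline.
# scales_mm spans trachea-to-subsegmental airway radii.

[lung-airways]
air_threshold_hu = -500
scales_mm = 1.5, 2, 3, 4.5, 6
contrast_hu = 150
probability_threshold = 0.5
hu_air_max = -925
prune_mm = 0
dilation_radius_mm = 1.0
hu_ceiling = -500
gradient_factor = 0.5

[lung-airways-phantom]
air_threshold_hu = -500
scales_mm = 1.5, 2, 3, 4.5, 6
contrast_hu = 150
probability_threshold = 0.5
hu_air_max = -925
prune_mm = 0
dilation_radius_mm = 1.0
hu_ceiling = -500
gradient_factor = 0.5
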