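speed_label: high
speed_multiplier: 1.0
orbital_speed: 0.5
missile_speed: 5.0
firing_lower_bound: 500.0
firing_upper_bound: 1200.0
points_per_burst: 200.0
miss_penalty: 2.0
double_shot_window: 250.0
inflation_step: 0.1
deflation_rate: 0.005
rotation_probability: 0.333333333333333
rotation_magnitude_range:
- 60.0
- 120.0
rotation_onset_range:
- 1000.0
- 4000.0
post_rotation_grace: 4000.0
game_duration_ms: 180000.0
tick_ms: 16.0
turn_step: 15.0
orbit_radius: 124.340000000000003
balloon_full_size: 18.0
balloon_base_size: 8.0
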