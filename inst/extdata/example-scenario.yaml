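# Desk-scale app scenario: 25% baseline exercise probability, mid-level
# engagement (50% aware, 58.23% of those download, 55% of those opt into
# notifications), 5-year horizon, 10 paired replicates.
population:
  n_agents: 10000
  smartphone_ownership: 0.80
environment:
  centers_per_ward: [3, 3, 3, 4, 3, 6, 1, 2]
  geofence_radius_miles: 0.5
  walk_reach_km: 1.0
  drive_reach_km: 8.0
  class_duration_min: 50
  class_mets: 6.5
engagement:
  p_aware: 0.50
  p_download: 0.5823
  p_notify: 0.55
  mode: sampled
attrition:
  r_inf: 0.3
  window_days: 90
app:
  intro_day: 0
baseline_exercise_prob: 0.25
horizon_years: 5
replicates: 10
seed: 2024
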