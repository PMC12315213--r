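# Conventional temperate maize-silage parameterisation (not a published
# calibration); fields map 1:1 onto crop_phenology_params().
crop_name: maize
base_temp: 8
upper_cutoff_temp: 30
sowing_rule:
  type: fixed
  month_day: "10-01"
stage_thresholds: [150, 450, 900, 1350]
stage_kc: [0.3, 0.75, 1.2, 0.5]
season_start: "07-01"
season_cutoff: "06-30"
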