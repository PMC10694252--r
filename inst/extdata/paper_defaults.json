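{
  "base_pct": 40,
  "d_pred": 7.85,
  "d_main_mid": 9.78,
  "d_mid_detail": 5.61,
  "d_format": 6.83,
  "d_clarity": 4.78,
  "interaction_atten": 0.55,
  "sd_participant": 8,
  "sd_item": 5,
  "sd_item_slope": 2,
  "sd_resid": 0,
  "rspan_loading": 0.5,
  "pause_loading_between": 0.6,
  "pause_loading_within": 0.3,
  "n_props_per_level": {"main": 10, "mid": 15, "detail": 20}
}
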