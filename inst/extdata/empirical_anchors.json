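{
  "unsafe_behavior_ratio": 0.3333,
  "unsafe_behavior_ratio_source": "field observation studies: about one third of construction workers act unsafely",
  "near_miss_to_accident": 10.0,
  "near_miss_to_accident_source": "classical industrial-accident pyramid, 300 near misses : 30 accidents",
  "accident_rate": 3.2,
  "accident_rate_source": "US BLS 2016 recordable occupational injury and illness incidence in construction, per 100 full-time workers"
}
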