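{
  "title": "wearbiosig session report",
  "type": "object",
  "required": ["mode", "seed", "fs", "duration"],
  "properties": {
    "mode": {"type": "string"},
    "seed": {"type": "integer"},
    "fs": {"type": "number"},
    "duration": {"type": "number"},
    "n_peaks": {"type": "integer"},
    "mean_bpm": {"type": "number"},
    "sdnn": {"type": "number"},
    "rmssd": {"type": "number"},
    "lf_nu": {"type": "number"},
    "hf_nu": {"type": "number"},
    "lf_hf": {"type": "number"},
    "mean_rms": {"type": "number"},
    "max_rms": {"type": "number"},
    "n_long_windows": {"type": "integer"}
  }
}
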