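{
  "version": 1,
  "dialects": {
    "native": {
      "columns": {
        "call_id": "call_id",
        "rat_id": "rat_id",
        "session_id": "session_id",
        "onset": "onset_s",
        "duration": "duration_s",
        "peak_frequency": "peak_freq_hz",
        "mean_power": "mean_power_db",
        "call_type": "call_type",
        "subtype": "subtype"
      },
      "time_unit": "s",
      "frequency_unit": "hz",
      "separator": ","
    },
    "avisoft_like": {
      "columns": {
        "call_id": "label",
        "onset": "start_time_s",
        "duration": "duration_ms",
        "peak_frequency": "peak_freq_khz",
        "mean_power": "mean_power_db"
      },
      "time_unit": "ms",
      "onset_unit": "s",
      "frequency_unit": "khz",
      "separator": "\t"
    },
    "deepsqueak_like": {
      "columns": {
        "call_id": "id",
        "onset": "begin_time_s",
        "duration": "call_length_s",
        "peak_frequency": "principal_frequency_khz",
        "mean_power": "mean_power_db"
      },
      "time_unit": "s",
      "frequency_unit": "khz",
      "separator": ","
    }
  }
}
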