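# Per-artifact roaming-beat criteria for the four nursing-home activities.
# t_min / t_max / quantum are minutes; quantum defaults to t_min.
activities:
  feeding:
    t_min: 5
    t_max: 50
    quantum: 5
    mode: strict
    artifacts:
      tray: {min_beats: 2, max_beats: 2}
  blood_pressure:
    t_min: 5
    t_max: 10
    quantum: 5
    mode: strict
    artifacts:
      bp_device: {min_beats: 3, max_beats: 4}
  hygiene:
    t_min: 10
    t_max: 30
    quantum: 10
    mode: flexible
    k_required: 2
    artifacts:
      solution: {min_beats: 3}
      cream: {min_beats: 3}
      paper_towel: {min_beats: 6}
  medications:
    t_min: 3
    t_max: 5
    quantum: 3
    mode: strict
    artifacts:
      pillbox: {min_beats: 2}
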